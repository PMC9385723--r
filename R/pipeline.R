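# Workflow drivers tying the stages together: the plastome/mitogenome
# comparison report, the graph-resolution wrapper, and the genome-size
# difference table.

as_genome_input <- function(x, circular = TRUE) {
  if (inherits(x, "genome")) return(x)
  if (is.character(x) && length(x) == 1L && file.exists(x))
    return(read_fasta(x, circular = circular)[[1L]])
  stop("expected a genome object or a FASTA path, got ", class(x)[1])
}

#' Compare a plastome and a mitogenome
#'
#' Runs the full desk pipeline: per-genome summary statistics, repeat
#' landscapes (SSR, dispersed, tandem), quadripartite structure of the
#' plastome, homologous-fragment detection (with origin classification
#' when an outgroup pair is supplied), and the headline size difference
#' `mitogenome length - plastome length`. Every number in the report is
#' recomputed from the stage outputs it cites.
#'
#' @param plastome,mitogenome [genome()] objects or FASTA paths.
#' @param outgroup_plastome,outgroup_mito optional outgroup pair for
#'   origin classification.
#' @param out_dir optional directory: stage TSVs and a `summary.json` are
#'   written there.
#' @param evalue_cutoff homology significance cutoff.
#' @param run_tandem tandem detection is the slowest stage; disable for
#'   quick passes.
#' @return the summary report (list).
#' @export
run_compare <- function(plastome, mitogenome, outgroup_plastome = NULL,
                        outgroup_mito = NULL, out_dir = NULL,
                        evalue_cutoff = 1e-5, run_tandem = TRUE) {
  cp <- as_genome_input(plastome)
  mt <- as_genome_input(mitogenome)

  stats <- rbind(genome_stats(cp), genome_stats(mt))
  stats$role <- c("plastome", "mitogenome")

  ssr_cp <- find_ssrs(cp)
  ssr_mt <- find_ssrs(mt)
  disp_cp <- find_dispersed(cp)
  disp_mt <- find_dispersed(mt)
  tan_cp <- if (run_tandem) find_tandem(cp) else NULL
  tan_mt <- if (run_tandem) find_tandem(mt) else NULL

  quad <- tryCatch(detect_quadripartite(cp), error = function(e) NULL)

  frags <- find_fragments(cp, mt, evalue_cutoff = evalue_cutoff)
  fstats <- fragment_stats(frags, mt)
  origin <- if (!is.null(outgroup_plastome) && !is.null(outgroup_mito) &&
                nrow(frags) > 0L)
    classify_origin(frags, cp, as_genome_input(outgroup_plastome),
                    as_genome_input(outgroup_mito),
                    evalue_cutoff = evalue_cutoff)
  else NULL

  report <- list(
    genomes = stats,
    size_difference = genome_length(mt) - genome_length(cp),
    plastome_repeats = summarize_repeats(ssr_cp, disp_cp, tan_cp),
    mitogenome_repeats = summarize_repeats(ssr_mt, disp_mt, tan_mt),
    quadripartite = if (is.null(quad)) NULL else
      list(lsc_length = ((quad$lsc[2] - quad$lsc[1]) %% genome_length(cp)) + 1L,
           ssc_length = ((quad$ssc[2] - quad$ssc[1]) %% genome_length(cp)) + 1L,
           ir_length = quad$ir_length,
           regions = quad),
    homology = fstats,
    origin_calls = if (is.null(origin)) NULL else as.list(table(origin$call)))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_report(stats, file.path(out_dir, "genome_stats.tsv"))
    write_tsv_report(ssr_cp, file.path(out_dir, "ssr_plastome.tsv"))
    write_tsv_report(ssr_mt, file.path(out_dir, "ssr_mitogenome.tsv"))
    write_tsv_report(disp_cp, file.path(out_dir, "dispersed_plastome.tsv"))
    write_tsv_report(disp_mt, file.path(out_dir, "dispersed_mitogenome.tsv"))
    if (run_tandem) {
      write_tsv_report(tan_cp, file.path(out_dir, "tandem_plastome.tsv"))
      write_tsv_report(tan_mt, file.path(out_dir, "tandem_mitogenome.tsv"))
    }
    write_tsv_report(frags, file.path(out_dir, "fragments.tsv"))
    if (!is.null(origin)) write_tsv_report(origin, file.path(out_dir, "origin.tsv"))
    write_json_report(report, file.path(out_dir, "summary.json"))
  }
  report
}

#' Resolve a unitig graph from files and emit the master circle
#'
#' Thin wrapper: read GFA and FASTQ, resolve all DBSs with read support,
#' walk the Eulerian circuit and write the circular genome FASTA plus a
#' decisions table.
#'
#' @param gfa path to the unitig GFA.
#' @param reads_fastq path to long reads (FASTQ).
#' @param out_fasta output genome FASTA path.
#' @param decisions_tsv optional decision-log TSV path.
#' @param k,min_span,flank see [resolve_graph()].
#' @return the reconstructed [genome()] (invisibly the file is written).
#' @export
run_resolve <- function(gfa, reads_fastq, out_fasta = NULL,
                        decisions_tsv = NULL, k = 15L, min_span = 200L,
                        flank = 1000L) {
  g <- read_gfa(gfa)
  reads <- read_fastq(reads_fastq)
  res <- resolve_graph(g, reads, k = k, min_span = min_span, flank = flank)
  path <- cyclic_path(res$graph)
  out <- path_to_sequence(res$graph, path)
  if (!is.null(out_fasta)) write_fasta(out, out_fasta)
  if (!is.null(decisions_tsv)) write_tsv_report(res$decisions, decisions_tsv)
  out
}

#' Organelle genome size-difference table
#'
#' Recomputes the size-difference column (mitogenome minus plastome) from
#' the size columns of a comparison table such as the bundled Asteraceae
#' table (`system.file("extdata", "asteraceae_genome_sizes.tsv",
#' package = "organellr")`).
#'
#' @param tbl data.frame with columns `species`, `mitogenome_bp`,
#'   `plastome_bp` (a path to such a TSV is also accepted).
#' @return the table with a recomputed `size_difference` column.
#' @export
size_difference_table <- function(tbl) {
  if (is.character(tbl)) tbl <- utils::read.delim(tbl, stringsAsFactors = FALSE)
  stopifnot(all(c("species", "mitogenome_bp", "plastome_bp") %in% names(tbl)))
  tbl$size_difference <- tbl$mitogenome_bp - tbl$plastome_bp
  tbl
}
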