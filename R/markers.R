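# Hypervariable intergenic spacers and diagnostic markers: IGS extraction
# from annotated genomes, deterministic center-star alignment, Kimura
# 2-parameter distances with pairwise gap deletion, region ranking, and
# greedy selection of a diagnostic SNP/indel set that discriminates every
# species pair.

#' Extract intergenic spacer regions from an annotated genome
#'
#' For each pair of genes adjacent in circular order (outermost gene
#' boundaries, multi-interval genes taken as one span) the inter-gene
#' interval and its sequence are returned. Names join the flanking gene
#' names (tRNA anticodon suffixes preserved, e.g. `rpl32-trnL-UAG`).
#' Overlapping or abutting genes give a zero-length spacer.
#'
#' @param g an annotated [genome()] with >= 2 features.
#' @return data.frame: name, gene_left, gene_right, start, end (end <
#'   start marks the origin-wrapping spacer), length, seq.
#' @export
extract_igs <- function(g) {
  if (is.null(g$features) || length(unique(g$features$name)) < 2L)
    stop("genome has fewer than 2 annotated genes")
  f <- g$features
  sp <- split(f, f$name)
  genes <- data.frame(name = names(sp),
                      start = vapply(sp, function(d) as.integer(min(d$start)), 1L),
                      end = vapply(sp, function(d) as.integer(max(d$end)), 1L),
                      stringsAsFactors = FALSE)
  genes <- genes[order(genes$start), , drop = FALSE]
  L <- genome_length(g)
  n <- nrow(genes)
  rows <- vector("list", n)
  last <- if (g$circular) n else n - 1L
  for (i in seq_len(last)) {
    j <- if (i == n) 1L else i + 1L
    s <- genes$end[i] + 1L
    e <- genes$start[j] - 1L
    if (i == n) { # wrap spacer
      s <- idx_mod(s, L)
      e <- idx_mod(genes$start[j] - 1L + L, L)
      len <- ((e - s) %% L) + 1L
      if (genes$end[i] >= L && genes$start[j] == 1L) len <- 0L
      seq <- if (len > 0L) genome_subseq(g, s, e) else ""
    } else if (e < s) { # overlapping/abutting genes
      len <- 0L
      seq <- ""
    } else {
      len <- e - s + 1L
      seq <- substr(g$seq, s, e)
    }
    rows[[i]] <- data.frame(name = paste0(genes$name[i], "-", genes$name[j]),
                            gene_left = genes$name[i],
                            gene_right = genes$name[j],
                            start = if (len > 0L) s else NA_integer_,
                            end = if (len > 0L) e else NA_integer_,
                            length = len, seq = seq, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Collect one IGS region across a species panel
#'
#' @param genomes named list of annotated genomes (names = species).
#' @return named list: region name -> named character vector of sequences
#'   (species with a zero-length or missing region dropped with a
#'   warning). Regions present in fewer than 2 species are omitted.
#' @export
igs_panel <- function(genomes) {
  if (is.null(names(genomes)))
    names(genomes) <- paste0("sp", seq_along(genomes))
  per_sp <- lapply(genomes, extract_igs)
  all_regions <- unique(unlist(lapply(per_sp, `[[`, "name")))
  out <- list()
  for (rg in all_regions) {
    seqs <- character(0)
    for (sp in names(per_sp)) {
      d <- per_sp[[sp]]
      hit <- d[d$name == rg & d$length > 0L, , drop = FALSE]
      if (nrow(hit) == 0L) {
        warning("species ", sp, " lacks region ", rg, "; dropped from panel")
        next
      }
      seqs[sp] <- hit$seq[1]
    }
    if (length(seqs) >= 2L) out[[rg]] <- seqs
  }
  out
}

## center-star merge bookkeeping for one pairwise alignment:
## returns per-center-slot insertion chars and the subject char aligned to
## each center position
project_alignment <- function(center_aln, subject_aln, Lc) {
  cs <- strsplit(center_aln, "", fixed = TRUE)[[1]]
  os <- strsplit(subject_aln, "", fixed = TRUE)[[1]]
  ins <- vector("list", Lc + 1L)
  at <- character(Lc)
  c_i <- 0L
  for (col in seq_along(cs)) {
    if (cs[col] == "-") {
      ins[[c_i + 1L]] <- c(ins[[c_i + 1L]], os[col])
    } else {
      c_i <- c_i + 1L
      at[c_i] <- os[col]
    }
  }
  list(ins = ins, at = at)
}

#' Align one IGS region across species (center-star)
#'
#' Deterministic progressive alignment: the sequence minimising the summed
#' pairwise edit distance is the center; every other sequence is aligned
#' to it with affine gaps (open 10, extend 2), and the pairwise alignments
#' are merged by gap projection.
#'
#' @param seqs named character vector (>= 2 non-empty sequences).
#' @param gap_open,gap_ext affine gap penalties.
#' @return list: `aln` (character matrix, rows = species, columns over
#'   `A,C,G,T,N,-`), `species`, `classes` (per column: invariant, SNP,
#'   indel).
#' @export
align_region <- function(seqs, gap_open = 10, gap_ext = 2) {
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning("dropping species with empty region: ",
            paste(names(seqs)[empty], collapse = ", "))
    seqs <- seqs[!empty]
  }
  if (length(seqs) < 2L) stop("fewer than 2 non-empty sequences to align")
  species <- names(seqs)

  if (length(unique(seqs)) == 1L) {
    m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
    rownames(m) <- species
    return(structure(list(aln = m, species = species,
                          classes = rep("invariant", ncol(m))),
                     class = "aligned_panel"))
  }

  dm <- utils::adist(seqs)
  center_i <- which.min(rowSums(dm))
  center <- seqs[[center_i]]
  Lc <- nchar(center)
  others <- setdiff(seq_along(seqs), center_i)

  sub_mat <- Biostrings::nucleotideSubstitutionMatrix(match = 2, mismatch = -1,
                                                      baseOnly = FALSE)
  projs <- list()
  for (oi in others) {
    pa <- Biostrings::pairwiseAlignment(center, seqs[[oi]], type = "global",
                                        substitutionMatrix = sub_mat,
                                        gapOpening = gap_open,
                                        gapExtension = gap_ext)
    projs[[as.character(oi)]] <- project_alignment(
      as.character(Biostrings::alignedPattern(pa)),
      as.character(Biostrings::alignedSubject(pa)), Lc)
  }
  max_ins <- integer(Lc + 1L)
  for (p in projs) max_ins <- pmax(max_ins, lengths(p$ins))

  build_row <- function(at, ins) {
    parts <- character(0)
    for (slot in seq_len(Lc + 1L)) {
      block <- ins[[slot]]
      pad <- max_ins[slot] - length(block)
      parts <- c(parts, block, rep("-", pad),
                 if (slot <= Lc) at[slot])
    }
    parts
  }
  rows <- vector("list", length(seqs))
  names(rows) <- species
  rows[[center_i]] <- build_row(strsplit(center, "", fixed = TRUE)[[1]],
                                vector("list", Lc + 1L))
  for (oi in others) {
    p <- projs[[as.character(oi)]]
    rows[[oi]] <- build_row(p$at, p$ins)
  }
  m <- do.call(rbind, rows)
  rownames(m) <- species
  structure(list(aln = m, species = species, classes = column_classes(m)),
            class = "aligned_panel")
}

column_classes <- function(m) {
  vapply(seq_len(ncol(m)), function(j) {
    col <- m[, j]
    if (any(col == "-")) return("indel")
    if (length(unique(col[col != "N"])) > 1L) "SNP" else "invariant"
  }, "")
}

#' Kimura 2-parameter distance between two aligned rows
#'
#' Sites where either row carries a gap or `N` are excluded pairwise
#' (distmat-style pairwise deletion). With transition fraction P and
#' transversion fraction Q over the included sites,
#' `d = -1/2 * ln((1 - 2P - Q) * sqrt(1 - 2Q))`; `NA` (undefined) when the
#' logarithm argument is non-positive or no sites remain.
#'
#' @param x,y equal-length aligned sequences (strings or char vectors).
#' @return distance, or `NA_real_` when undefined.
#' @export
k2p <- function(x, y) {
  if (is.character(x) && length(x) == 1L) x <- strsplit(x, "", fixed = TRUE)[[1]]
  if (is.character(y) && length(y) == 1L) y <- strsplit(y, "", fixed = TRUE)[[1]]
  stopifnot(length(x) == length(y))
  ok <- x %in% c("A", "C", "G", "T") & y %in% c("A", "C", "G", "T")
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n == 0L) return(NA_real_)
  diff <- x != y
  purine <- c("A", "G")
  transition <- diff & ((x %in% purine) == (y %in% purine))
  P <- sum(transition) / n
  Q <- sum(diff & !transition) / n
  arg1 <- 1 - 2 * P - Q
  arg2 <- 1 - 2 * Q
  if (arg1 <= 0 || arg2 <= 0) return(NA_real_)
  -0.5 * log(arg1 * sqrt(arg2))
}

#' Pairwise K2p matrix for an aligned panel
#' @param panel an `aligned_panel` from [align_region()].
#' @return symmetric matrix with zero diagonal; `NA` marks undefined pairs.
#' @export
k2p_matrix <- function(panel) {
  m <- panel$aln
  n <- nrow(m)
  out <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  if (n > 1L) for (i in 1:(n - 1L)) for (j in (i + 1L):n) {
    d <- k2p(m[i, ], m[j, ])
    out[i, j] <- out[j, i] <- d
  }
  out
}

#' Rank IGS regions by mean pairwise K2p distance
#'
#' @param panels named list of `aligned_panel` objects.
#' @return data.frame sorted by descending mean K2p: region, n_species,
#'   mean_k2p, median_k2p, max_k2p, frac_undefined, flag. Regions whose
#'   pairs are mostly undefined rank last and are flagged.
#' @export
rank_regions <- function(panels) {
  stopifnot(length(panels) >= 1L)
  rows <- lapply(names(panels), function(rg) {
    km <- k2p_matrix(panels[[rg]])
    v <- km[upper.tri(km)]
    def <- v[!is.na(v)]
    data.frame(region = rg, n_species = nrow(km),
               mean_k2p = if (length(def)) mean(def) else NA_real_,
               median_k2p = if (length(def)) stats::median(def) else NA_real_,
               max_k2p = if (length(def)) max(def) else NA_real_,
               frac_undefined = if (length(v)) mean(is.na(v)) else 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flag <- ifelse(out$frac_undefined > 0.5, "UNDEFINED_DOMINATED", "")
  dominated <- out$flag != ""
  out <- rbind(out[!dominated, , drop = FALSE][order(-out$mean_k2p[!dominated]), ,
                                               drop = FALSE],
               out[dominated, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Call variant sites in an aligned panel
#'
#' SNP site: a gap-free column with >= 2 observed bases. Indel site: a
#' maximal run of adjacent columns sharing an identical gap pattern,
#' collapsed to one event (columns mixing gaps and base variation are part
#' of the indel event). Alleles are per-species states: single bases for
#' SNPs, the spanned subsequence (with `-`) for indels.
#'
#' @param panel an `aligned_panel`.
#' @param region optional region label carried into the output.
#' @return data.frame: region, column (first column of the site), type
#'   (`SNP`/`indel`), and an `alleles` list-column of named character
#'   vectors.
#' @export
call_variant_sites <- function(panel, region = NA_character_) {
  m <- panel$aln
  nc <- ncol(m)
  gap_pattern <- vapply(seq_len(nc), function(j)
    paste(as.integer(m[, j] == "-"), collapse = ""), "")
  has_gap <- grepl("1", gap_pattern, fixed = TRUE)

  sites <- list()
  # SNP columns
  for (j in which(!has_gap)) {
    col <- m[, j]
    if (length(unique(col[col != "N"])) >= 2L)
      sites[[length(sites) + 1L]] <- list(column = j, type = "SNP",
                                          alleles = stats::setNames(col, rownames(m)))
  }
  # indel events: maximal runs of identical gap patterns
  j <- 1L
  while (j <= nc) {
    if (!has_gap[j]) { j <- j + 1L; next }
    j2 <- j
    while (j2 < nc && has_gap[j2 + 1L] && gap_pattern[j2 + 1L] == gap_pattern[j])
      j2 <- j2 + 1L
    alleles <- apply(m[, j:j2, drop = FALSE], 1L, paste, collapse = "")
    sites[[length(sites) + 1L]] <- list(column = j, type = "indel",
                                        alleles = stats::setNames(alleles, rownames(m)))
    j <- j2 + 1L
  }
  if (length(sites) == 0L)
    return(data.frame(region = character(), column = integer(),
                      type = character(),
                      alleles = I(list()), stringsAsFactors = FALSE))
  out <- data.frame(region = region,
                    column = vapply(sites, `[[`, 1L, "column"),
                    type = vapply(sites, `[[`, "", "type"),
                    stringsAsFactors = FALSE)
  out$alleles <- I(lapply(sites, `[[`, "alleles"))
  out[order(out$column), , drop = FALSE]
}

#' Select a diagnostic site set that discriminates all species pairs
#'
#' Greedy set cover over unordered species pairs: repeatedly add the
#' variant site (from the top `max_regions` ranked regions) that
#' discriminates the most not-yet-discriminated pairs; ties prefer the
#' earlier-ranked region, then the smaller column index. A site
#' discriminates a pair when both alleles are defined and differ
#' (undefined/missing states never discriminate). Errors, listing the
#' indistinguishable pairs, if full discrimination is impossible.
#'
#' @param panels named list of `aligned_panel` objects.
#' @param max_regions restrict to the top-ranked regions (default 2).
#' @param ranking optional precomputed [rank_regions()] output.
#' @return list: `sites` (selected rows, with region/column/type/alleles),
#'   `n_sites`, `pairs_total`, `coverage` (data.frame pair -> first
#'   covering site).
#' @export
select_diagnostic_sites <- function(panels, max_regions = 2L, ranking = NULL) {
  if (is.null(ranking)) ranking <- rank_regions(panels)
  top <- ranking$region[seq_len(min(max_regions, nrow(ranking)))]
  species <- Reduce(intersect, lapply(panels[top], function(p) p$species))
  if (length(species) < 2L) stop("fewer than 2 species common to all panels")
  species <- sort(species)

  site_tabs <- list()
  for (ri in seq_along(top)) {
    st <- call_variant_sites(panels[[top[ri]]], region = top[ri])
    if (nrow(st)) { st$region_rank <- ri; site_tabs[[length(site_tabs) + 1L]] <- st }
  }
  sites <- if (length(site_tabs)) do.call(rbind, site_tabs) else NULL
  prs <- utils::combn(species, 2L)
  n_pairs <- ncol(prs)
  if (is.null(sites) || nrow(sites) == 0L)
    stop("no variant sites available; indistinguishable pairs: ",
         paste(apply(prs, 2L, paste, collapse = "/"), collapse = ", "))

  discriminates <- function(al, s1, s2) {
    a1 <- al[[s1]]; a2 <- al[[s2]]
    !is.null(a1) && !is.null(a2) && !is.na(a1) && !is.na(a2) &&
      !(a1 == "N") && !(a2 == "N") && a1 != a2
  }
  cover <- matrix(FALSE, nrow(sites), n_pairs)
  for (i in seq_len(nrow(sites))) {
    al <- sites$alleles[[i]]
    cover[i, ] <- vapply(seq_len(n_pairs), function(p)
      discriminates(al, prs[1, p], prs[2, p]), TRUE)
  }
  ord <- order(sites$region_rank, sites$column)
  covered <- rep(FALSE, n_pairs)
  chosen <- integer(0)
  first_cover <- rep(NA_integer_, n_pairs)
  while (!all(covered)) {
    gain <- rowSums(cover[, !covered, drop = FALSE])
    gain[chosen] <- -1L
    if (max(gain) <= 0L) {
      left <- apply(prs[, !covered, drop = FALSE], 2L, paste, collapse = "/")
      stop("complete discrimination impossible; indistinguishable pairs: ",
           paste(left, collapse = ", "))
    }
    best <- ord[which(gain[ord] == max(gain))[1L]]
    chosen <- c(chosen, best)
    newly <- cover[best, ] & !covered
    first_cover[newly] <- best
    covered <- covered | cover[best, ]
  }
  coverage <- data.frame(species1 = prs[1, ], species2 = prs[2, ],
                         site_region = sites$region[first_cover],
                         site_column = sites$column[first_cover],
                         stringsAsFactors = FALSE)
  list(sites = sites[chosen, , drop = FALSE], n_sites = length(chosen),
       pairs_total = n_pairs, species = species, coverage = coverage)
}

## exhaustive minimal cover size (small panels only); used as a test oracle
## bound, not by the greedy selector. Identical and dominated coverage
## patterns are pruned first (neither changes the minimum), which keeps the
## combinatorial search tiny.
min_cover_size <- function(cover) {
  cover <- unique(cover)
  cover <- cover[rowSums(cover) > 0L, , drop = FALSE]
  n <- nrow(cover)
  if (n == 0L) return(Inf)
  dominated <- vapply(seq_len(n), function(i)
    any(vapply(seq_len(n), function(j)
      j != i && all(cover[i, ] <= cover[j, ]) && any(cover[j, ] > cover[i, ]),
      TRUE)), TRUE)
  cover <- cover[!dominated, , drop = FALSE]
  n <- nrow(cover)
  for (sz in seq_len(n)) {
    if (choose(n, sz) > 2e5) break   # defensive cap; callers use tiny panels
    combos <- utils::combn(n, sz, simplify = FALSE)
    for (cb in combos)
      if (all(colSums(cover[cb, , drop = FALSE]) > 0L)) return(sz)
  }
  Inf
}
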