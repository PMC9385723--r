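# Synthetic-data generator: every input class the pipeline consumes, with
# planted ground truth. One integer seed determines every output. Planted
# elements never overlap and are "sealed": the bases flanking each planted
# copy are forced to break any chance extension, so planted coordinates are
# exactly the maximal ones a detector should report.

#' Simulation configuration
#'
#' @param seed integer; drives all randomness of the run.
#' @param genome_length circle length in bp.
#' @param repeat_spec list of `list(arm_length, orientation)` entries
#'   (`orientation` one of `"forward"`, `"inverted"`); each plants a
#'   2-copy repeat family.
#' @param ssr_spec list of `list(motif, copies)` entries.
#' @param gc background G+C fraction.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, genome_length = 30000L,
                       repeat_spec = list(), ssr_spec = list(), gc = 0.5) {
  structure(list(seed = as.integer(seed), genome_length = as.integer(genome_length),
                 repeat_spec = repeat_spec, ssr_spec = ssr_spec, gc = gc),
            class = "sim_config")
}

## choose non-overlapping intervals of the given lengths inside [margin,
## L - margin], separated by >= gap; rejection sampling. Row i of the
## result is the interval for lens[i].
place_intervals <- function(L, lens, gap = 20L, margin = 50L, tries = 5000L) {
  if (sum(lens) + (length(lens) + 1L) * (gap + margin) > L)
    stop("infeasible packing: planted elements exceed genome length")
  n <- length(lens)
  for (t in seq_len(tries)) {
    starts <- sort(sample.int(L - margin * 2L, n) + margin)
    slot <- sample.int(n)                  # element i takes slot[i]
    st <- starts[slot]
    en <- st + lens - 1L
    o <- order(st)
    if (all(en <= L - margin) &&
        (n < 2L || all(st[o][-1L] - en[o][-n] > gap)))
      return(data.frame(start = st, end = en, len = lens))
  }
  stop("infeasible packing: could not place planted elements")
}

## force ch[i] to differ from `avoid` (a base); deterministic given RNG state
reseal_base <- function(ch, i, avoid) {
  if (i < 1L || i > length(ch)) return(ch)
  if (ch[i] %in% avoid) ch[i] <- sample(setdiff(c("A", "C", "G", "T"), avoid), 1L)
  ch
}

#' Generate a circular genome with planted repeat families and SSRs
#'
#' Background is uniform random (optionally GC-skewed); each repeat family
#' plants two exact copies (direct or inverted); SSR runs are perfect.
#' Flanking bases are sealed so each planted element is exactly maximal.
#'
#' @param cfg a [sim_config()].
#' @return `list(genome, truth)`; `truth$repeats` and `truth$ssrs` carry the
#'   planted coordinates (1-based inclusive).
#' @export
make_circular_genome <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$genome_length
  ch <- strsplit(random_seq(L, cfg$gc), "", fixed = TRUE)[[1]]

  lens <- integer(0)
  kinds <- character(0)
  for (r in cfg$repeat_spec) { lens <- c(lens, r$arm_length, r$arm_length)
                               kinds <- c(kinds, "rep", "rep") }
  for (s in cfg$ssr_spec) { lens <- c(lens, nchar(s$motif) * s$copies)
                            kinds <- c(kinds, "ssr") }

  rep_truth <- ssr_truth <- NULL
  if (length(lens)) {
    iv <- place_intervals(L, lens)
    # hand intervals out in the order elements were declared
    take <- order(iv$len)  # not used; assign sequentially by matching length
    used <- rep(FALSE, nrow(iv))
    pick <- function(len) {
      i <- which(!used & iv$len == len)[1]
      used[i] <<- TRUE
      c(iv$start[i], iv$end[i])
    }
    ri <- 0L
    rep_rows <- list()
    for (r in cfg$repeat_spec) {
      ri <- ri + 1L
      arm <- strsplit(random_seq(r$arm_length, cfg$gc), "", fixed = TRUE)[[1]]
      p1 <- pick(r$arm_length); p2 <- pick(r$arm_length)
      if (p1[1] > p2[1]) { tmp <- p1; p1 <- p2; p2 <- tmp }
      ch[p1[1]:p1[2]] <- arm
      if (identical(r$orientation, "inverted")) {
        ch[p2[1]:p2[2]] <- strsplit(revcomp(paste(arm, collapse = "")), "")[[1]]
        # seal: right of arm1 vs left of arm2, left of arm1 vs right of arm2
        comp <- c(A = "T", C = "G", G = "C", T = "A")
        ch <- reseal_base(ch, p1[2] + 1L, comp[[ch[p2[1] - 1L]]])
        ch <- reseal_base(ch, p1[1] - 1L, comp[[ch[p2[2] + 1L]]])
      } else {
        ch[p2[1]:p2[2]] <- arm
        ch <- reseal_base(ch, p1[1] - 1L, ch[p2[1] - 1L])
        ch <- reseal_base(ch, p1[2] + 1L, ch[p2[2] + 1L])
      }
      rep_rows[[ri]] <- data.frame(
        family = sprintf("r%02d", ri), arm_length = r$arm_length,
        orientation = if (identical(r$orientation, "inverted")) "inverted" else "forward",
        start1 = p1[1], end1 = p1[2], start2 = p2[1], end2 = p2[2],
        stringsAsFactors = FALSE)
    }
    if (length(rep_rows)) rep_truth <- do.call(rbind, rep_rows)

    ssr_rows <- list()
    for (s in cfg$ssr_spec) {
      p <- nchar(s$motif)
      run_len <- p * s$copies
      pos <- pick(run_len)
      ch[pos[1]:pos[2]] <- strsplit(strrep(toupper(s$motif), s$copies), "")[[1]]
      # seal so the run is exactly maximal under period p
      ch <- reseal_base(ch, pos[1] - 1L, ch[pos[1] - 1L + p])
      ch <- reseal_base(ch, pos[2] + 1L, ch[pos[2] + 1L - p])
      ssr_rows[[length(ssr_rows) + 1L]] <- data.frame(
        motif = toupper(s$motif), period = p, copies = s$copies,
        start = pos[1], end = pos[2], stringsAsFactors = FALSE)
    }
    if (length(ssr_rows)) ssr_truth <- do.call(rbind, ssr_rows)
  }

  g <- genome(sprintf("sim%d", cfg$seed), paste(ch, collapse = ""), circular = TRUE)
  list(genome = g, truth = list(repeats = rep_truth, ssrs = ssr_truth, config = cfg))
}

#' Generate a quadripartite plastome-like circle (LSC + IRa + SSC + IRb)
#'
#' `IRb = revcomp(IRa)`; total length `lsc + 2*ir + ssc`. IR boundaries are
#' sealed to be exactly maximal. Optionally plants gene features (for IGS
#' work) via [plant_genes()].
#'
#' @param lsc,ir,ssc region lengths in bp (all > 0).
#' @param seed integer seed.
#' @param n_genes number of gene features to plant (0 = none).
#' @return `list(genome, truth)`; `truth$regions` holds the planted
#'   intervals, `truth$genes` the planted gene table when requested.
#' @export
make_quadripartite_plastome <- function(lsc, ir, ssc, seed = 1L, n_genes = 0L) {
  stopifnot(lsc > 0, ir > 0, ssc > 0)
  set.seed(seed)
  L <- lsc + 2L * ir + ssc
  ira <- random_seq(ir)
  ch <- strsplit(paste0(random_seq(lsc), ira, random_seq(ssc), revcomp(ira)),
                 "", fixed = TRUE)[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  # seal IR maximality across both junction pairs (positions are circular:
  # the base right of IRb is position 1)
  ch <- reseal_base(ch, lsc, comp[[ch[1L]]])
  ch <- reseal_base(ch, lsc + ir + 1L, comp[[ch[lsc + ir + ssc]]])
  regions <- list(LSC = c(1L, lsc), IRa = c(lsc + 1L, lsc + ir),
                  SSC = c(lsc + ir + 1L, lsc + ir + ssc),
                  IRb = c(lsc + ir + ssc + 1L, L))
  g <- genome(sprintf("cp_sim%d", seed), paste(ch, collapse = ""),
              circular = TRUE, regions = regions)
  truth <- list(regions = regions, ir_length = ir)
  if (n_genes > 0L) {
    pg <- plant_genes(g, n_genes, seed = seed + 1L)
    g <- pg$genome
    truth$genes <- pg$truth
  }
  list(genome = g, truth = truth)
}

## plastid-flavoured gene names used for synthetic annotations
.gene_name_pool <- c("ndhG", "ndhI", "ccsA", "ndhD", "rpl32", "trnL-UAG",
                     "psbA", "matK", "rbcL", "atpB", "rpoC1", "trnK-UUU",
                     "ndhF", "rps16", "petA", "psaB", "trnH-GUG", "ycf3",
                     "rpl16", "clpP", "atpF", "rpoB", "psbD", "cemA",
                     "ndhA", "rps4", "trnV-UAC", "petB", "rpl2", "rps12")

#' Plant non-overlapping gene features on a genome
#'
#' Genes are placed around the circle with random intergenic gaps, random
#' strands, and realistic plastid gene names (tRNA names keep their
#' anticodon suffix). The gaps between consecutive genes are the ground
#' truth for IGS extraction.
#'
#' @param g a circular [genome()].
#' @param n_genes number of genes (<= 30).
#' @param gene_len gene length in bp.
#' @param seed integer seed.
#' @return `list(genome, truth)` where truth is the gene table.
#' @export
plant_genes <- function(g, n_genes, gene_len = 300L, seed = 1L) {
  set.seed(seed)
  stopifnot(n_genes >= 2L, n_genes <= length(.gene_name_pool))
  L <- genome_length(g)
  stopifnot(n_genes * (gene_len + 40L) < L)
  # evenly spaced anchors with jitter keeps genes orderly and non-wrapping
  anchors <- floor(seq(1L, L - gene_len - 20L, length.out = n_genes + 1L))[1:n_genes]
  jitter <- sample.int(20L, n_genes, replace = TRUE)
  starts <- anchors + jitter
  names <- .gene_name_pool[seq_len(n_genes)]
  feats <- data.frame(name = names, kind = ifelse(grepl("^trn", names), "tRNA", "CDS"),
                      strand = sample(c("+", "-"), n_genes, replace = TRUE),
                      start = starts, end = starts + gene_len - 1L,
                      part = 1L, stringsAsFactors = FALSE)
  g$features <- validate_features(feats, L)
  list(genome = g, truth = feats)
}

#' Collapse planted exact repeats into a unitig graph
#'
#' Detects maximal exact 2-copy repeats (direct and inverted) of at least
#' `min_repeat` bp, collapses each family into a single segment, and cuts
#' the remaining circle into flank segments. Links carry orientation so
#' every traversal of the planted genome is a walk in the graph; all
#' overlaps are 0M. Collapsed segments carry coverage `copies * base_cov`.
#'
#' @param g a circular [genome()].
#' @param min_repeat minimal repeat arm length to collapse, bp.
#' @param base_cov single-copy coverage depth tag.
#' @return `list(graph, truth)`; `truth$path` is the walk spelling the
#'   genome, `truth$genome` the input sequence.
#' @export
genome_to_unitig_graph <- function(g, min_repeat = 500L, base_cov = 60) {
  stopifnot(g$circular)
  seq <- g$seq
  fw <- exact_forward_pairs(seq, min_repeat)
  pal <- exact_palindromic_pairs(seq, min_repeat)

  occs <- NULL
  fam_seq <- list()
  add_fam <- function(id, s1, e1, s2, e2, inverted) {
    fam_seq[[id]] <<- substr(seq, s1, e1)
    rbind(data.frame(fam = id, start = s1, end = e1, orient = "+"),
          data.frame(fam = id, start = s2, end = e2,
                     orient = if (inverted) "-" else "+"))
  }
  fi <- 0L
  rows <- list()
  if (nrow(fw)) for (i in seq_len(nrow(fw))) {
    fi <- fi + 1L
    rows[[fi]] <- add_fam(sprintf("r%02d", fi), fw$s1[i], fw$e1[i],
                          fw$s2[i], fw$e2[i], FALSE)
  }
  if (nrow(pal)) for (i in seq_len(nrow(pal))) {
    fi <- fi + 1L
    rows[[fi]] <- add_fam(sprintf("r%02d", fi), pal$s1[i], pal$e1[i],
                          pal$s2[i], pal$e2[i], TRUE)
  }
  if (length(rows)) occs <- do.call(rbind, rows)

  if (is.null(occs) || nrow(occs) == 0L) {
    gr <- unitig_graph(list(u1 = list(seq = seq, cov = base_cov)),
                       data.frame(from = "u1", from_orient = "+", to = "u1",
                                  to_orient = "+", overlap = 0L))
    return(list(graph = gr,
                truth = list(path = data.frame(segment = "u1", orient = "+"),
                             genome = g)))
  }

  occs <- occs[order(occs$start), , drop = FALSE]
  if (any(occs$start[-1L] <= occs$end[-nrow(occs)]))
    stop("overlapping repeat occurrences are not supported")

  L <- nchar(seq)
  m <- nrow(occs)
  segments <- lapply(fam_seq, function(s) list(seq = s, cov = 2 * base_cov))
  links <- list()
  path <- list()
  for (i in seq_len(m)) {
    nxt <- if (i == m) 1L else i + 1L
    fl_id <- sprintf("f%02d", i)
    fl_start <- occs$end[i] + 1L
    fl_end <- occs$start[nxt] - 1L
    fl_seq <- if (i == m)
      paste0(substr(seq, fl_start, L), substr(seq, 1L, max(fl_end, 0L)))
    else substr(seq, fl_start, fl_end)
    path[[length(path) + 1L]] <- data.frame(segment = occs$fam[i],
                                            orient = occs$orient[i])
    if (nchar(fl_seq) > 0L) {
      segments[[fl_id]] <- list(seq = fl_seq, cov = base_cov)
      links[[length(links) + 1L]] <- data.frame(
        from = occs$fam[i], from_orient = occs$orient[i],
        to = fl_id, to_orient = "+", overlap = 0L)
      links[[length(links) + 1L]] <- data.frame(
        from = fl_id, from_orient = "+",
        to = occs$fam[nxt], to_orient = occs$orient[nxt], overlap = 0L)
      path[[length(path) + 1L]] <- data.frame(segment = fl_id, orient = "+")
    } else {
      links[[length(links) + 1L]] <- data.frame(
        from = occs$fam[i], from_orient = occs$orient[i],
        to = occs$fam[nxt], to_orient = occs$orient[nxt], overlap = 0L)
    }
  }
  gr <- unitig_graph(segments, do.call(rbind, links))
  list(graph = gr, truth = list(path = do.call(rbind, path), genome = g,
                                occurrences = occs))
}

#' Simulate long reads from a circular genome
#'
#' Start positions are uniform around the circle (reads may wrap the
#' origin), lengths are normal with the given mean/sd (clamped), strand is
#' random, and substitution errors are applied at `error_rate`.
#'
#' @param g a circular [genome()].
#' @param n_reads number of reads.
#' @param mean_len,sd_len read length distribution (bp).
#' @param error_rate per-base substitution rate in `[0, 0.2]`.
#' @param seed integer seed.
#' @return `list(reads, truth)`; reads are `list(id, seq, qual = NULL)`,
#'   truth records origin (`start`, `len`, `strand`).
#' @export
simulate_long_reads <- function(g, n_reads = 100L, mean_len = 6000L,
                                sd_len = 1000L, error_rate = 0,
                                seed = 1L) {
  stopifnot(g$circular, error_rate >= 0, error_rate <= 0.2)
  set.seed(seed)
  L <- genome_length(g)
  if (n_reads == 0L)
    return(list(reads = list(),
                truth = data.frame(id = character(), start = integer(),
                                   len = integer(), strand = character())))
  dbl <- paste0(g$seq, g$seq)
  starts <- sample.int(L, n_reads, replace = TRUE)
  lens <- pmin(pmax(round(stats::rnorm(n_reads, mean_len, sd_len)), 100L), L)
  strands <- sample(c("+", "-"), n_reads, replace = TRUE)
  reads <- vector("list", n_reads)
  for (i in seq_len(n_reads)) {
    s <- substr(dbl, starts[i], starts[i] + lens[i] - 1L)
    if (error_rate > 0) {
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      hit <- which(stats::runif(length(ch)) < error_rate)
      for (j in hit) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
      s <- paste(ch, collapse = "")
    }
    if (strands[i] == "-") s <- revcomp(s)
    reads[[i]] <- list(id = sprintf("read%04d", i), seq = s, qual = NULL)
  }
  list(reads = reads,
       truth = data.frame(id = vapply(reads, `[[`, "", "id"), start = starts,
                          len = lens, strand = strands,
                          stringsAsFactors = FALSE))
}

#' Derive a species panel from an annotated ancestor
#'
#' Mutations (substitutions and short indels) are placed only in intergenic
#' spacers; each derived species additionally receives one private planted
#' variant (SNP for odd species indices, a short deletion for even ones) at
#' a reserved IGS position no other species touches, so every species is
#' discriminable by construction.
#'
#' @param ancestor an annotated circular [genome()] (features required).
#' @param n_species number of derived species (>= 2).
#' @param igs_mutation_rate per-site substitution rate within IGS.
#' @param indel_rate per-site indel initiation rate within IGS.
#' @param seed integer seed.
#' @return `list(panel, truth)`; panel is a named list of genomes with
#'   shifted feature coordinates; truth lists all planted variants with
#'   ancestor coordinates and the owning species for private ones.
#' @export
make_species_panel <- function(ancestor, n_species, igs_mutation_rate = 0.005,
                               indel_rate = 0.001, seed = 1L) {
  if (n_species < 2L) stop("n_species must be >= 2")
  stopifnot(!is.null(ancestor$features))
  set.seed(seed)
  igs <- extract_igs(ancestor)
  igs <- igs[igs$length > 0L & igs$start <= igs$end, , drop = FALSE] # skip wrap spacer
  igs_pos <- unlist(mapply(function(s, e) s:e, igs$start, igs$end,
                           SIMPLIFY = FALSE))
  # reserved private-variant positions, well separated
  stopifnot(length(igs_pos) > 40L * n_species)
  reserved <- sort(sample(igs_pos[seq(20L, length(igs_pos) - 20L, by = 25L)],
                          n_species))
  free_pos <- setdiff(igs_pos, unlist(lapply(reserved, function(p) (p - 8L):(p + 8L))))

  anc_ch <- strsplit(ancestor$seq, "", fixed = TRUE)[[1]]
  panel <- list()
  truth_rows <- list()
  for (i in seq_len(n_species)) {
    sp <- sprintf("sp%02d", i)
    edits <- list()
    subs <- free_pos[stats::runif(length(free_pos)) < igs_mutation_rate]
    for (p in subs)
      edits[[length(edits) + 1L]] <- list(pos = p, type = "sub",
                                          alt = sample(setdiff(c("A","C","G","T"),
                                                               anc_ch[p]), 1L))
    inds <- free_pos[stats::runif(length(free_pos)) < indel_rate]
    for (p in inds) {
      w <- sample(1:3, 1L)
      if (stats::runif(1) < 0.5)
        edits[[length(edits) + 1L]] <- list(pos = p, type = "del", len = w)
      else
        edits[[length(edits) + 1L]] <- list(pos = p, type = "ins",
                                            alt = random_seq(w))
    }
    # private planted variant at this species' reserved position
    rp <- reserved[i]
    if (i %% 2L == 1L) {
      priv <- list(pos = rp, type = "sub",
                   alt = sample(setdiff(c("A","C","G","T"), anc_ch[rp]), 1L))
      ptype <- "SNP"
    } else {
      priv <- list(pos = rp, type = "del", len = 2L)
      ptype <- "indel"
    }
    edits[[length(edits) + 1L]] <- priv
    truth_rows[[length(truth_rows) + 1L]] <-
      data.frame(species = sp, pos_ancestor = rp, type = ptype,
                 region = igs$name[findInterval(rp, igs$start)],
                 private = TRUE, stringsAsFactors = FALSE)

    panel[[sp]] <- apply_edits(ancestor, edits, id = sp)
  }
  list(panel = panel,
       truth = list(private_variants = do.call(rbind, truth_rows),
                    igs = igs,
                    rates = c(sub = igs_mutation_rate, indel = indel_rate)))
}

## apply substitutions/insertions/deletions (ancestor coordinates) to a
## genome, shifting feature coordinates accordingly
apply_edits <- function(g, edits, id = g$id) {
  if (length(edits) == 0L)
    return(genome(id, g$seq, circular = g$circular, features = g$features))
  pos <- vapply(edits, `[[`, 1, "pos")
  edits <- edits[order(pos, decreasing = TRUE)]
  ch <- strsplit(g$seq, "", fixed = TRUE)[[1]]
  feats <- g$features
  for (e in edits) {
    if (e$type == "sub") {
      ch[e$pos] <- e$alt
    } else if (e$type == "del") {
      ch <- ch[-(e$pos:(e$pos + e$len - 1L))]
      if (!is.null(feats)) {
        feats$start <- ifelse(feats$start > e$pos, feats$start - e$len, feats$start)
        feats$end <- ifelse(feats$end > e$pos, feats$end - e$len, feats$end)
      }
    } else if (e$type == "ins") {
      ins <- strsplit(e$alt, "", fixed = TRUE)[[1]]
      ch <- append(ch, ins, after = e$pos)
      if (!is.null(feats)) {
        w <- length(ins)
        feats$start <- ifelse(feats$start > e$pos, feats$start + w, feats$start)
        feats$end <- ifelse(feats$end > e$pos, feats$end + w, feats$end)
      }
    }
  }
  genome(id, paste(ch, collapse = ""), circular = g$circular, features = feats)
}

#' Generate an organelle genome pair with planted shared fragments
#'
#' Two unrelated random circles share planted fragments at recorded
#' coordinates. An outgroup pair is built so that the `vertical` subset of
#' fragments is present in both outgroup genomes while `horizontal`
#' fragments occur only in the outgroup plastome, mirroring the
#' presence/absence logic used to call plastid-to-mitochondrion transfer.
#'
#' @param n_fragments number of shared fragments.
#' @param frag_len fragment length(s) in bp (recycled), each >= 30.
#' @param identity per-fragment plastome-vs-mitogenome identity fraction.
#' @param n_horizontal how many fragments are horizontal (absent from the
#'   outgroup mitogenome); the rest are vertical.
#' @param cp_len,mt_len genome lengths.
#' @param outgroup_identity identity of outgroup copies vs the fragment.
#' @param seed integer seed.
#' @return `list(plastome, mitogenome, outgroup_plastome, outgroup_mito,
#'   truth)`.
#' @export
make_organelle_pair <- function(n_fragments = 5L, frag_len = 500L,
                                identity = 1.0, n_horizontal = 1L,
                                cp_len = 40000L, mt_len = 60000L,
                                outgroup_identity = 0.98, seed = 1L) {
  stopifnot(all(frag_len >= 30L))
  n_horizontal <- min(n_horizontal, n_fragments)
  set.seed(seed)
  frag_len <- rep_len(frag_len, max(n_fragments, 1L))
  identity <- rep_len(identity, max(n_fragments, 1L))

  cp <- strsplit(random_seq(cp_len), "", fixed = TRUE)[[1]]
  mt <- strsplit(random_seq(mt_len), "", fixed = TRUE)[[1]]
  ocp <- strsplit(random_seq(cp_len), "", fixed = TRUE)[[1]]
  omt <- strsplit(random_seq(mt_len), "", fixed = TRUE)[[1]]

  truth <- NULL
  if (n_fragments > 0L) {
    cp_iv <- place_intervals(cp_len, frag_len)
    mt_iv <- place_intervals(mt_len, frag_len)
    ocp_iv <- place_intervals(cp_len, frag_len)
    omt_iv <- place_intervals(mt_len, frag_len)
    origin <- sample(c(rep("horizontal", n_horizontal),
                       rep("vertical", n_fragments - n_horizontal)))
    rows <- list()
    for (i in seq_len(n_fragments)) {
      fl <- frag_len[i]
      frag <- strsplit(random_seq(fl), "", fixed = TRUE)[[1]]
      cp[cp_iv$start[i]:cp_iv$end[i]] <- frag
      mt[mt_iv$start[i]:mt_iv$end[i]] <- mutate_copy(frag, identity[i])
      ocp[ocp_iv$start[i]:ocp_iv$end[i]] <- mutate_copy(frag, outgroup_identity)
      if (origin[i] == "vertical")
        omt[omt_iv$start[i]:omt_iv$end[i]] <- mutate_copy(frag, outgroup_identity)
      rows[[i]] <- data.frame(
        fragment = sprintf("P%02d", i), length = fl, identity = identity[i],
        cp_start = cp_iv$start[i], cp_end = cp_iv$end[i],
        mt_start = mt_iv$start[i], mt_end = mt_iv$end[i],
        origin = origin[i], stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
    truth <- truth[order(truth$mt_start), , drop = FALSE]
    rownames(truth) <- NULL
  }
  list(plastome = genome("cp_sim", paste(cp, collapse = ""), circular = TRUE),
       mitogenome = genome("mt_sim", paste(mt, collapse = ""), circular = TRUE),
       outgroup_plastome = genome("ocp_sim", paste(ocp, collapse = ""), circular = TRUE),
       outgroup_mito = genome("omt_sim", paste(omt, collapse = ""), circular = TRUE),
       truth = truth)
}

## substitute bases to bring a copy to the requested identity fraction
mutate_copy <- function(ch, identity) {
  n_mut <- round((1 - identity) * length(ch))
  if (n_mut == 0L) return(ch)
  at <- sample.int(length(ch), n_mut)
  for (j in at) ch[j] <- sample(setdiff(c("A", "C", "G", "T"), ch[j]), 1L)
  ch
}

#' Write a simulated dataset (FASTA + GFA + FASTQ + ground-truth TSV)
#'
#' @param cfg a [sim_config()].
#' @param out_dir output directory (created if needed).
#' @param min_repeat,n_reads,mean_len,error_rate forwarded to
#'   [genome_to_unitig_graph()] and [simulate_long_reads()].
#' @return invisibly, the list of generated objects.
#' @export
write_simulated_dataset <- function(cfg, out_dir, min_repeat = 500L,
                                    n_reads = 100L, mean_len = 6000L,
                                    error_rate = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_circular_genome(cfg)
  ug <- genome_to_unitig_graph(sim$genome, min_repeat = min_repeat)
  rd <- simulate_long_reads(sim$genome, n_reads = n_reads, mean_len = mean_len,
                            error_rate = error_rate, seed = cfg$seed + 1L)
  write_fasta(sim$genome, file.path(out_dir, "genome.fasta"))
  write_gfa(ug$graph, file.path(out_dir, "unitigs.gfa"))
  write_fastq(rd$reads, file.path(out_dir, "reads.fastq"))
  if (!is.null(sim$truth$repeats))
    write_tsv_report(sim$truth$repeats, file.path(out_dir, "truth_repeats.tsv"))
  if (!is.null(sim$truth$ssrs))
    write_tsv_report(sim$truth$ssrs, file.path(out_dir, "truth_ssrs.tsv"))
  write_tsv_report(rd$truth, file.path(out_dir, "truth_reads.tsv"))
  invisible(list(sim = sim, graph = ug, reads = rd))
}
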