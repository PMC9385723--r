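# Plastome <-> mitogenome homologous-fragment detection: exact k-mer
# seeding on both strands, ungapped X-drop extension, diagonal-band
# merging into fragments, binomial-free Karlin-Altschul significance, and
# outgroup-based origin classification.

## Karlin-Altschul lambda for a +match/-mismatch scheme at uniform base
## composition: solves 0.25*exp(lambda*match) + 0.75*exp(lambda*mismatch) = 1
karlin_lambda <- function(match = 2, mismatch = -3) {
  f <- function(l) 0.25 * exp(l * match) + 0.75 * exp(l * mismatch) - 1
  stats::uniroot(f, c(1e-6, 5))$root
}

## E = K * m * n * exp(-lambda * S); K fixed at 0.35 (documented constant
## for DNA scoring at uniform composition)
ka_evalue <- function(score, m, n, lambda, K = 0.35) {
  K * as.numeric(m) * as.numeric(n) * exp(-lambda * score)
}

## ungapped X-drop extension around an exact seed; chs are char vectors,
## pa/pb 1-based seed starts, k seed length. Returns the best-scoring
## extent and its match count.
xdrop_extend <- function(cha, chb, pa, pb, k, match = 2L, mismatch = -3L,
                         xdrop = 20L) {
  la <- length(cha); lb <- length(chb)
  # right of the seed
  sc <- 0L; best_r <- 0L; best_sc_r <- 0L; mat_r <- 0L; best_mat_r <- 0L
  x <- 0L
  while (TRUE) {
    i <- pa + k + x; j <- pb + k + x
    if (i > la || j > lb) break
    sc <- sc + (if (cha[i] == chb[j]) { mat_r <- mat_r + 1L; match } else mismatch)
    if (sc > best_sc_r) { best_sc_r <- sc; best_r <- x + 1L; best_mat_r <- mat_r }
    if (best_sc_r - sc > xdrop) break
    x <- x + 1L
  }
  # left of the seed
  sc <- 0L; best_l <- 0L; best_sc_l <- 0L; mat_l <- 0L; best_mat_l <- 0L
  x <- 0L
  while (TRUE) {
    i <- pa - 1L - x; j <- pb - 1L - x
    if (i < 1L || j < 1L) break
    sc <- sc + (if (cha[i] == chb[j]) { mat_l <- mat_l + 1L; match } else mismatch)
    if (sc > best_sc_l) { best_sc_l <- sc; best_l <- x + 1L; best_mat_l <- mat_l }
    if (best_sc_l - sc > xdrop) break
    x <- x + 1L
  }
  len <- best_l + k + best_r
  matches <- best_mat_l + k + best_mat_r
  list(astart = pa - best_l, aend = pa + k - 1L + best_r,
       bstart = pb - best_l, bend = pb + k - 1L + best_r,
       score = best_sc_l + match * k + best_sc_r, len = len, matches = matches)
}

## all ungapped local alignments between two strings (one strand);
## seeds already covered by an alignment on their diagonal are skipped
strand_alignments <- function(a, b, k, match, mismatch, xdrop) {
  A <- kmer_table(a, k)
  B <- kmer_table(b, k)
  m <- merge(A, B, by = "kmer", allow.cartesian = TRUE, suffixes = c("_a", "_b"))
  if (nrow(m) == 0L) return(NULL)
  m$diag <- m$pos_a - m$pos_b
  data.table::setorderv(m, c("diag", "pos_a"))
  cha <- strsplit(a, "", fixed = TRUE)[[1]]
  chb <- strsplit(b, "", fixed = TRUE)[[1]]
  out <- list()
  cur_diag <- NA_integer_
  covered_to <- -1L
  for (i in seq_len(nrow(m))) {
    d <- m$diag[i]
    if (is.na(cur_diag) || d != cur_diag) { cur_diag <- d; covered_to <- -1L }
    if (m$pos_a[i] + k - 1L <= covered_to) next
    al <- xdrop_extend(cha, chb, m$pos_a[i], m$pos_b[i], k, match, mismatch,
                       xdrop)
    covered_to <- al$aend
    out[[length(out) + 1L]] <- as.data.frame(al)
  }
  do.call(rbind, out)
}

## merge alignments into fragments: same strand, diagonals within
## band, intervals overlapping or abutting within merge_dist on both axes
merge_alignments <- function(al, merge_dist = 10L, band = 20L) {
  n <- nrow(al)
  if (n == 1L) { al$group <- 1L; return(al) }
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  al$diag <- al$astart - al$bstart
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (abs(al$diag[i] - al$diag[j]) > band) next
    gap_a <- max(al$astart[i], al$astart[j]) - min(al$aend[i], al$aend[j])
    gap_b <- max(al$bstart[i], al$bstart[j]) - min(al$bend[i], al$bend[j])
    if (gap_a <= merge_dist && gap_b <= merge_dist)
      parent[find(i)] <- find(j)
  }
  al$group <- vapply(seq_len(n), find, 1L)
  al
}

#' Find homologous fragments between two genomes
#'
#' Seed-and-extend local search: exact k-mer seeds on both strands,
#' ungapped X-drop extension, then merging of overlapping or abutting
#' alignments on compatible diagonals into fragments. Merged fragments are
#' re-scored by affine-gap pairwise alignment. Fragments above the
#' expectation-value cutoff are discarded; output is sorted by position on
#' `b` and labelled F1..Fn (in the pipeline `b` is the mitogenome, so
#' numbering follows mitogenome coordinates).
#'
#' @param a,b [genome()] objects or strings.
#' @param k seed length (>= 11).
#' @param match,mismatch,xdrop ungapped extension scoring.
#' @param evalue_cutoff significance cutoff (1e-5).
#' @param merge_dist merge gap tolerance, bp.
#' @param min_len discard fragments shorter than this (defaults to `k`).
#' @return data.frame: id, a_start, a_end, b_start, b_end, strand, length
#'   (b-side), identity (fraction), score, evalue.
#' @export
find_fragments <- function(a, b, k = 13L, match = 2L, mismatch = -3L,
                           xdrop = 20L, evalue_cutoff = 1e-5,
                           merge_dist = 10L, min_len = NULL) {
  stopifnot(k >= 11L)
  if (is.null(min_len)) min_len <- k
  sa <- if (inherits(a, "genome")) a$seq else toupper(a)
  sb <- if (inherits(b, "genome")) b$seq else toupper(b)
  la <- nchar(sa); lb <- nchar(sb)
  lambda <- karlin_lambda(match, mismatch)

  frag_rows <- list()
  for (strand in c("+", "-")) {
    sb_use <- if (strand == "+") sb else revcomp(sb)
    al <- strand_alignments(sa, sb_use, k, match, mismatch, xdrop)
    if (is.null(al) || nrow(al) == 0L) next
    al <- merge_alignments(al, merge_dist = merge_dist)
    for (gid in unique(al$group)) {
      gr <- al[al$group == gid, , drop = FALSE]
      a1 <- min(gr$astart); a2 <- max(gr$aend)
      b1 <- min(gr$bstart); b2 <- max(gr$bend)
      if (nrow(gr) == 1L) {
        score <- gr$score
        ident <- gr$matches / gr$len
      } else {
        pa <- Biostrings::pairwiseAlignment(
          substr(sa, a1, a2), substr(sb_use, b1, b2), type = "global",
          substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
            match = match, mismatch = mismatch, baseOnly = TRUE),
          gapOpening = 5, gapExtension = 2)
        score <- Biostrings::score(pa)
        ident <- Biostrings::nmatch(pa) / Biostrings::nchar(pa)
      }
      ev <- ka_evalue(score, la, lb, lambda)
      # map minus-strand coordinates back to b
      if (strand == "-") { tmp <- b1; b1 <- lb - b2 + 1L; b2 <- lb - tmp + 1L }
      frag_rows[[length(frag_rows) + 1L]] <- data.frame(
        a_start = a1, a_end = a2, b_start = b1, b_end = b2, strand = strand,
        length = b2 - b1 + 1L, identity = ident, score = as.numeric(score),
        evalue = ev, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(frag_rows)) do.call(rbind, frag_rows)
         else data.frame(a_start = integer(), a_end = integer(),
                         b_start = integer(), b_end = integer(),
                         strand = character(), length = integer(),
                         identity = numeric(), score = numeric(),
                         evalue = numeric(), stringsAsFactors = FALSE)
  out <- out[out$evalue <= evalue_cutoff & out$length >= min_len, ,
             drop = FALSE]
  out <- out[order(out$b_start, out$b_end), , drop = FALSE]
  if (nrow(out)) out <- cbind(id = sprintf("F%d", seq_len(nrow(out))), out,
                              stringsAsFactors = FALSE)
  else out <- cbind(id = character(0), out)
  rownames(out) <- NULL
  out
}

#' Fragment statistics relative to the mitogenome
#'
#' @param frags output of [find_fragments()] (`b` side = mitogenome).
#' @param mito the mitogenome [genome()].
#' @return list: count, total_bp (sum of fragment lengths), union_bp
#'   (union of mitogenome intervals), min/max length, and the fraction of
#'   the mitogenome covered under both conventions (percent, 2 decimals).
#' @export
fragment_stats <- function(frags, mito) {
  L <- genome_length(mito)
  if (nrow(frags) == 0L)
    return(list(count = 0L, total_bp = 0L, union_bp = 0L,
                min_len = NA_integer_, max_len = NA_integer_,
                percent_of_genome_sum = 0, percent_of_genome_union = 0))
  iv <- frags[order(frags$b_start), c("b_start", "b_end")]
  union_bp <- 0L
  cur_s <- iv$b_start[1]; cur_e <- iv$b_end[1]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    if (iv$b_start[i] <= cur_e + 1L) cur_e <- max(cur_e, iv$b_end[i])
    else { union_bp <- union_bp + (cur_e - cur_s + 1L); cur_s <- iv$b_start[i]; cur_e <- iv$b_end[i] }
  }
  union_bp <- union_bp + (cur_e - cur_s + 1L)
  list(count = nrow(frags), total_bp = sum(frags$length),
       union_bp = union_bp,
       min_len = min(frags$length), max_len = max(frags$length),
       percent_of_genome_sum = round(100 * sum(frags$length) / L, 2),
       percent_of_genome_union = round(100 * union_bp / L, 2))
}

## is a query sequence present in a target genome? presence = significant
## fragment hits covering >= coverage_min of the query
present_in <- function(query_seq, target, evalue_cutoff = 1e-5,
                       coverage_min = 0.7, ...) {
  hits <- find_fragments(query_seq, target, evalue_cutoff = evalue_cutoff, ...)
  if (nrow(hits) == 0L) return(FALSE)
  iv <- hits[order(hits$a_start), c("a_start", "a_end")]
  cov <- 0L; cur_s <- iv$a_start[1]; cur_e <- iv$a_end[1]
  if (nrow(iv) > 1L) for (i in 2:nrow(iv)) {
    if (iv$a_start[i] <= cur_e + 1L) cur_e <- max(cur_e, iv$a_end[i])
    else { cov <- cov + (cur_e - cur_s + 1L); cur_s <- iv$a_start[i]; cur_e <- iv$a_end[i] }
  }
  cov <- cov + (cur_e - cur_s + 1L)
  cov / nchar(if (inherits(query_seq, "genome")) query_seq$seq else query_seq) >=
    coverage_min
}

#' Classify fragment origin against an outgroup genome pair
#'
#' For each fragment, its plastid-side sequence is searched against the
#' outgroup plastome and outgroup mitogenome with the same seeded engine
#' and cutoff (presence requires >= 70% query coverage). Decision table:
#' present in both outgroup genomes -> vertical; only in the outgroup
#' plastome -> horizontal_plastid_to_mito; in neither -> unresolved; only
#' in the outgroup mitogenome -> unresolved (flagged anomalous).
#'
#' @param frags fragments from [find_fragments()] run as (plastome, mito).
#' @param plastome the plastome the fragments were called on (`a` side).
#' @param outgroup_plastome,outgroup_mito outgroup [genome()] pair.
#' @param evalue_cutoff,coverage_min presence criteria.
#' @return data.frame: id, call, in_outgroup_plastome, in_outgroup_mito,
#'   anomalous.
#' @export
classify_origin <- function(frags, plastome, outgroup_plastome, outgroup_mito,
                            evalue_cutoff = 1e-5, coverage_min = 0.7) {
  rows <- lapply(seq_len(nrow(frags)), function(i) {
    q <- substr(plastome$seq, frags$a_start[i], frags$a_end[i])
    in_cp <- present_in(q, outgroup_plastome, evalue_cutoff, coverage_min)
    in_mt <- present_in(q, outgroup_mito, evalue_cutoff, coverage_min)
    call <- if (in_cp && in_mt) "vertical"
            else if (in_cp) "horizontal_plastid_to_mito"
            else "unresolved"
    data.frame(id = frags$id[i], call = call, in_outgroup_plastome = in_cp,
               in_outgroup_mito = in_mt, anomalous = (!in_cp && in_mt),
               stringsAsFactors = FALSE)
  })
  if (length(rows)) do.call(rbind, rows)
  else data.frame(id = character(), call = character(),
                  in_outgroup_plastome = logical(),
                  in_outgroup_mito = logical(), anomalous = logical())
}

#' Dotplot data for synteny visualisation
#'
#' The fragment engine run with a relaxed cutoff; forward and reverse hits
#' are emitted for separate plotting.
#'
#' @param a,b genomes or strings.
#' @param evalue_cutoff relaxed cutoff (default 1e-3).
#' @param ... passed to [find_fragments()].
#' @return data.frame: a_start, a_end, b_start, b_end, strand.
#' @export
dotplot_data <- function(a, b, evalue_cutoff = 1e-3, ...) {
  fr <- find_fragments(a, b, evalue_cutoff = evalue_cutoff, ...)
  fr[, c("a_start", "a_end", "b_start", "b_end", "strand")]
}
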