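# k-mer utilities shared by the graph builder, quadripartite detector and
# the seeded homology engine. All positions 1-based.

kmer_starts <- function(seq, k) {
  n <- nchar(seq)
  if (n < k) return(integer(0))
  seq_len(n - k + 1L)
}

kmer_vector <- function(seq, k) {
  st <- kmer_starts(seq, k)
  substring(seq, st, st + k - 1L)
}

kmer_table <- function(seq, k) {
  st <- kmer_starts(seq, k)
  data.table::data.table(kmer = substring(seq, st, st + k - 1L), pos = st)
}

## split positions (sorted) into runs of consecutive integers; returns
## group index vector
run_groups <- function(pos) {
  if (length(pos) == 0L) return(integer(0))
  cumsum(c(1L, as.integer(diff(pos) != 1L)))
}

## maximal exact direct (same-strand) repeat pairs of length >= min_len.
## Each pair reported once with s1 < s2. Arms that overlap each other
## (tandem-style) are dropped when disjoint_only = TRUE.
exact_forward_pairs <- function(seq, min_len, k = min(min_len, 32L),
                                disjoint_only = TRUE) {
  pos <- kmer <- pos2 <- NULL # data.table NSE
  A <- kmer_table(seq, k)
  m <- merge(A, A, by = "kmer", allow.cartesian = TRUE,
             suffixes = c("", "2"))
  m <- m[m$pos2 > m$pos, ]
  if (nrow(m) == 0L) return(empty_pairs())
  m$d <- m$pos2 - m$pos
  data.table::setorderv(m, c("d", "pos"))
  m$grp <- paste0(m$d, "_", stats::ave(m$pos, m$d, FUN = run_groups))
  agg <- m[, list(s1 = min(pos), e1 = max(pos) + k - 1L, d = .SD$d[1]),
           by = "grp"]
  out <- data.frame(s1 = agg$s1, e1 = agg$e1,
                    s2 = agg$s1 + agg$d, e2 = agg$e1 + agg$d)
  out$len <- out$e1 - out$s1 + 1L
  out <- out[out$len >= min_len, , drop = FALSE]
  if (disjoint_only) out <- out[out$s2 > out$e1, , drop = FALSE]
  out[order(out$s1, out$s2), , drop = FALSE]
}

## maximal exact palindromic (reverse-complement) repeat pairs of length
## >= min_len; arm2 is the reverse complement of arm1. Pairs reported once
## with s1 < s2; arms must be disjoint.
exact_palindromic_pairs <- function(seq, min_len, k = min(min_len, 32L)) {
  pos <- NULL
  L <- nchar(seq)
  A <- kmer_table(seq, k)
  B <- kmer_table(revcomp(seq), k)
  m <- merge(A, B, by = "kmer", allow.cartesian = TRUE, suffixes = c("", "_rc"))
  if (nrow(m) == 0L) return(empty_pairs())
  # arm1 read forward appears contiguously in revcomp(seq), so within one
  # palindromic pair pos - pos_rc is constant (a diagonal in (seq, rc) space)
  m$cc <- m$pos - m$pos_rc
  data.table::setorderv(m, c("cc", "pos"))
  m$grp <- paste0(m$cc, "_", stats::ave(m$pos, m$cc, FUN = run_groups))
  agg <- m[, list(p0 = min(pos), p1 = max(pos), cc = .SD$cc[1]), by = "grp"]
  # genome coordinates of arm2 (reverse strand of the rc match)
  s2 <- L - agg$p1 + agg$cc - k + 2L
  e2 <- L - agg$p0 + agg$cc + 1L
  out <- data.frame(s1 = agg$p0, e1 = agg$p1 + k - 1L, s2 = s2, e2 = e2)
  out$len <- out$e1 - out$s1 + 1L
  out <- out[out$len >= min_len, , drop = FALSE]
  # normalise to s1 < s2 and dedupe the two symmetric discoveries
  swap <- out$s1 > out$s2
  tmp <- out[swap, c("s2", "e2")]
  out[swap, c("s2", "e2")] <- out[swap, c("s1", "e1")]
  out[swap, c("s1", "e1")] <- tmp
  out <- out[out$s2 > out$e1, , drop = FALSE]  # disjoint arms only
  out <- out[!duplicated(out[c("s1", "e1", "s2", "e2")]), , drop = FALSE]
  out[order(out$s1, out$s2), , drop = FALSE]
}

empty_pairs <- function() {
  data.frame(s1 = integer(), e1 = integer(), s2 = integer(), e2 = integer(),
             len = integer())
}
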