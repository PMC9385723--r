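# Independent oracles used by the tests. These deliberately use naive
# character-by-character algorithms, separate from the package's
# vectorised implementations.

## brute-force SSR scanner: tests every (position, period) pair and
## extends perfect periodicity one character at a time
brute_force_ssrs <- function(seq, thresholds = c(`1` = 10L, `2` = 5L, `3` = 4L,
                                                 `4` = 3L, `5` = 3L, `6` = 3L)) {
  ch <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  for (p in 1:6) {
    thr <- thresholds[[as.character(p)]]
    i <- 1L
    while (i + p <= n) {
      # maximal run starting at i: skip if the run extends left
      if (i > 1L && i + p - 1L <= n && ch[i - 1L] == ch[i - 1L + p]) {
        i <- i + 1L
        next
      }
      j <- i
      while (j + p <= n && ch[j] == ch[j + p]) j <- j + 1L
      run_len <- (j - i) + p
      copies <- run_len %/% p
      if (copies >= thr) {
        motif <- paste(ch[i:(i + p - 1L)], collapse = "")
        primitive <- TRUE
        for (d in seq_len(p - 1L)) {
          if (p %% d == 0L && strrep(substr(motif, 1L, d), p %/% d) == motif)
            primitive <- FALSE
        }
        if (primitive)
          rows[[length(rows) + 1L]] <- data.frame(
            period = p, copies = copies, start = i, end = i + run_len - 1L,
            stringsAsFactors = FALSE)
      }
      i <- j + 1L
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(period = integer(), copies = integer(),
                         start = integer(), end = integer())
  out[order(out$start, out$period), , drop = FALSE]
}

## naive reverse complement, independent of Biostrings
naive_revcomp <- function(seq) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(map[strsplit(toupper(seq), "", fixed = TRUE)[[1]]]), collapse = "")
}

## random sequence helper for tests
rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

## spell a walk through a unitig graph (all-0M overlaps), for comparing
## against the planted genome
spell_walk <- function(graph, path) {
  paste(vapply(seq_len(nrow(path)), function(i) {
    s <- graph$segments[[path$segment[i]]]$seq
    if (path$orient[i] == "-") naive_revcomp(s) else s
  }, ""), collapse = "")
}
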