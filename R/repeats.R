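# Repeat landscape: perfect microsatellites (MISA-style thresholds),
# dispersed repeats in three orientations with a mismatch budget, a
# simplified tandem-array finder, and the plastome quadripartite structure.

.default_ssr_thresholds <- c(`1` = 10L, `2` = 5L, `3` = 4L, `4` = 3L,
                             `5` = 3L, `6` = 3L)

ssr_class_names <- c("mono", "di", "tri", "tetra", "penta", "hexa")

## canonical rotation of a motif: lexicographically smallest rotation
canonical_rotation <- function(motif) {
  n <- nchar(motif)
  if (n == 1L) return(motif)
  rots <- vapply(seq_len(n), function(i)
    paste0(substr(motif, i, n), substr(motif, 1L, i - 1L)), "")
  min(rots)
}

## is the motif a repetition of a shorter motif?
is_primitive_motif <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d != 0L) next
    if (strrep(substr(motif, 1L, d), p %/% d) == motif) return(FALSE)
  }
  TRUE
}

#' Find perfect microsatellites (SSRs)
#'
#' Reports all maximal perfect runs of a 1-6 bp motif meeting the
#' per-class copy-number thresholds (MISA-style defaults
#' `1-10 2-5 3-4 4-3 5-3 6-3`). A run is reported once, under its shortest
#' explaining period; reported coordinates are the maximal perfect run
#' (which may include a partial final copy), and `copies` counts whole
#' copies. On circular genomes the scan crosses the origin. SSRs whose
#' maximal runs lie within 100 bp of each other share a `compound` group
#' id but are counted individually.
#'
#' @param g a [genome()] or nucleotide string.
#' @param thresholds named vector, unit length (`"1"`..`"6"`) to minimum
#'   copies.
#' @return data.frame: motif (canonical rotation), motif_obs, period,
#'   copies, start, end, length, class, wrapped, compound.
#' @export
find_ssrs <- function(g, thresholds = .default_ssr_thresholds) {
  stopifnot(all(as.character(1:6) %in% names(thresholds)))
  seq <- if (inherits(g, "genome")) g$seq else toupper(g)
  circular <- inherits(g, "genome") && g$circular
  L <- nchar(seq)
  W <- if (circular) min(L, 240L) else 0L
  ext <- if (W > 0L) paste0(seq, substr(seq, 1L, W)) else seq
  ch <- strsplit(ext, "", fixed = TRUE)[[1]]
  n <- length(ch)

  rows <- list()
  for (p in 1:6) {
    if (n <= p) next
    thr <- as.integer(thresholds[[as.character(p)]])
    eq <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    r <- rle(eq)
    ends_r <- cumsum(r$lengths)
    starts_r <- ends_r - r$lengths + 1L
    for (j in which(r$values)) {
      i0 <- starts_r[j]
      i1 <- ends_r[j]
      run_len <- (i1 - i0 + 1L) + p        # bp of the maximal perfect run
      copies <- run_len %/% p
      if (copies < thr) next
      motif <- paste(ch[i0:(i0 + p - 1L)], collapse = "")
      if (!is_primitive_motif(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = canonical_rotation(motif), motif_obs = motif, period = p,
        copies = copies, start = i0, end = i0 + run_len - 1L,
        length = run_len, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(motif = character(), motif_obs = character(),
                         period = integer(), copies = integer(),
                         start = integer(), end = integer(),
                         length = integer(), stringsAsFactors = FALSE)
  if (nrow(out) && W > 0L) {
    out <- out[out$start <= L, , drop = FALSE]
    wrapped <- out$end > L
    # drop origin-prefix re-discoveries of wrapped runs
    if (any(wrapped)) {
      keep <- rep(TRUE, nrow(out))
      for (wi in which(wrapped)) {
        wend <- out$end[wi] - L
        keep <- keep & !(out$period == out$period[wi] & out$start >= 1L &
                         out$end <= wend & seq_len(nrow(out)) != wi)
      }
      out <- out[keep, , drop = FALSE]
      wrapped <- out$end > L
    }
    out$end <- ifelse(out$end > L, out$end - L, out$end)
    out$wrapped <- wrapped
  } else if (nrow(out)) {
    out$wrapped <- FALSE
  } else out$wrapped <- logical(0)

  out$class <- if (nrow(out)) ssr_class_names[out$period] else character(0)
  out <- out[order(out$start, out$period), , drop = FALSE]
  rownames(out) <- NULL
  # compound annotation: chains of SSRs within 100 bp
  out$compound <- rep(NA_integer_, nrow(out))
  if (nrow(out) > 1L) {
    gid <- cumsum(c(1L, as.integer(out$start[-1L] - out$end[-nrow(out)] > 100L)))
    tab <- table(gid)
    multi <- as.integer(names(tab)[tab > 1L])
    out$compound <- ifelse(gid %in% multi, match(gid, multi), NA_integer_)
  }
  out
}

# ---------------------------------------------------------------------------
# dispersed repeats

comp_map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

## expectation value of a length-l arm pair with <= m mismatches among
## L^2 placements (uniform composition)
dispersed_evalue <- function(len, mism, L) {
  vapply(seq_along(len), function(i)
    as.numeric(L)^2 * sum(stats::dbinom(0:mism[i], size = len[i], prob = 3 / 4)),
    1.0)
}

#' Find dispersed repeats (forward, palindromic, reverse)
#'
#' Maximal repeated arm pairs with Hamming distance at most `max_mismatch`
#' in three orientations: forward (direct copy), palindromic
#' (reverse-complement copy), reverse (reversed, non-complemented copy).
#' Arms are extended from exact seeds over all splits of the mismatch
#' budget between the two directions; the longest extension is kept.
#' Pairs are scored with a binomial expectation value
#' `E = L^2 * P(Hamming <= m | length)` and filtered at `max_evalue`;
#' at most `max_count` pairs are returned, longest first.
#'
#' @param g a [genome()] or string.
#' @param min_len minimal arm length (>= 8).
#' @param max_mismatch Hamming budget between arms.
#' @param max_evalue expectation-value cutoff.
#' @param max_count cap on reported pairs.
#' @return data.frame: orientation, start1, end1, start2, end2, length,
#'   mismatches, evalue.
#' @export
find_dispersed <- function(g, min_len = 30L, max_mismatch = 3L,
                           max_evalue = 1e-4, max_count = 5000L) {
  stopifnot(min_len >= 8L)
  seq <- if (inherits(g, "genome")) g$seq else toupper(g)
  L <- nchar(seq)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  k <- choose_dispersed_k(L, min_len, max_mismatch, max_evalue)

  out <- list()
  for (ori in c("forward", "palindromic", "reverse")) {
    hits <- dispersed_orientation(ch, seq, L, k, ori, min_len, max_mismatch)
    if (!is.null(hits) && nrow(hits)) {
      hits$orientation <- ori
      out[[length(out) + 1L]] <- hits
    }
  }
  res <- if (length(out)) do.call(rbind, out)
         else data.frame(start1 = integer(), end1 = integer(),
                         start2 = integer(), end2 = integer(),
                         length = integer(), mismatches = integer(),
                         orientation = character(), stringsAsFactors = FALSE)
  if (nrow(res)) {
    res$evalue <- dispersed_evalue(res$length, res$mismatches, L)
    res <- res[res$evalue <= max_evalue, , drop = FALSE]
    res <- res[order(-res$length, res$start1, res$start2), , drop = FALSE]
    if (nrow(res) > max_count) res <- res[seq_len(max_count), , drop = FALSE]
    rownames(res) <- NULL
  } else res$evalue <- numeric(0)
  res[, c("orientation", "start1", "end1", "start2", "end2", "length",
          "mismatches", "evalue")]
}

## largest seed length still guaranteed (pigeonhole) to hit every arm pair
## that can pass the e-value filter: a pair of length l with m mismatches
## contains an exact block of >= ceiling((l - m) / (m + 1)) bases
choose_dispersed_k <- function(L, min_len, max_mismatch, max_evalue) {
  k_bound <- min_len                       # m = 0 case
  for (m in seq_len(max_mismatch)) {
    for (l in min_len:(min_len + 200L)) {
      if (dispersed_evalue(l, m, L) <= max_evalue) {
        k_bound <- min(k_bound, as.integer(ceiling((l - m) / (m + 1))))
        break
      }
    }
  }
  max(4L, min(31L, k_bound))
}

## seed, extend and deduplicate one orientation class.
## Coordinate model: arm1 position a pairs with arm2 position b where
##   forward:      b = b1 + (a - a1)        (both read left-to-right)
##   palindromic:  b = b2 - (a - a1), base comp'd (arm2 = revcomp(arm1))
##   reverse:      b = b2 - (a - a1)        (arm2 = reverse(arm1))
## Extension runs in lock-step over all seeds (vectorised), trying every
## split of the mismatch budget between the two directions and keeping
## the longest result per seed.
dispersed_orientation <- function(ch, seq, L, k, ori, min_len, max_mismatch) {
  pos <- NULL
  A <- kmer_table(seq, k)
  t <- switch(ori, forward = seq, palindromic = revcomp(seq),
              reverse = paste(rev(ch), collapse = ""))
  B <- kmer_table(t, k)
  m <- merge(A, B, by = "kmer", allow.cartesian = TRUE, suffixes = c("", "_t"))
  if (nrow(m) == 0L) return(NULL)
  if (ori == "forward") {
    m <- m[m$pos_t > m$pos, ]                 # each unordered pair once
    if (nrow(m) == 0L) return(NULL)
    a <- m$pos
    bref <- m$pos_t                           # arm2 start for this offset
    dkey <- bref - a
  } else {
    # t position q covers genome arm2 interval [L-q-k+2, L-q+1]
    a <- m$pos
    bref <- L - m$pos_t + 1L                  # arm2 END for this offset
    keepi <- bref - k + 1L > a + k - 1L       # disjoint arms, arm1 first
    a <- a[keepi]; bref <- bref[keepi]
    if (length(a) == 0L) return(NULL)
    dkey <- bref + a
  }
  # collapse runs of consecutive seeds on one diagonal: one representative
  # per run (long exact repeats otherwise seed thousands of times)
  o <- order(dkey, a)
  a <- a[o]; bref <- bref[o]; dkey <- dkey[o]
  first <- c(TRUE, diff(a) != 1L | diff(dkey) != 0L)
  a <- a[first]; bref <- bref[first]
  n <- length(a)

  sgn <- if (ori == "forward") 1L else -1L
  match_at <- function(i, j) {
    ok <- i >= 1L & j >= 1L & i <= L & j <= L & i < j
    eq <- rep(FALSE, length(i))
    eq[ok] <- if (ori == "palindromic")
      ch[i[ok]] == unname(comp_map[ch[j[ok]]])
    else ch[i[ok]] == ch[j[ok]]
    list(ok = ok, eq = eq)
  }
  ## one direction of lock-step extension; dir = -1 (left of seed) or +1
  ## (right past the seed end); returns reached offset and mismatches used
  extend_dir <- function(budget, dir) {
    off0 <- if (dir < 0L) 0L else k - 1L
    reach <- rep(off0, n)
    used <- rep(0L, n)
    act <- rep(TRUE, n)
    s <- 0L
    while (any(act)) {
      s <- s + 1L
      if (s > L) break
      idx <- which(act)
      x <- off0 + dir * s
      i <- a[idx] + x
      j <- bref[idx] + sgn * x
      mt <- match_at(i, j)
      die <- !mt$ok | (!mt$eq & used[idx] >= budget)
      cons <- !die & !mt$eq
      used[idx[cons]] <- used[idx[cons]] + 1L
      reach[idx[!die]] <- x
      act[idx[die]] <- FALSE
    }
    list(reach = reach, used = used)
  }

  best_lo <- rep(0L, n); best_hi <- rep(k - 1L, n)
  best_len <- rep(k, n); best_mm <- rep(0L, n)
  left <- lapply(0:max_mismatch, function(b) extend_dir(b, -1L))
  right <- lapply(0:max_mismatch, function(b) extend_dir(b, +1L))
  for (lm in 0:max_mismatch) {
    rm <- max_mismatch - lm
    lo <- left[[lm + 1L]]$reach
    hi <- right[[rm + 1L]]$reach
    mm <- left[[lm + 1L]]$used + right[[rm + 1L]]$used
    len <- hi - lo + 1L
    upd <- len > best_len | (len == best_len & mm < best_mm)
    best_lo[upd] <- lo[upd]; best_hi[upd] <- hi[upd]
    best_len[upd] <- len[upd]; best_mm[upd] <- mm[upd]
  }

  s1 <- a + best_lo; e1 <- a + best_hi
  if (ori == "forward") {
    s2 <- bref + best_lo; e2 <- bref + best_hi
  } else {
    s2 <- bref - best_hi; e2 <- bref - best_lo
  }
  keepi <- best_len >= min_len & s2 > e1
  if (!any(keepi)) return(NULL)
  h <- data.frame(start1 = s1[keepi], end1 = e1[keepi], start2 = s2[keepi],
                  end2 = e2[keepi], length = best_len[keepi],
                  mismatches = best_mm[keepi], stringsAsFactors = FALSE)
  h <- h[!duplicated(h[c("start1", "end1", "start2", "end2")]), , drop = FALSE]
  # drop pairs whose arms are both contained in a longer reported pair
  h <- h[order(-h$length), , drop = FALSE]
  keep <- rep(TRUE, nrow(h))
  for (i in seq_len(nrow(h))) {
    if (!keep[i]) next
    contained <- h$start1 >= h$start1[i] & h$end1 <= h$end1[i] &
                 h$start2 >= h$start2[i] & h$end2 <= h$end2[i] &
                 seq_len(nrow(h)) != i
    keep[contained] <- FALSE
  }
  h[keep, , drop = FALSE]
}

## Hamming distance between the oriented arm sequences of a reported pair;
## used by the re-verification invariant
dispersed_arm_mismatches <- function(seq, row) {
  a <- substr(seq, row$start1, row$end1)
  b <- substr(seq, row$start2, row$end2)
  b <- switch(row$orientation,
              forward = b,
              palindromic = revcomp(b),
              reverse = paste(rev(strsplit(b, "", fixed = TRUE)[[1]]),
                              collapse = ""))
  sum(strsplit(a, "", fixed = TRUE)[[1]] != strsplit(b, "", fixed = TRUE)[[1]])
}

# ---------------------------------------------------------------------------
# tandem repeats (simplified TRF)

#' Find tandem repeat arrays
#'
#' A simplified tandem-repeat finder: candidate periods are seeded by
#' positions matching their `period`-shifted copy (tolerating short
#' interruptions), then each candidate array is scored against its
#' majority-consensus unit tiled across the array (match +2,
#' mismatch `mismatch`). Arrays with at least 2 copies, percent identity
#' >= `min_identity` and score >= `min_score` are reported; overlapping
#' explanations keep the smallest period.
#'
#' @param g a [genome()] or string.
#' @param match,mismatch alignment scores (TRF-style 2, -7).
#' @param min_identity percent identity threshold (80).
#' @param min_score minimal alignment score (50).
#' @param max_period maximal period (500).
#' @return data.frame: unit, period, copies, start, end, length,
#'   percent_identity, score.
#' @export
find_tandem <- function(g, match = 2L, mismatch = -7L, min_identity = 80,
                        min_score = 50L, max_period = 500L) {
  seq <- if (inherits(g, "genome")) g$seq else toupper(g)
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(ch)
  rows <- list()
  for (p in seq_len(min(max_period, n %/% 2L))) {
    eq <- ch[seq_len(n - p)] == ch[(p + 1L):n]
    r <- rle(eq)
    # bridge short interruptions, but only between substantial match runs
    # (otherwise random background mismatches chain into bogus arrays)
    vals <- r$values
    lens <- r$lengths
    solid <- vals & lens >= max(4L, p %/% 2L)
    for (j in which(!vals & lens <= max(2L, p %/% 10L))) {
      if (j > 1L && j < length(vals) && solid[j - 1L] && solid[j + 1L])
        vals[j] <- TRUE
    }
    r2 <- rle(inverse.rle(list(values = vals, lengths = lens)))
    ends_r <- cumsum(r2$lengths)
    starts_r <- ends_r - r2$lengths + 1L
    for (j in which(r2$values)) {
      run_len <- (ends_r[j] - starts_r[j] + 1L) + p
      if (run_len < 2L * p) next
      st <- starts_r[j]
      en <- st + run_len - 1L
      copies <- run_len / p
      # consensus unit: per-phase majority over the array
      cons <- vapply(seq_len(p), function(ph) {
        at <- seq(st + ph - 1L, en, by = p)
        names(which.max(table(ch[at])))
      }, "")
      if (!is_primitive_motif(paste(cons, collapse = ""))) next
      tiled <- rep_len(cons, run_len)
      mat <- sum(tiled == ch[st:en])
      mis <- run_len - mat
      score <- match * mat + mismatch * mis
      pid <- 100 * mat / run_len
      if (score < min_score || pid < min_identity || copies < 2) next
      rows[[length(rows) + 1L]] <- data.frame(
        unit = paste(cons, collapse = ""), period = p, copies = copies,
        start = st, end = en, length = run_len, percent_identity = pid,
        score = score, stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(unit = character(), period = integer(),
                         copies = numeric(), start = integer(),
                         end = integer(), length = integer(),
                         percent_identity = numeric(), score = numeric(),
                         stringsAsFactors = FALSE)
  if (nrow(out) > 1L) {
    # overlapping arrays: keep the smallest period (then best score)
    out <- out[order(out$period, -out$score), , drop = FALSE]
    keep <- rep(TRUE, nrow(out))
    for (i in seq_len(nrow(out))) {
      if (!keep[i]) next
      ov <- pmax(0L, pmin(out$end, out$end[i]) - pmax(out$start, out$start[i]) + 1L)
      dup <- ov > 0.5 * out$length & seq_len(nrow(out)) > i
      keep[dup] <- FALSE
    }
    out <- out[keep, , drop = FALSE]
    out <- out[order(out$start), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

# ---------------------------------------------------------------------------
# quadripartite structure

idx_mod <- function(i, L) ((i - 1L) %% L) + 1L

#' Detect the quadripartite LSC/IRa/SSC/IRb structure of a plastome
#'
#' The longest pair of disjoint reverse-complement-identical intervals of
#' at least `min_ir` bp defines the inverted repeats; boundaries are
#' maximal (extension, with circular wrap, breaks identity). The longer
#' arc between the IRs is the LSC, the shorter the SSC; regions are
#' labelled so the circle reads LSC, IRa, SSC, IRb.
#'
#' @param g a circular [genome()].
#' @param min_ir minimal IR length (default 1000 bp).
#' @return `list(lsc, ira, ssc, irb, ir_length)`; each region is
#'   `c(start, end)` (possibly wrapping).
#' @export
detect_quadripartite <- function(g, min_ir = 1000L) {
  stopifnot(inherits(g, "genome"), g$circular)
  seq <- g$seq
  L <- nchar(seq)
  pairs <- exact_palindromic_pairs(seq, min_ir)
  if (nrow(pairs) == 0L) stop("no IR structure: no reverse-complement pair >= ",
                              min_ir, " bp")
  pairs <- pairs[order(-pairs$len), , drop = FALSE]
  pr <- pairs[1L, ]
  ch <- strsplit(seq, "", fixed = TRUE)[[1]]
  a1 <- pr$s1; a2 <- pr$e1; b1 <- pr$s2; b2 <- pr$e2
  # maximal extension with circular wrap
  for (step in seq_len(L)) {
    i <- idx_mod(a1 - 1L, L); j <- idx_mod(b2 + 1L, L)
    if (i == b2 || j == a1 || i == j) break
    if (ch[i] != comp_map[[ch[j]]]) break
    a1 <- a1 - 1L; b2 <- b2 + 1L
    if (a1 < 1L || b2 > L) { a1 <- a1 + 1L; b2 <- b2 - 1L; break } # keep non-wrapping arms
  }
  for (step in seq_len(L)) {
    i <- idx_mod(a2 + 1L, L); j <- idx_mod(b1 - 1L, L)
    if (i >= b1 || j <= a2) break
    if (ch[i] != comp_map[[ch[j]]]) break
    a2 <- a2 + 1L; b1 <- b1 - 1L
  }
  ir_len <- a2 - a1 + 1L
  arc1 <- c(idx_mod(a2 + 1L, L), idx_mod(b1 - 1L, L))   # between arm1 and arm2
  arc2 <- c(idx_mod(b2 + 1L, L), idx_mod(a1 - 1L, L))   # wraps past the origin
  arc_len <- function(iv) ((iv[2] - iv[1]) %% L) + 1L
  if (arc_len(arc2) >= arc_len(arc1)) {
    res <- list(lsc = arc2, ira = c(a1, a2), ssc = arc1, irb = c(b1, b2))
  } else {
    res <- list(lsc = arc1, ira = c(b1, b2), ssc = arc2, irb = c(a1, a2))
  }
  res$ir_length <- ir_len
  res
}

#' Compare two circular assemblies up to rotation and SSC inversion
#'
#' Equality is tested up to rotation and global reverse complement; if the
#' genomes differ, the SSC of `a` is reverse-complemented in place (using
#' [detect_quadripartite()]) and equality is retested.
#'
#' @param a,b circular [genome()] objects.
#' @return `"identical"`, `"identical_after_ssc_inversion"` or
#'   `"different"` (with a `note` attribute when structure detection
#'   fails).
#' @export
compare_up_to_ssc_flip <- function(a, b) {
  stopifnot(a$circular, b$circular)
  if (circular_equal(a$seq, b$seq)) return("identical")
  q <- tryCatch(detect_quadripartite(a), error = function(e) e)
  if (inherits(q, "error")) {
    out <- "different"
    attr(out, "note") <- paste("quadripartite detection failed:",
                               conditionMessage(q))
    return(out)
  }
  flipped <- flip_region(a$seq, q$ssc)
  if (circular_equal(flipped, b$seq)) "identical_after_ssc_inversion"
  else "different"
}

## reverse-complement a (possibly wrapping) region in place
flip_region <- function(seq, iv) {
  L <- nchar(seq)
  if (iv[1] <= iv[2]) {
    paste0(substr(seq, 1L, iv[1] - 1L),
           revcomp(substr(seq, iv[1], iv[2])),
           substr(seq, iv[2] + 1L, L))
  } else {
    # rotate so the region is contiguous, flip, rotate back
    rot <- paste0(substr(seq, iv[1], L), substr(seq, 1L, iv[1] - 1L))
    w <- L - iv[1] + 1L + iv[2]
    flipped <- paste0(revcomp(substr(rot, 1L, w)), substr(rot, w + 1L, L))
    paste0(substr(flipped, L - iv[1] + 2L, L), substr(flipped, 1L, L - iv[1] + 1L))
  }
}

#' Summarise repeat detector outputs
#'
#' @param ssrs output of [find_ssrs()] (may be empty).
#' @param dispersed optional output of [find_dispersed()].
#' @param tandem optional output of [find_tandem()].
#' @return list with per-class SSR counts and percentages, dispersed
#'   orientation counts and percentages, and length summaries; percentages
#'   are 0 (not NaN) on empty input.
#' @export
summarize_repeats <- function(ssrs, dispersed = NULL, tandem = NULL) {
  cls <- factor(ssrs$class, levels = ssr_class_names)
  counts <- as.integer(table(cls))
  names(counts) <- ssr_class_names
  total <- sum(counts)
  pct <- if (total > 0L) round(100 * counts / total, 2) else counts * 0
  out <- list(ssr_total = total, ssr_counts = as.list(counts),
              ssr_percent = as.list(pct))
  if (!is.null(dispersed)) {
    ori <- factor(dispersed$orientation,
                  levels = c("forward", "palindromic", "reverse"))
    dc <- as.integer(table(ori))
    names(dc) <- levels(ori)
    dt <- sum(dc)
    out$dispersed_total <- dt
    out$dispersed_counts <- as.list(dc)
    out$dispersed_percent <- as.list(if (dt > 0L) round(100 * dc / dt, 2)
                                     else dc * 0)
    out$dispersed_length_range <- if (dt > 0L) range(dispersed$length)
                                  else c(NA_integer_, NA_integer_)
  }
  if (!is.null(tandem)) out$tandem_total <- nrow(tandem)
  out
}
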