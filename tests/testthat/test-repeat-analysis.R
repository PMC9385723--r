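test_that("SSR thresholds are sharp at every class boundary", {
  set.seed(41)
  bg <- rand_seq(800)
  cases <- list(list(motif = "A", below = 9L, at = 10L),
                list(motif = "AG", below = 4L, at = 5L),
                list(motif = "ACT", below = 3L, at = 4L),
                list(motif = "ACGT", below = 2L, at = 3L),
                list(motif = "ACGTT", below = 2L, at = 3L),
                list(motif = "ACGTAG", below = 2L, at = 3L))
  bases <- c("A", "C", "G", "T")
  for (cs in cases) {
    p <- nchar(cs$motif)
    # breaker bases seal the run so it is exactly the planted one
    bL <- setdiff(bases, substr(cs$motif, p, p))[1]
    bR <- setdiff(bases, substr(cs$motif, 1, 1))[1]
    mk <- function(n) paste0(substr(bg, 1, 299), bL, strrep(cs$motif, n),
                             bR, substr(bg, 302 + n * p, 800))
    hit_at <- find_ssrs(mk(cs$at))
    hit_below <- find_ssrs(mk(cs$below))
    expect_true(any(hit_at$period == p & hit_at$start == 301L),
                label = paste(cs$motif, "at threshold"))
    expect_false(any(hit_below$period == p & hit_below$start == 301L),
                 label = paste(cs$motif, "below threshold"))
  }
})

test_that("SSR runs are reported once, under the shortest period", {
  s <- paste0(rand_seq(100), strrep("AT", 8), rand_seq(100))
  set.seed(42)
  s <- paste0(rand_seq(100), strrep("AT", 8), rand_seq(100))
  r <- find_ssrs(s)
  at <- r[r$start == 101L, ]
  expect_equal(nrow(at), 1L)
  expect_equal(at$period, 2L)
  expect_equal(at$motif, "AT")
})

test_that("find_ssrs equals the brute-force scanner on random sequences", {
  for (s in 1:12) {
    set.seed(200 + s)
    x <- rand_seq(3000)
    # plant threshold-boundary runs to exercise every class
    x <- paste0(x, strrep("T", 10), rand_seq(50), strrep("GA", 5),
                rand_seq(50), strrep("CAT", 4), rand_seq(50),
                strrep("GATC", 3), rand_seq(50))
    got <- find_ssrs(x)[, c("period", "copies", "start", "end")]
    want <- brute_force_ssrs(x)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, label = paste("seed", 200 + s))
  }
})

test_that("circular SSR scanning crosses the origin once", {
  core <- rand_seq(400)
  set.seed(77)
  core <- rand_seq(400)
  s <- paste0("AAAAA", core, "AAAAA")    # A x10 wrapping the origin
  g <- genome("c", s, circular = TRUE)
  r <- find_ssrs(g)
  wrap <- r[r$motif == "A" & r$wrapped, ]
  expect_equal(nrow(wrap), 1L)
  expect_equal(wrap$copies, 10L)
  expect_equal(wrap$start, 406L)
  expect_equal(wrap$end, 5L)
  # linear treatment must not report it
  lin <- find_ssrs(genome("l", s, circular = FALSE))
  expect_false(any(lin$motif == "A" & lin$copies >= 10L))
})

test_that("planted dispersed repeats are recovered in the right
           orientation class and re-verify their Hamming bound", {
  cfg <- sim_config(seed = 51, genome_length = 6000,
                    repeat_spec = list(list(arm_length = 60,
                                            orientation = "forward"),
                                       list(arm_length = 60,
                                            orientation = "inverted")))
  sim <- make_circular_genome(cfg)
  d <- find_dispersed(sim$genome)
  tr <- sim$truth$repeats
  for (i in seq_len(nrow(tr))) {
    want_ori <- if (tr$orientation[i] == "inverted") "palindromic" else "forward"
    hit <- d[d$orientation == want_ori & d$start1 <= tr$start1[i] &
             d$end1 >= tr$end1[i] & d$start2 <= tr$start2[i] &
             d$end2 >= tr$end2[i], ]
    expect_equal(nrow(hit), 1L, label = paste("family", tr$family[i]))
  }
  # every reported pair re-verifies: oriented arm Hamming distance <= 3,
  # length >= 30
  for (i in seq_len(nrow(d))) {
    expect_gte(d$length[i], 30L)
    expect_lte(organellr:::dispersed_arm_mismatches(sim$genome$seq, d[i, ]),
               3L)
    expect_equal(d$end1[i] - d$start1[i] + 1L, d$length[i])
  }
})

test_that("a planted reversed (non-complemented) copy is classed reverse", {
  set.seed(53)
  arm <- rand_seq(60)
  rev_arm <- paste(rev(strsplit(arm, "")[[1]]), collapse = "")
  s <- paste0(rand_seq(1000), arm, rand_seq(1000), rev_arm, rand_seq(1000))
  d <- find_dispersed(s)
  hit <- d[d$orientation == "reverse" & d$start1 <= 1001 & d$end1 >= 1060, ]
  expect_gte(nrow(hit), 1L)
})

test_that("the dispersed e-value filter is monotone in length", {
  ev30 <- organellr:::dispersed_evalue(30L, 3L, 150000L)
  ev60 <- organellr:::dispersed_evalue(60L, 3L, 150000L)
  expect_lt(ev60, ev30)
  expect_lt(organellr:::dispersed_evalue(60L, 0L, 150000L), ev60)
})

test_that("tandem arrays: exact, substituted, and random negatives", {
  set.seed(61)
  s <- paste0(rand_seq(900), strrep("ACGTT", 6), rand_seq(900))
  ft <- find_tandem(s)
  hit <- ft[ft$period == 5L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$unit, "ACGTT")
  expect_gte(hit$copies, 6)
  expect_equal(hit$percent_identity, 100)

  unit <- rand_seq(20)
  arr <- strsplit(strrep(unit, 10), "")[[1]]
  arr[57] <- setdiff(c("A", "C", "G", "T"), arr[57])[1]
  s2 <- paste0(rand_seq(700), paste(arr, collapse = ""), rand_seq(700))
  ft2 <- find_tandem(s2)
  hit2 <- ft2[ft2$period == 20L, ]
  expect_equal(nrow(hit2), 1L)
  expect_gte(hit2$percent_identity, 99)   # 1 substitution in 200 bp

  for (sd in 1:6) {
    set.seed(300 + sd)
    ft0 <- find_tandem(rand_seq(5000))
    false_pos <- ft0[ft0$percent_identity == 100 & ft0$copies >= 3 &
                     ft0$period >= 10, ]
    expect_equal(nrow(false_pos), 0L, label = paste("seed", 300 + sd))
  }
})

test_that("quadripartite boundaries are recovered exactly for random
           size configurations", {
  for (s in 1:8) {
    set.seed(400 + s)
    lsc <- sample(4000:9000, 1)
    ir <- sample(1000:2500, 1)
    ssc <- sample(1500:3000, 1)
    qp <- make_quadripartite_plastome(lsc, ir, ssc, seed = 400 + s)
    det <- detect_quadripartite(qp$genome)
    r <- qp$truth$regions
    expect_equal(unname(det$lsc), as.integer(r$LSC))
    expect_equal(unname(det$ira), as.integer(r$IRa))
    expect_equal(unname(det$ssc), as.integer(r$SSC))
    expect_equal(unname(det$irb), as.integer(r$IRb))
    expect_equal(det$ir_length, ir)
  }
})

test_that("random genomes have no IR structure", {
  set.seed(71)
  g <- genome("r", rand_seq(20000), circular = TRUE)
  expect_error(detect_quadripartite(g), "no IR structure")
})

test_that("assembly comparison distinguishes rotation, SSC flip and
           genuine difference", {
  qp <- make_quadripartite_plastome(6000, 1500, 2000, seed = 81)
  g <- qp$genome
  rot <- genome("rot", paste0(substr(g$seq, 500, nchar(g$seq)),
                              substr(g$seq, 1, 499)), circular = TRUE)
  expect_equal(compare_up_to_ssc_flip(g, rot), "identical")
  rc <- genome("rc", revcomp(g$seq), circular = TRUE)
  expect_equal(compare_up_to_ssc_flip(g, rc), "identical")

  r <- qp$truth$regions
  flipped_seq <- paste0(substr(g$seq, 1, r$SSC[1] - 1),
                        revcomp(substr(g$seq, r$SSC[1], r$SSC[2])),
                        substr(g$seq, r$SSC[2] + 1, nchar(g$seq)))
  flipped <- genome("fl", flipped_seq, circular = TRUE)
  expect_equal(compare_up_to_ssc_flip(g, flipped),
               "identical_after_ssc_inversion")

  set.seed(82)
  other <- genome("o", rand_seq(nchar(g$seq)), circular = TRUE)
  res <- compare_up_to_ssc_flip(other, g)   # no IR in `other`
  expect_equal(as.character(res), "different")
})

test_that("repeat summaries normalise percentages and survive empty input", {
  cfg <- sim_config(seed = 91, genome_length = 4000,
                    ssr_spec = list(list(motif = "A", copies = 11),
                                    list(motif = "AT", copies = 6),
                                    list(motif = "ACGT", copies = 4)))
  sim <- make_circular_genome(cfg)
  ssrs <- find_ssrs(sim$genome)
  sm <- summarize_repeats(ssrs, find_dispersed(sim$genome))
  expect_equal(sum(unlist(sm$ssr_percent)), 100, tolerance = 0.05)
  expect_equal(sm$ssr_total, nrow(ssrs))

  empty <- find_ssrs("ACGTAGCT")
  sm0 <- summarize_repeats(empty)
  expect_equal(sm0$ssr_total, 0L)
  expect_true(all(unlist(sm0$ssr_percent) == 0))
})
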