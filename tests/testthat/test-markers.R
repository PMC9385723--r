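## tiny annotated circle: two genes on a 1000 bp genome
two_gene_genome <- function(seed = 131) {
  set.seed(seed)
  g <- genome("tg", rand_seq(1000), circular = TRUE,
              features = data.frame(
                name = c("gA", "gB"), kind = "CDS", strand = "+",
                start = c(1L, 501L), end = c(100L, 600L), part = 1L))
  g
}

test_that("IGS extraction returns the circular complement of the genes", {
  g <- two_gene_genome()
  igs <- extract_igs(g)
  expect_equal(nrow(igs), 2L)
  mid <- igs[igs$name == "gA-gB", ]
  expect_equal(c(mid$start, mid$end, mid$length), c(101L, 500L, 400L))
  wrap <- igs[igs$name == "gB-gA", ]
  expect_equal(c(wrap$start, wrap$end, wrap$length), c(601L, 1000L, 400L))
  expect_equal(wrap$seq, substr(g$seq, 601, 1000))
})

test_that("abutting genes give a zero-length spacer", {
  set.seed(132)
  g <- genome("tg", rand_seq(500), circular = TRUE,
              features = data.frame(
                name = c("gA", "gB"), kind = "CDS", strand = "+",
                start = c(1L, 101L), end = c(100L, 200L), part = 1L))
  igs <- extract_igs(g)
  expect_equal(igs$length[igs$name == "gA-gB"], 0L)
})

test_that("IGS names preserve tRNA anticodon suffixes", {
  qp <- make_quadripartite_plastome(9000, 1500, 2500, seed = 133, n_genes = 8)
  igs <- extract_igs(qp$genome)
  expect_true(any(grepl("trnL-UAG", igs$name, fixed = TRUE)))
})

test_that("spacers extracted per species match the generator ground truth", {
  qp <- make_quadripartite_plastome(9000, 1500, 2500, seed = 134, n_genes = 8)
  igs <- extract_igs(qp$genome)
  tr <- qp$truth$genes
  tr <- tr[order(tr$start), ]
  for (i in seq_len(nrow(tr) - 1L)) {
    row <- igs[igs$gene_left == tr$name[i], ]
    expect_equal(row$start, tr$end[i] + 1L)
    expect_equal(row$end, tr$start[i + 1L] - 1L)
  }
})

test_that("alignment: identical sequences give no gap columns, one
           deletion gives one gap run", {
  seqs <- c(a = "ACGTACGTAA", b = "ACGTACGTAA", c = "ACGTACGTAA")
  al <- align_region(seqs)
  expect_true(all(al$classes == "invariant"))
  expect_equal(ncol(al$aln), 10L)

  seqs2 <- c(a = "ACGTACGTAA", b = "ACGTCGTAA", c = "ACGTACGTAA")  # 1 bp del
  al2 <- align_region(seqs2)
  expect_equal(sum(al2$aln == "-"), 1L)
  expect_equal(sum(al2$classes == "indel"), 1L)
})

test_that("k2p matches independent closed-form evaluation on (P,Q) grids", {
  n <- 200L
  for (ts in 0:6) for (tv in 0:6) {
    if (2 * ts / n + tv / n >= 0.5) next
    x <- rep(c("A", "C"), length.out = n)
    y <- x
    # transitions A->G on the first ts A-positions, transversions C->G after
    a_pos <- which(x == "A")[seq_len(ts)]
    c_pos <- which(x == "C")[seq_len(tv)]
    y[a_pos] <- "G"
    y[c_pos] <- "G"
    P <- ts / n; Q <- tv / n
    want <- -0.5 * log((1 - 2 * P - Q) * sqrt(1 - 2 * Q))
    expect_equal(k2p(x, y), want, tolerance = 1e-12,
                 label = sprintf("ts=%d tv=%d", ts, tv))
  }
  expect_equal(k2p("ACGTACGT", "ACGTACGT"), 0)
  expect_true(is.na(k2p("----", "AC--")))
  # saturation: argument of the log non-positive
  expect_true(is.na(k2p(c("A", "G"), c("G", "A"))))
})

test_that("k2p uses pairwise deletion and is symmetric", {
  x <- strsplit("ACGTAC-TAC", "")[[1]]
  y <- strsplit("ACGTACGT-C", "")[[1]]
  # included sites: positions where both are bases (8 of them)
  expect_equal(k2p(x, y), k2p(y, x))
  expect_equal(k2p(x, y), 0)  # identical at all co-present sites
  x2 <- x; x2[1] <- "G"       # one transition among 8 included sites
  P <- 1 / 8
  expect_equal(k2p(x2, y), -0.5 * log((1 - 2 * P) * sqrt(1)),
               tolerance = 1e-12)
})

test_that("region ranking orders by mean K2p and ignores species order", {
  qp <- make_quadripartite_plastome(9000, 1500, 2500, seed = 141, n_genes = 8)
  pan <- make_species_panel(qp$genome, n_species = 5,
                            igs_mutation_rate = 0.01, indel_rate = 0,
                            seed = 142)
  panels <- lapply(igs_panel(pan$panel), align_region)
  rk <- rank_regions(panels)
  expect_equal(rk$mean_k2p, sort(rk$mean_k2p, decreasing = TRUE))

  shuffled <- lapply(igs_panel(rev(pan$panel)), align_region)
  rk2 <- rank_regions(shuffled)
  expect_equal(rk2[order(rk2$region), c("region", "mean_k2p")],
               rk[order(rk$region), c("region", "mean_k2p")])

  single <- rank_regions(panels[1])
  expect_equal(nrow(single), 1L)
})

test_that("regions with planted higher mutation rates rank first", {
  wins <- 0L
  for (s in 1:5) {
    set.seed(150 + s)
    anc <- genome("anc", rand_seq(3000), circular = TRUE,
                  features = data.frame(
                    name = c("g1", "g2", "g3"), kind = "CDS", strand = "+",
                    start = c(1L, 1101L, 2101L), end = c(100L, 1200L, 2200L),
                    part = 1L))
    # region g1-g2 mutated at 2%, g2-g3 and the wrap at 0.1%
    hi <- 101:1100
    sp <- list()
    for (i in 1:4) {
      ch <- strsplit(anc$seq, "")[[1]]
      mut <- function(pos, rate) {
        at <- pos[stats::runif(length(pos)) < rate]
        for (p in at) ch[p] <<- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1)
      }
      mut(hi, 0.02)
      mut(1201:2100, 0.001)
      sp[[paste0("s", i)]] <- genome(paste0("s", i), paste(ch, collapse = ""),
                                     circular = TRUE, features = anc$features)
    }
    panels <- lapply(igs_panel(sp), align_region)
    rk <- rank_regions(panels)
    wins <- wins + (rk$region[1] == "g1-g2")
  }
  expect_gte(wins, 4L)   # majority across seeds
})

test_that("variant sites: SNP columns and collapsed indel events", {
  m <- rbind(a = strsplit("ACGTAAACGT", "")[[1]],
             b = strsplit("ACGTAAACGT", "")[[1]],
             c = strsplit("ACCT---CGT", "")[[1]])
  panel <- structure(list(aln = m, species = rownames(m),
                          classes = organellr:::column_classes(m)),
                     class = "aligned_panel")
  sites <- call_variant_sites(panel, region = "r")
  expect_equal(nrow(sites), 2L)
  snp <- sites[sites$type == "SNP", ]
  expect_equal(snp$column, 3L)
  ind <- sites[sites$type == "indel", ]
  expect_equal(ind$column, 5L)         # 3 columns collapsed to one event
  expect_equal(unname(ind$alleles[[1]]["c"]), "---")

  inv <- structure(list(aln = m[1:2, ], species = c("a", "b"),
                        classes = organellr:::column_classes(m[1:2, ])),
                   class = "aligned_panel")
  expect_equal(nrow(call_variant_sites(inv)), 0L)
})

test_that("diagnostic selection: minimal cases and failure modes", {
  m <- rbind(a = c("A", "C"), b = c("A", "T"))
  panel <- structure(list(aln = m, species = c("a", "b"),
                          classes = organellr:::column_classes(m)),
                     class = "aligned_panel")
  sel <- select_diagnostic_sites(list(r1 = panel), max_regions = 1)
  expect_equal(sel$n_sites, 1L)
  expect_equal(sel$pairs_total, 1L)

  m2 <- rbind(a = c("A", "C"), b = c("A", "C"))
  dup <- structure(list(aln = m2, species = c("a", "b"),
                        classes = organellr:::column_classes(m2)),
                   class = "aligned_panel")
  expect_error(select_diagnostic_sites(list(r1 = dup), max_regions = 1),
               "a/b")
})

test_that("planted panels are fully discriminated and independently
           re-verified", {
  qp <- make_quadripartite_plastome(12000, 1500, 2500, seed = 161,
                                    n_genes = 10)
  pan <- make_species_panel(qp$genome, n_species = 8,
                            igs_mutation_rate = 0.004, indel_rate = 0.001,
                            seed = 162)
  panels <- lapply(igs_panel(pan$panel), align_region)
  sel <- select_diagnostic_sites(panels, max_regions = length(panels))
  expect_equal(sel$pairs_total, choose(8, 2))
  # independent re-verification: for every pair some selected site differs
  for (pi in seq_len(nrow(sel$coverage))) {
    s1 <- sel$coverage$species1[pi]
    s2 <- sel$coverage$species2[pi]
    diffs <- vapply(seq_len(nrow(sel$sites)), function(si) {
      al <- sel$sites$alleles[[si]]
      !is.na(al[s1]) && !is.na(al[s2]) && al[s1] != al[s2]
    }, TRUE)
    expect_true(any(diffs), label = paste(s1, s2))
  }
})

test_that("greedy cover size is near the exhaustive optimum on small
           panels", {
  qp <- make_quadripartite_plastome(9000, 1500, 2500, seed = 171, n_genes = 8)
  pan <- make_species_panel(qp$genome, n_species = 5,
                            igs_mutation_rate = 0.003, indel_rate = 0.001,
                            seed = 172)
  panels <- lapply(igs_panel(pan$panel), align_region)
  sel <- select_diagnostic_sites(panels, max_regions = length(panels))
  # rebuild the coverage matrix over the selected candidate sites and
  # compare to the exhaustive minimum (ln(#pairs) approximation bound)
  species <- sort(sel$species)
  prs <- utils::combn(species, 2)
  all_sites <- do.call(rbind, lapply(names(panels), function(rg)
    call_variant_sites(panels[[rg]], region = rg)))
  cov <- t(vapply(seq_len(nrow(all_sites)), function(si) {
    al <- all_sites$alleles[[si]]
    vapply(seq_len(ncol(prs)), function(p) {
      a1 <- al[prs[1, p]]; a2 <- al[prs[2, p]]
      !is.na(a1) && !is.na(a2) && a1 != a2
    }, TRUE)
  }, logical(ncol(prs))))
  opt <- organellr:::min_cover_size(cov)
  expect_lte(sel$n_sites, max(opt * ceiling(log(ncol(prs))), opt))
})
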