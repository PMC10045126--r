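# scalar-loop AMOVA oracle: textbook mean squares from a squared-distance
# matrix, coded independently of the package's vectorized path
amova_oracle <- function(d2, groups) {
  N <- length(groups); gs <- unique(groups); K <- length(gs)
  sst <- 0
  for (i in 1:(N - 1)) for (j in (i + 1):N) sst <- sst + d2[i, j]
  sst <- sst / N
  ssw <- 0
  for (g in gs) {
    idx <- which(groups == g)
    if (length(idx) < 2) next
    acc <- 0
    for (i in idx) for (j in idx) if (i < j) acc <- acc + d2[i, j]
    ssw <- ssw + acc / length(idx)
  }
  msw <- ssw / (N - K)
  msa <- (sst - ssw) / (K - 1)
  nprime <- (N - sum(table(groups)^2) / N) / (K - 1)
  sa <- (msa - msw) / nprime
  sa / (sa + msw)
}

test_that("Phi-ST hits the 0 and 1 anchors", {
  # identical haplotype composition: SS_among is exactly 0, so the
  # (untruncated, unbiased) estimate is <= 0
  a <- toy_alignment(rep(c("ACGTACGT", "ACGAACGA"), 4),
                     pops = rep(c("p1", "p2"), each = 4))
  expect_lte(phist_matrix(a, "diff")$phist["p1", "p2"], 0)
  # each population fixed for its own haplotype -> 1
  b <- toy_alignment(rep(c("ACGTACGT", "TCGATCGA"), each = 4),
                     pops = rep(c("p1", "p2"), each = 4))
  expect_equal(phist_matrix(b, "diff")$phist["p1", "p2"], 1)
})

test_that("Phi-ST equals the brute-force AMOVA oracle", {
  # 3+3 toy with one shared and one private haplotype
  a <- toy_alignment(c("AAAA", "AAAT", "AAAT", "AAAT", "AATT", "AATT"),
                     pops = c("p1", "p1", "p1", "p2", "p2", "p2"))
  d2 <- pairwise_dist_matrix(a, "diff")^2
  expect_equal(phist_matrix(a, "diff")$phist["p1", "p2"],
               amova_oracle(d2, a$pop_labels), tolerance = 1e-12)
  # and on a larger random configuration with three populations
  set.seed(7)
  r <- random_alignment(12, 60, seed = 3,
                        pops = rep(c("x", "y", "z"), times = c(5, 4, 3)))
  d2r <- pairwise_dist_matrix(r, "diff")^2
  ph <- phist_matrix(r, "diff")$phist
  for (pr in list(c("x", "y"), c("x", "z"), c("y", "z"))) {
    idx <- r$pop_labels %in% pr
    expect_equal(ph[pr[1], pr[2]],
                 amova_oracle(d2r[idx, idx], r$pop_labels[idx]),
                 tolerance = 1e-12)
  }
})

test_that("Phi-ST is invariant to population order and within-pop relabeling", {
  set.seed(5)
  a <- random_alignment(10, 80, seed = 11,
                        pops = rep(c("p1", "p2"), each = 5))
  ph1 <- phist_matrix(a, "diff")$phist
  perm <- c(sample(1:5), sample(6:10))  # shuffle within populations
  b <- subset_alignment(a, perm)
  expect_equal(phist_matrix(b, "diff")$phist, ph1)
  rev_order <- c(6:10, 1:5)  # present p2 first
  c_ <- subset_alignment(a, rev_order)
  ph2 <- phist_matrix(c_, "diff")$phist
  expect_equal(ph2["p1", "p2"], ph1["p1", "p2"])
})

test_that("permutation p-values are high for identical compositions", {
  a <- toy_alignment(rep(c("ACGTACGT", "ACGAACGA"), 4),
                     pops = rep(c("p1", "p2"), each = 4))
  res <- phist_matrix(a, "diff", n_perm = 50, seed = 1)
  expect_gte(res$p["p1", "p2"], 0.5)
})

test_that("microsatellite summaries match hand-evaluated formulas", {
  # one locus, two identical heterozygotes 120/140:
  # Ho = 1, He = (4/3)(1 - 0.5) = 2/3, FIS = 1 - Ho/He = -0.5
  G <- genotype_matrix(c("i1", "i2"), "L1", matrix(c(120L, 120L)),
                       matrix(c(140L, 140L)), "p1")
  s <- msat_summaries(G)
  expect_equal(s$Ho, 1)
  expect_equal(s$He, 2 / 3, tolerance = 1e-12)
  expect_equal(s$FIS, -0.5, tolerance = 1e-12)

  # fixed population: He = 0, Ho = 0, FIS undefined
  Gf <- genotype_matrix(c("i1", "i2"), c("L1", "L2"),
                        matrix(120L, 2, 2), matrix(120L, 2, 2), "p1")
  sf <- msat_summaries(Gf)
  expect_equal(sf$Ho, 0)
  expect_equal(sf$He, 0)
  expect_true(is.na(sf$FIS))

  # adding a monomorphic locus leaves the other locus untouched pairwise
  G2 <- genotype_matrix(c("i1", "i2"), c("L1", "L2"),
                        cbind(c(120L, 120L), c(100L, 100L)),
                        cbind(c(140L, 140L), c(100L, 100L)), "p1")
  s2 <- msat_summaries(G2)
  expect_equal(s2$Ho, mean(c(1, 0)))
  expect_equal(s2$He, mean(c(2 / 3, 0)), tolerance = 1e-12)
})

# independent hand-coded Weir-Cockerham components for one locus, two
# alleles, two populations of scored individuals
wc_oracle_one_locus <- function(g1, g2) {
  n1 <- nrow(g1); n2 <- nrow(g2)
  alleles <- sort(unique(c(g1, g2)))
  num <- den <- 0
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  for (A in alleles) {
    p1 <- sum(g1 == A) / (2 * n1); p2 <- sum(g2 == A) / (2 * n2)
    h1 <- sum((g1[, 1] == A) != (g1[, 2] == A)) / n1
    h2 <- sum((g2[, 1] == A) != (g2[, 2] == A)) / n2
    pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
    s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
    hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
    a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                        (nbar - 1))
    b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                (2 * nbar - 1) / (4 * nbar) * hbar)
    cc <- hbar / 2
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

test_that("Weir-Cockerham theta matches the variance-component oracle", {
  set.seed(13)
  g1 <- matrix(sample(c(100L, 104L, 108L), 20, TRUE, prob = c(.6, .3, .1)),
               10, 2)
  g2 <- matrix(sample(c(100L, 104L, 108L), 20, TRUE, prob = c(.2, .3, .5)),
               10, 2)
  G <- genotype_matrix(sprintf("i%02d", 1:20), "L1",
                       rbind(g1[, 1, drop = FALSE], g2[, 1, drop = FALSE]),
                       rbind(g1[, 2, drop = FALSE], g2[, 2, drop = FALSE]),
                       rep(c("p1", "p2"), each = 10))
  expect_equal(wc_fst(G)["p1", "p2"], wc_oracle_one_locus(g1, g2),
               tolerance = 1e-12)
})

test_that("Weir-Cockerham theta hits its anchors", {
  # fixed for different alleles -> 1
  G1 <- genotype_matrix(sprintf("i%02d", 1:12), "L1",
                        matrix(rep(c(100L, 140L), each = 6)),
                        matrix(rep(c(100L, 140L), each = 6)),
                        rep(c("p1", "p2"), each = 6))
  expect_equal(wc_fst(G1)["p1", "p2"], 1)
  # identical allele frequencies, equal n -> ~0 (within small-sample bias)
  set.seed(3)
  pool <- sample(c(100L, 104L, 108L, 112L), 80, TRUE)
  G0 <- genotype_matrix(sprintf("i%02d", 1:40), "L1",
                        matrix(pool[1:40]), matrix(pool[41:80]),
                        rep(c("p1", "p2"), each = 20))
  expect_lt(abs(wc_fst(G0)["p1", "p2"]), 0.15)
  # input-order invariance
  perm <- sample(1:12)
  G1p <- genotype_matrix(G1$individual_ids[perm], "L1",
                         G1$a1[perm, , drop = FALSE],
                         G1$a2[perm, , drop = FALSE], G1$pop_labels[perm])
  expect_equal(wc_fst(G1p)["p1", "p2"], 1)
})
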