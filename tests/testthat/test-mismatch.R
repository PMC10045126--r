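test_that("observed mismatch histograms on tiny alignments", {
  expect_equal(unname(observed_mismatch(toy_alignment(c("ACGT", "ACGT")))), 1)
  m3 <- observed_mismatch(toy_alignment(c("ACGTACGT", "TCGAACGA")))
  expect_equal(unname(m3), c(0, 0, 0, 1))  # all mass at class 3
  # pairwise diffs {1,1,2} -> frequencies {0, 2/3, 1/3}
  tri <- toy_alignment(c("AAAA", "AAAT", "AATA"))
  expect_equal(unname(observed_mismatch(tri)), c(0, 2 / 3, 1 / 3))
})

test_that("expected mismatch reduces to the equilibrium geometric at tau=0", {
  f <- expected_mismatch(0, 1, 1, 60)
  expect_equal(f[1:4], 0.5^(1:4), tolerance = 1e-10)
  # a probability distribution for arbitrary parameter corners
  for (par in list(c(0, 0, 0), c(5, 0.5, 50), c(12, 3, 0.2), c(0.3, 8, 8))) {
    g <- expected_mismatch(par[1], par[2], par[3], 40)
    expect_equal(sum(g), 1, tolerance = 1e-12)
    expect_true(all(g >= 0))
  }
})

test_that("expected mismatch matches the coalescent simulation oracle", {
  # empirical pairwise-difference distribution of the simulator at
  # (tau=5, theta0=0.5, theta1=50) vs the closed form
  set.seed(77)
  reps <- 1500
  cnt <- integer(reps)
  for (r in seq_len(reps)) {
    a <- simulate_mtdna(2, expansion = c(5, 0.5, 50), L = 1500)
    cnt[r] <- pairwise_diff_counts(a)$diffs[1, 2]
  }
  emp <- tabulate(cnt + 1L, nbins = 26) / reps   # classes 0..25
  thr <- expected_mismatch(5, 0.5, 50, 300)[1:26]
  expect_lt(max(abs(emp - thr)), 0.035)          # MC tolerance
})

test_that("raggedness follows the stated boundary convention", {
  expect_equal(raggedness(1), 1)                 # all mass at class 0
  expect_equal(raggedness(c(0.5, 0.5)), 0.25)
  # smooth geometric curve is less ragged than a two-spike curve
  smooth <- expected_mismatch(0, 2, 2, 10)
  spiky <- c(0.5, 0, 0, 0, 0, 0.5, rep(0, 5))
  expect_lt(raggedness(smooth), raggedness(spiky))
})

test_that("sudden-expansion fit recovers exact curves and is monotone", {
  obs <- expected_mismatch(3, 1, 30, 60)
  fit <- fit_sudden_expansion(obs, extra_classes = 0)
  expect_lt(fit$ssd, 1e-8)
  expect_equal(fit$tau, 3, tolerance = 0.05)
  expect_equal(fit$theta0, 1, tolerance = 0.1)
  expect_equal(fit$theta1, 30, tolerance = 1)

  # right-shifting the histogram by one class increases tau-hat
  base <- expected_mismatch(2, 0.5, 20, 30)
  shifted <- c(0, base[-length(base)])
  shifted <- shifted / sum(shifted)
  f0 <- fit_sudden_expansion(base, extra_classes = 0)
  f1 <- fit_sudden_expansion(shifted, extra_classes = 0)
  expect_gt(f1$tau, f0$tau)
})

test_that("tau is recovered from simulated expansions", {
  set.seed(11)
  taus <- replicate(60, {
    a <- simulate_mtdna(30, expansion = c(2, 0.1, 1000), L = 1000)
    fit_sudden_expansion(observed_mismatch(a))$tau
  })
  expect_lt(median(abs(taus - 2) / 2), 0.25)
})

test_that("goodness-of-fit bootstrap is calibrated at the boundary and reproducible", {
  obs <- expected_mismatch(2, 0.5, 25, 30)
  fit <- fit_sudden_expansion(obs, extra_classes = 0)
  g1 <- gof_bootstrap(fit, n = 25, L = 900, n_reps = 60, seed = 5)
  g2 <- gof_bootstrap(fit, n = 25, L = 900, n_reps = 60, seed = 5)
  expect_identical(g1$p_ssd, g2$p_ssd)            # seed-reproducible
  expect_gte(g1$p_ssd, 0.95)                      # exact curve: p ~ 1
  expect_true(g1$p_hri >= 0 && g1$p_hri <= 1)
})

test_that("expansion clock reproduces the published tau-to-time table", {
  taus <- c(2.5, 1.875, 1.5, 1.5, 1.375, 1.375, 2.13281, 1.74023, 0.89680)
  kyr <- c(22.67, 17.00, 13.60, 13.60, 12.47, 12.46, 19.34, 15.78, 8.13)
  got <- expansion_time(taus)
  expect_true(all(abs(got - kyr) <= 0.01))
  expect_equal(expansion_time(0), 0)
  # linearity: doubling tau doubles the time (up to the 2-decimal rounding)
  expect_equal(expansion_time(5), 2 * expansion_time(2.5), tolerance = 1e-3)
})
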