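test_that("prior draws respect bounds, ordering and the seed", {
  spec <- prior_spec()
  p <- draw_priors(spec, 500, seed = 1)
  for (nm in names(spec)) {
    expect_true(all(p[[nm]] >= spec[[nm]][1] & p[[nm]] <= spec[[nm]][2]),
                label = nm)
  }
  expect_true(all(p$t1 < p$t2 & p$t2 < p$t3))
  p2 <- draw_priors(spec, 500, seed = 1)
  expect_identical(p, p2)
  # near-unsatisfiable ordering constraints warn
  tight <- prior_spec(list(t1 = c(1, 1000), t2 = c(1, 1000), t3 = c(10, 20)))
  expect_warning(draw_priors(tight, 10, seed = 2), "fewer than 1%")
})

test_that("summary statistics: determinism, symmetry, hand toy", {
  sc <- flat_scenario(N = 2000)
  G <- simulate_msat_dataset(sc, mutation_model(5e-4, 0.15), c(6, 6, 6, 6),
                             n_loci = 6, seed = 3)
  s1 <- msat_summary_stats(G)
  s2 <- msat_summary_stats(G)
  expect_identical(s1, s2)
  expect_identical(length(s1), 30L)
  expect_identical(names(s1), summary_stat_names())

  # two identical groups: pairwise FST ~ 0 and (delta-mu)^2 = 0
  a1 <- matrix(rep(c(100L, 104L), 6), 6, 2)
  G2 <- genotype_matrix(sprintf("i%d", 1:6), c("L1", "L2"),
                        rbind(a1[1:3, ], a1[1:3, ]),
                        rbind(a1[4:6, ], a1[4:6, ]),
                        rep(c("g1", "g2", "g3", "g4"), times = c(2, 2, 1, 1)))
  s <- msat_summary_stats(G2, rep(c("g1", "g2", "g3", "g4"), times = c(2, 2, 1, 1)))
  expect_equal(unname(s["DM2_TW"]), 0)
  expect_lte(unname(s["FST_TW"]), 0)  # identical groups: no among-variance

  # hand-computed two-group, one-locus toy
  # g1: genotypes {100/100, 100/104}; g2: {104/104, 104/104}
  Gh <- genotype_matrix(c("a", "b", "c", "d"), "L1",
                        matrix(c(100L, 100L, 104L, 104L)),
                        matrix(c(100L, 104L, 104L, 104L)),
                        c("g1", "g1", "g2", "g2"))
  # four clusters are required; duplicate the groups
  Gh4 <- genotype_matrix(rep(c("a", "b", "c", "d"), 2), "L1",
                         matrix(rep(c(100L, 100L, 104L, 104L), 2)),
                         matrix(rep(c(100L, 104L, 104L, 104L), 2)),
                         rep(c("g1", "g2", "g3", "g4"), each = 2))
  sh <- msat_summary_stats(Gh4)
  # group 1 = {100/100, 100/104}: 2 alleles, He = (4/3)(1 - (9+1)/16) = 0.5,
  # allele sizes {100,100,100,104}: var = 4
  expect_equal(unname(sh["NAL_T"]), 2)
  expect_equal(unname(sh["HET_T"]), 0.5, tolerance = 1e-12)
  expect_equal(unname(sh["VAR_T"]), var(c(100, 100, 100, 104)))
  # (delta-mu)^2 between groups 1 and 2: (101 - 104)^2 = 9
  expect_equal(unname(sh["DM2_TW"]), 9)
  # shared-allele distance: proportions shared are 0 (a-c), 0 (a-d),
  # 1/2 (b-c), 1/2 (b-d), so Das = mean(1, 1, 0.5, 0.5) = 0.75
  expect_equal(unname(sh["DAS_TW"]), 0.75)
})

test_that("rejection step: ranking, tolerance, MAD guard", {
  spec <- validation_priors()
  tab <- abc_reference_table(spec, n_per_scenario = 300,
                             sample_sizes = c(4, 6, 6, 6), n_loci = 5,
                             seed = 4)
  # observed equal to a table row ranks that row first at zero distance
  obs <- tab$stats[123, ]
  rej <- abc_reject(obs, tab, tolerance = 0.05)
  expect_identical(rej$index[1], 123L)
  expect_equal(rej$distance[1], 0)
  # tolerance 1.0 returns the whole table; retained distances bound the rest
  rej_all <- abc_reject(obs, tab, tolerance = 1)
  expect_identical(length(rej_all$index), nrow(tab$stats))
  excluded <- setdiff(rej_all$index, rej$index)
  d_excl <- rej_all$distance[match(excluded, rej_all$index)]
  expect_lte(max(rej$distance), min(d_excl) + 1e-12)
  expect_true(!is.unsorted(rej$distance))
})

test_that("direct model choice: symmetry anchors and unit sum", {
  fake <- list(scenario = rep(1:3, times = 400), distance = rep(1, 1200))
  out <- choose_model_direct(fake, k = 1200)
  expect_equal(out$posterior, rep(1 / 3, 3))
  expect_equal(sum(out$posterior), 1)
  one <- list(scenario = rep(2L, 500), distance = rep(1, 500))
  out1 <- choose_model_direct(one, k = 400)
  expect_equal(out1$posterior, c(0, 1, 0))
  expect_equal(attr(out1, "n_used"), 400)
})

test_that("logistic model choice is ~symmetric for indistinguishable scenarios", {
  # scenarios 1 and 2 generated from the same process: posteriors near 1/2
  spec <- validation_priors()
  set.seed(6)
  tab <- abc_reference_table(spec, scenarios = c(2, 2), n_per_scenario = 400,
                             sample_sizes = c(4, 6, 6, 6), n_loci = 6)
  tab$params$scenario <- rep(1:2, each = 400)  # relabel identical halves
  p <- draw_priors(spec, 1)
  sc <- scenario_spec(2, as.numeric(p[1, 1:4]), p$t1, p$t2, p$t3, p$ra)
  G <- simulate_msat_dataset(sc, mutation_model(p$mu, p$P), c(4, 6, 6, 6),
                             n_loci = 6)
  rej <- abc_reject(msat_summary_stats(G), tab, tolerance = 0.25)
  out <- choose_model_logistic(rej, scenarios = 1:2)
  expect_equal(sum(out$posterior), 1, tolerance = 1e-6)
  expect_lt(abs(out$posterior[1] - 0.5), 0.35)
})

test_that("logistic choice handles a scenario absent from the retained set", {
  spec <- validation_priors()
  set.seed(16)
  tab <- abc_reference_table(spec, scenarios = c(1, 2), n_per_scenario = 250,
                             sample_sizes = c(4, 6, 6, 6), n_loci = 6)
  p <- draw_priors(spec, 1)
  sc <- scenario_spec(2, as.numeric(p[1, 1:4]), p$t1, p$t2, p$t3, p$ra)
  G <- simulate_msat_dataset(sc, mutation_model(p$mu, p$P), c(4, 6, 6, 6),
                             n_loci = 6)
  rej <- abc_reject(msat_summary_stats(G), tab, tolerance = 0.2)
  out <- choose_model_logistic(rej, scenarios = 1:3)  # 3 asked, 2 present
  expect_identical(nrow(out), 3L)
  expect_equal(sum(out$posterior), 1, tolerance = 1e-9)
  expect_equal(out$posterior[3], 0)  # scenario 3 never simulated
})

test_that("parameter estimation stays inside the prior bounds", {
  spec <- validation_priors()
  set.seed(7)
  tab <- abc_reference_table(spec, scenarios = 2, n_per_scenario = 600,
                             sample_sizes = c(4, 6, 6, 6), n_loci = 6)
  p <- draw_priors(spec, 1)
  sc <- scenario_spec(2, as.numeric(p[1, 1:4]), p$t1, p$t2, p$t3, p$ra)
  G <- simulate_msat_dataset(sc, mutation_model(p$mu, p$P), c(4, 6, 6, 6),
                             n_loci = 6)
  rej <- abc_reject(msat_summary_stats(G), tab, tolerance = 0.2)
  est <- estimate_parameters(rej, tab, spec, scenario = 2)
  for (i in seq_len(nrow(est))) {
    b <- spec[[est$parameter[i]]]
    expect_true(est$median[i] >= b[1] && est$median[i] <= b[2])
    expect_true(est$q025[i] >= b[1] && est$q975[i] <= b[2])
  }
})

test_that("POD validation on indistinguishable scenarios gives ~2/3 type I", {
  # degenerate time priors collapse the three hypotheses onto (almost)
  # the same process: every split falls within a few generations of t3
  spec <- prior_spec(list(N_T = c(2000, 4000), N_W = c(2000, 4000),
                          N_E = c(2000, 4000), N_C = c(2000, 4000),
                          t1 = c(50, 60), t2 = c(9000, 9050),
                          t3 = c(9100, 9150), mu = c(2e-4, 8e-4)))
  set.seed(8)
  tab <- abc_reference_table(spec, scenarios = 1:3, n_per_scenario = 500,
                             sample_sizes = c(4, 6, 6, 6), n_loci = 6)
  rep_pod <- pod_validation(tab, spec, n_pods = 12, seed = 9,
                            method = "direct", tolerance = 0.1, k = 150)
  expect_s3_class(rep_pod, "pod_report")
  expect_true(all(rep_pod$errors$type1 >= 0 & rep_pod$errors$type1 <= 1))
  # with three interchangeable scenarios the mean type-I error is ~ 2/3
  expect_lt(abs(mean(rep_pod$errors$type1) - 2 / 3), 0.25)
  expect_identical(sum(rep_pod$assignments), 36L)
})

test_that("PCA goodness-of-fit projection is deterministic and calibrated", {
  spec <- validation_priors()
  tab <- abc_reference_table(spec, scenarios = 2, n_per_scenario = 400,
                             sample_sizes = c(4, 6, 6, 6), n_loci = 6,
                             seed = 10)
  obs <- tab$stats[57, ]
  g1 <- gof_pca(tab, obs)
  g2 <- gof_pca(tab, obs)
  expect_identical(g1$observed_coords, g2$observed_coords)
  # a table-drawn observation projects inside the cloud
  rng1 <- range(g1$table_coords[, 1])
  rng2 <- range(g1$table_coords[, 2])
  expect_true(g1$observed_coords[1] >= rng1[1] &&
                g1$observed_coords[1] <= rng1[2])
  expect_true(g1$observed_coords[2] >= rng2[1] &&
                g1$observed_coords[2] <= rng2[2])
})

test_that("reference tables are bit-reproducible under a seed", {
  spec <- validation_priors()
  t1 <- abc_reference_table(spec, scenarios = 2, n_per_scenario = 50,
                            sample_sizes = c(3, 4, 4, 4), n_loci = 4, seed = 12)
  t2 <- abc_reference_table(spec, scenarios = 2, n_per_scenario = 50,
                            sample_sizes = c(3, 4, 4, 4), n_loci = 4, seed = 12)
  expect_identical(t1$params, t2$params)
  expect_identical(t1$stats, t2$stats)
})
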