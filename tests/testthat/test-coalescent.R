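test_that("genealogies conserve leaves and reproduce E[T2] = 2N", {
  sc <- flat_scenario(N = 1000)
  g <- simulate_genealogy(sc, c(2, 3, 4, 1), seed = 1)
  expect_identical(g$n_leaves, 10L)
  expect_identical(length(g$parent), 19L)
  expect_identical(sum(g$parent == -1L), 1L)     # single root
  expect_identical(tabulate(g$leaf_pop + 1L, 4), c(2L, 3L, 4L, 1L))

  set.seed(2)
  t2 <- replicate(4000, max(simulate_genealogy(sc, c(0, 0, 2, 0))$time))
  se <- sd(t2) / sqrt(length(t2))
  expect_lt(abs(mean(t2) - 2000), 3 * se + 1e-9)

  g1 <- simulate_genealogy(sc, c(2, 2, 2, 2), seed = 99)
  g2 <- simulate_genealogy(sc, c(2, 2, 2, 2), seed = 99)
  expect_identical(g1, g2)                       # same seed, same genealogy
})

test_that("stranded scenarios are rejected", {
  # a hypothesis-1 scenario sampled only in Thrace and West never merges
  # before t3; sampling a single lineage in two unlinked populations with
  # zero rate would strand without the final merges -- here every lineage
  # reaches the root, so this must run:
  sc <- scenario_spec(1, c(100, 100, 100, 100), t1 = 10, t2 = 20, t3 = 30,
                      ra = 0.5)
  expect_silent(simulate_genealogy(sc, c(1, 1, 1, 1), seed = 3))
  expect_error(simulate_genealogy(sc, c(1, 0, 0, 0)), "two sampled")
})

test_that("microsatellite mutation layer has the random-walk moments", {
  # two leaves at distance T = 5000 generations from their ancestor
  g <- list(parent = c(2L, 2L, -1L), time = c(0, 0, 5000), n_leaves = 2L)
  mu <- 5e-4
  smm <- mutation_model(mu, P = 0)
  set.seed(4)
  d <- replicate(8000, {a <- mutate_microsat(g, smm, 30L); a[1] - a[2]})
  # strict SMM: Var(diff) = E[mutations] = mu * 2T
  expect_equal(mean(d), 0, tolerance = 0.1)
  expect_equal(var(d), mu * 10000, tolerance = 0.35)

  # mu = 0: every leaf equals the root allele
  expect_identical(mutate_microsat(g, mutation_model(0), 30L), c(30L, 30L))

  # GSM with P -> 0 reproduces strict SMM moments
  set.seed(5)
  dg <- replicate(8000, {
    a <- mutate_microsat(g, mutation_model(mu, P = 1e-9), 30L); a[1] - a[2]
  })
  expect_equal(var(dg), var(d), tolerance = 0.3)
  # GSM with P > 0 inflates the step variance
  set.seed(6)
  db <- replicate(8000, {
    a <- mutate_microsat(g, mutation_model(mu, P = 0.5), 30L); a[1] - a[2]
  })
  expect_gt(var(db), var(d))
  # alleles always within bounds
  big <- mutation_model(0.05, P = 0.4, bounds = c(10L, 49L))
  a <- mutate_microsat(list(parent = c(2L, 2L, -1L), time = c(0, 0, 5e4),
                            n_leaves = 2L), big, 30L, seed = 7)
  expect_true(all(a >= 10L & a <= 49L))
})

test_that("msat datasets: shape, determinism, and divergence monotonicity", {
  sc <- flat_scenario(N = 2000)
  mm <- mutation_model(5e-4, P = 0.15)
  G <- simulate_msat_dataset(sc, mm, c(10, 10, 10, 10), n_loci = 13, seed = 1)
  expect_identical(dim(G$a1), c(40L, 13L))
  expect_identical(as.integer(table(G$pop_labels)[c("Thrace", "West")]),
                   c(10L, 10L))
  G2 <- simulate_msat_dataset(sc, mm, c(10, 10, 10, 10), n_loci = 13, seed = 1)
  expect_identical(G$a1, G2$a1)

  # panmictic scenario: mean multi-locus theta ~ 0
  set.seed(8)
  th0 <- replicate(30, {
    Gp <- simulate_msat_dataset(flat_scenario(N = 5000), mm, c(0, 15, 15, 0),
                                n_loci = 10)
    wc_fst(Gp)["West", "East"]
  })
  expect_lt(abs(mean(th0)), 0.02)

  # deeper splits produce monotonically larger theta
  set.seed(9)
  mean_theta <- vapply(c(100, 1000, 10000), function(ts) {
    mean(replicate(12, {
      sc2 <- scenario_spec(1, rep(2000, 4), t1 = ts * 0.1, t2 = ts,
                           t3 = ts * 10, ra = 0.5)
      Gd <- simulate_msat_dataset(sc2, mm, c(0, 15, 15, 0), n_loci = 10)
      wc_fst(Gd)["West", "East"]
    }))
  }, numeric(1))
  expect_true(all(diff(mean_theta) > 0))
})

test_that("exchangeability: relabeling samples within a population", {
  sc <- flat_scenario(N = 3000)
  mm <- mutation_model(5e-4, P = 0.15)
  G <- simulate_msat_dataset(sc, mm, c(5, 8, 8, 5), n_loci = 8, seed = 21)
  idx <- which(G$pop_labels == "West")
  perm <- seq_along(G$individual_ids)
  perm[idx] <- sample(idx)
  Gp <- genotype_matrix(G$individual_ids, G$locus_names,
                        G$a1[perm, , drop = FALSE], G$a2[perm, , drop = FALSE],
                        G$pop_labels)
  expect_equal(msat_summary_stats(Gp), msat_summary_stats(G))
})

test_that("mtDNA simulator: anchors and expansion signature", {
  expect_identical(n_sequences(simulate_mtdna(5, theta = 0, L = 50, seed = 1)), 5L)
  a0 <- simulate_mtdna(5, theta = 0, L = 50, seed = 1)
  expect_identical(length(unique(a0$sequences)), 1L)  # theta = 0

  set.seed(10)
  d <- replicate(400, collapse_and_diversity(simulate_mtdna(6, theta = 3,
                                                            L = 800))$d)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 3), 4 * se)              # E[pi] = theta

  # strong expansion: smoother mismatch than constant size at equal diversity
  set.seed(12)
  r_exp <- replicate(25, raggedness(observed_mismatch(
    simulate_mtdna(25, expansion = c(5, 0.5, 100), L = 1200))))
  r_const <- replicate(25, raggedness(observed_mismatch(
    simulate_mtdna(25, theta = 5.5, L = 1200))))
  expect_lt(mean(r_exp), mean(r_const))

  b1 <- simulate_mtdna(8, theta = 2, L = 300, seed = 33)
  b2 <- simulate_mtdna(8, theta = 2, L = 300, seed = 33)
  expect_identical(b1$sequences, b2$sequences)     # bit-reproducible
})

test_that("pairwise coalescence times match the msprime oracle", {
  py <- Sys.which("python")
  skip_if(py == "", "python not on PATH")
  script <- '
import msprime, sys
dem = msprime.Demography()
dem.add_population(name="W", initial_size=2000)
dem.add_population(name="E", initial_size=2000)
dem.add_population_split(time=800, derived=["W"], ancestral="E")
ts_reps = msprime.sim_ancestry(samples={"W": 1, "E": 1}, demography=dem,
                               ploidy=1, num_replicates=1500, random_seed=7)
for ts in ts_reps:
    print(ts.max_root_time)
'
  out <- suppressWarnings(system2(py, c("-c", shQuote(script)),
                                  stdout = TRUE, stderr = FALSE))
  skip_if(length(out) < 1000, "msprime unavailable")
  ref <- as.numeric(out)
  sc <- scenario_spec(1, c(1000, 1000, 1000, 1000), t1 = 400, t2 = 800,
                      t3 = 1e6, ra = 0.5)
  set.seed(13)
  ours <- replicate(1500, max(simulate_genealogy(sc, c(0, 1, 1, 0))$time))
  expect_gt(suppressWarnings(ks.test(ours, ref))$p.value, 0.01)
})
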