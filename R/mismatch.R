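# Mismatch-distribution analysis under the sudden (stepwise) demographic
# expansion model, and conversion of the mutational expansion parameter tau
# into calendar time.

#' Observed mismatch distribution
#'
#' Histogram of pairwise nucleotide difference counts (pairwise deletion of
#' sites with `N`/`-`), normalized to sum to one over classes `0..max`.
#'
#' @param aln a [sequence_alignment()] with >= 2 sequences.
#' @return Named numeric vector of relative frequencies (names are the
#'   difference classes starting at 0).
#' @export
observed_mismatch <- function(aln) {
  if (n_sequences(aln) < 2) stop("need at least two sequences")
  pd <- pairwise_diff_counts(aln)
  cnt <- pd$diffs[upper.tri(pd$diffs)]
  f <- tabulate(cnt + 1L, nbins = max(cnt) + 1L)
  f <- f / sum(f)
  names(f) <- 0:(length(f) - 1L)
  f
}

# equilibrium pairwise-difference distribution for a stationary population,
# theta^i / (1+theta)^(i+1), in log space so large difference classes and
# large theta do not overflow
equilibrium_mismatch <- function(theta, i) {
  if (theta <= 0) return(as.numeric(i == 0))
  exp(i * log(theta) - (i + 1) * log1p(theta))
}

#' Expected mismatch distribution under sudden expansion
#'
#' The transient distribution of pairwise differences tau mutational time
#' units after an instantaneous change of the scaled mutation parameter from
#' `theta0` to `theta1`:
#' \deqn{F_j = \hat F_j(\theta_1) + e^{-\tau(\theta_1+1)/\theta_1}
#'   \sum_{i=0}^{j} [\hat F_i(\theta_0) - \hat F_i(\theta_1)]
#'   \tau^{j-i}/(j-i)!}
#' with the stationary distribution \eqn{\hat F_i(\theta) =
#' \theta^i/(1+\theta)^{i+1}}. The vector is truncated at `dmax` and
#' renormalized.
#'
#' @param tau expansion time in mutational units (`tau = 2 u t`).
#' @param theta0,theta1 scaled mutation parameters before/after expansion.
#' @param dmax largest difference class.
#' @return Numeric vector of probabilities over classes `0..dmax`, summing
#'   to 1.
#' @export
expected_mismatch <- function(tau, theta0, theta1, dmax) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 >= 0, dmax >= 0)
  i <- 0:dmax
  f1 <- equilibrium_mismatch(theta1, i)
  f0 <- equilibrium_mismatch(theta0, i)
  decay <- exp(-tau * (theta1 + 1) / max(theta1, 1e-12))
  # Poisson-style weights tau^m / m! evaluated in log space (large dmax)
  pw <- if (tau > 0)
    exp((0:dmax) * log(tau) - lgamma(1:(dmax + 1))) else
    c(1, rep(0, dmax))
  conv <- vapply(i, function(j) {
    k <- 0:j
    sum((f0[k + 1] - f1[k + 1]) * pw[j - k + 1])
  }, numeric(1))
  f <- f1 + decay * conv
  f[f < 0] <- 0
  f / sum(f)
}

#' Harpending's raggedness index
#'
#' `r = sum_{i=1}^{d+1} (x_i - x_{i-1})^2` over a frequency vector
#' `x_0..x_d`, with a single appended zero class `x_{d+1} = 0` and no
#' implicit class before the first.
#'
#' @param observed normalized frequency vector over classes `0..d`.
#' @return The raggedness index.
#' @export
raggedness <- function(observed) {
  x <- c(as.numeric(observed), 0)
  sum(diff(x)^2)
}

#' Fit the sudden-expansion model to a mismatch distribution
#'
#' Least-squares fit of (`tau`, `theta0`, `theta1`) minimizing the sum of
#' squared deviations between the observed and model-expected mismatch
#' distributions, by bounded multi-start optimization (a deterministic grid
#' of starts, L-BFGS-B). Bounds: `tau` in `[0, 2 dmax]`, `theta0` in
#' `[0, 10 dbar]`, `theta1` in `[0, max(10 dbar, 100)]` where `dbar` is the
#' observed mean difference count.
#'
#' @param observed normalized frequency vector over classes `0..dmax`
#'   (e.g. from [observed_mismatch()]).
#' @param extra_classes difference classes appended beyond the observed
#'   support when evaluating the model (finite support for the SSD).
#' @return A list of class `mismatch_fit`: `observed`, `expected`, `tau`,
#'   `theta0`, `theta1`, `ssd`, `hri`, `converged`.
#' @export
fit_sudden_expansion <- function(observed, extra_classes = 5) {
  obs <- as.numeric(observed)
  obs <- obs / sum(obs)
  dmax <- length(obs) - 1L + as.integer(extra_classes)
  obs_ext <- c(obs, rep(0, extra_classes))
  dbar <- sum(obs * seq(0, length(obs) - 1L))
  lower <- c(0, 0, 0)
  upper <- c(2 * max(dmax, 1), max(10 * dbar, 1), max(10 * dbar, 100))
  ssd_fn <- function(par) {
    e <- expected_mismatch(par[1], par[2], par[3], dmax)
    sum((obs_ext - e)^2)
  }
  mode_cls <- which.max(obs) - 1
  starts <- rbind(
    c(max(dbar, 0.1), 0.1, max(5 * dbar, 5)),
    c(max(mode_cls, 0.5), 0.5, max(10 * dbar, 20)),
    c(max(dbar / 2, 0.1), 1, max(2 * dbar, 2)),
    c(max(2 * dbar, 1), 0.01, upper[3] / 2),
    c(0.5, dbar, max(dbar, 1)),
    c(max(dbar, 0.5), 0, upper[3]))
  starts <- pmin(pmax(starts, rep(lower, each = nrow(starts))),
                 rep(upper, each = nrow(starts)))
  best <- NULL
  conv <- FALSE
  for (r in seq_len(nrow(starts))) {
    res <- tryCatch(
      optim(starts[r, ], ssd_fn, method = "L-BFGS-B", lower = lower,
            upper = upper, control = list(maxit = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) {
      best <- res
      conv <- res$convergence == 0
    }
  }
  if (is.null(best)) stop("mismatch fit failed from every start")
  e <- expected_mismatch(best$par[1], best$par[2], best$par[3], dmax)
  structure(list(observed = obs, expected = e[seq_along(obs)],
                 tau = best$par[1], theta0 = best$par[2],
                 theta1 = best$par[3], ssd = best$value,
                 hri = raggedness(obs), converged = conv),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf(
    "sudden-expansion fit: tau=%.4f theta0=%.4f theta1=%.4f ssd=%.3g hri=%.4f%s\n",
    x$tau, x$theta0, x$theta1, x$ssd, x$hri,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Parametric bootstrap goodness-of-fit for a mismatch fit
#'
#' Simulates `n_reps` coalescent datasets under the fitted expansion
#' parameters (same `n` and `L`), refits each, and reports the fraction of
#' simulated SSD / raggedness statistics at least as large as the observed
#' ones.
#'
#' @param fit a [fit_sudden_expansion()] result.
#' @param n number of sequences of the original sample.
#' @param L alignment length (bp).
#' @param n_reps bootstrap replicates.
#' @param seed RNG seed.
#' @return List with `p_ssd`, `p_hri`, and the simulated statistics.
#' @export
gof_bootstrap <- function(fit, n, L, n_reps = 1000, seed = NULL) {
  if (n_reps < 2) stop("n_reps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  ssd_sim <- hri_sim <- numeric(n_reps)
  for (r in seq_len(n_reps)) {
    aln <- simulate_mtdna(n, expansion = c(fit$tau, fit$theta0, fit$theta1),
                          L = L)
    obs <- observed_mismatch(aln)
    f <- fit_sudden_expansion(obs)
    ssd_sim[r] <- f$ssd
    hri_sim[r] <- f$hri
  }
  list(p_ssd = mean(ssd_sim >= fit$ssd), p_hri = mean(hri_sim >= fit$hri),
       ssd_sim = ssd_sim, hri_sim = hri_sim)
}

#' Molecular clock for expansion dating
#'
#' Default calibration: `mu_site = 2.1e-7` substitutions/site/generation on
#' `L = 1024` bp with a 3.9-year generation, i.e. `2 mu_site L = 4.3008e-4`
#' per generation.
#'
#' @param mu_site substitution rate per site per generation.
#' @param L sequence length (bp).
#' @param gen_years generation time in years.
#' @return A list of class `expansion_clock`.
#' @export
expansion_clock <- function(mu_site = 2.1e-7, L = 1024, gen_years = 3.9) {
  stopifnot(mu_site > 0, L > 0, gen_years > 0)
  structure(list(mu_site = mu_site, L = L, gen_years = gen_years),
            class = "expansion_clock")
}

#' Convert tau to time since expansion
#'
#' `tau = 2 u t` with the per-sequence rate `u = mu_site * L`, so
#' `t = tau / (2 mu_site L)` generations, converted to thousands of years
#' before present and rounded to 2 decimals.
#'
#' @param tau expansion parameter (mutational units).
#' @param clock an [expansion_clock()].
#' @return Expansion time in kyBP (rounded to 2 decimals).
#' @export
expansion_time <- function(tau, clock = expansion_clock()) {
  stopifnot(all(tau >= 0))
  gens <- tau / (2 * clock$mu_site * clock$L)
  round(gens * clock$gen_years / 1000, 2)
}

#' Convert generations to years before present
#' @param generations number of generations.
#' @param gen_years generation time in years (default 3.9).
#' @return Years before present.
#' @export
gens_to_years <- function(generations, gen_years = 3.9) generations * gen_years

#' Per-population mismatch/expansion table
#'
#' Fits the sudden-expansion model per population and converts tau to kyBP.
#'
#' @param aln a [sequence_alignment()] with population labels.
#' @param clock an [expansion_clock()].
#' @param n_boot bootstrap replicates for the goodness-of-fit p-values
#'   (0 = skip).
#' @param seed RNG seed for the bootstrap.
#' @return Data frame with columns `pop`, `N`, `theta0`, `theta1`, `tau`,
#'   `SSD`, `HRI`, `p_SSD`, `p_HRI`, `t_kyBP`.
#' @export
mismatch_table <- function(aln, clock = expansion_clock(), n_boot = 0,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  pops <- unique(aln$pop_labels)
  rows <- lapply(pops, function(p) {
    sub <- subset_alignment(aln, aln$pop_labels == p)
    if (n_sequences(sub) < 3)
      return(data.frame(pop = p, N = n_sequences(sub), theta0 = NA, theta1 = NA,
                        tau = NA, SSD = NA, HRI = NA, p_SSD = NA, p_HRI = NA,
                        t_kyBP = NA))
    fit <- fit_sudden_expansion(observed_mismatch(sub))
    p_ssd <- p_hri <- NA_real_
    if (n_boot > 0) {
      gof <- gof_bootstrap(fit, n_sequences(sub), sub$L, n_reps = n_boot)
      p_ssd <- gof$p_ssd; p_hri <- gof$p_hri
    }
    data.frame(pop = p, N = n_sequences(sub), theta0 = fit$theta0,
               theta1 = fit$theta1, tau = fit$tau, SSD = fit$ssd,
               HRI = fit$hri, p_SSD = p_ssd, p_HRI = p_hri,
               t_kyBP = expansion_time(fit$tau, clock))
  })
  do.call(rbind, rows)
}
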