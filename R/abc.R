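# Approximate Bayesian computation for demographic model choice among the
# three divergence/admixture hypotheses, and regression-adjusted parameter
# estimation, validated with pseudo-observed datasets (PODs).

#' Uniform prior specification for the scenario parameters
#'
#' Independent uniform priors on the 10 scenario parameters (diploid sizes
#' `N_T`, `N_W`, `N_E`, `N_C`; event times `t1 < t2 < t3` in generations,
#' enforced by rejection; admixture fraction `ra`; mean per-locus mutation
#' rate `mu`; GSM geometric parameter `P`). Defaults span the plausible
#' post-glacial ranges for the study system.
#'
#' @param bounds named list of `c(low, high)` pairs; any subset of
#'   `N_T, N_W, N_E, N_C, t1, t2, t3, ra, mu, P` to override the defaults.
#' @return An object of class `prior_spec` (named list of bounds).
#' @export
prior_spec <- function(bounds = list()) {
  def <- list(N_T = c(100, 50000), N_W = c(100, 50000), N_E = c(100, 50000),
              N_C = c(100, 50000), t1 = c(100, 5000), t2 = c(1000, 20000),
              t3 = c(5000, 50000), ra = c(0.05, 0.95), mu = c(1e-4, 1e-3),
              P = c(0, 0.3))
  for (nm in names(bounds)) {
    b <- bounds[[nm]]
    if (!nm %in% names(def)) stop("unknown parameter: ", nm)
    if (length(b) != 2 || b[1] >= b[2]) stop("bad bounds for ", nm)
    def[[nm]] <- as.numeric(b)
  }
  structure(def, class = "prior_spec")
}

#' Well-separated priors for POD validation experiments
#'
#' A prior preset whose event-time windows are pairwise disjoint
#' (`t1` in U\[100, 2500\], `t2` in U\[3000, 8000\], `t3` in
#' U\[10000, 40000\] generations), so the three hypotheses predict
#' distinguishable differentiation patterns while still containing the
#' study-scale posterior point estimates (`t1` about 2140, `t3` about
#' 12600 generations). Sizes are U\[500 or 1000, 20000\] and the mean
#' mutation rate U\[2e-4, 8e-4\].
#'
#' @return A [prior_spec()].
#' @export
validation_priors <- function() {
  prior_spec(list(N_T = c(500, 20000), N_W = c(1000, 20000),
                  N_E = c(1000, 20000), N_C = c(1000, 20000),
                  t1 = c(100, 2500), t2 = c(3000, 8000),
                  t3 = c(10000, 40000), mu = c(2e-4, 8e-4)))
}

#' Draw parameter vectors from the priors
#'
#' I.i.d. uniform draws; triples violating `t1 < t2 < t3` are rejected and
#' redrawn. A warning is issued if fewer than 1\% of raw draws satisfy the
#' ordering constraint.
#'
#' @param spec a [prior_spec()].
#' @param n number of draws.
#' @param seed optional RNG seed.
#' @return Data frame with columns `N_T, N_W, N_E, N_C, t1, t2, t3, ra, mu,
#'   P`.
#' @export
draw_priors <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "prior_spec"), n >= 1)
  if (!is.null(seed)) set.seed(seed)
  draw_block <- function(m) {
    as.data.frame(lapply(spec, function(b) runif(m, b[1], b[2])))
  }
  out <- NULL
  tried <- 0; kept <- 0
  while (is.null(out) || nrow(out) < n) {
    blk <- draw_block(max(n, 1000))
    ok <- blk$t1 < blk$t2 & blk$t2 < blk$t3
    tried <- tried + nrow(blk); kept <- kept + sum(ok)
    out <- rbind(out, blk[ok, , drop = FALSE])
    if (tried >= 1e6 && kept == 0) stop("ordering constraint never satisfied")
  }
  if (kept / tried < 0.01)
    warning("fewer than 1% of prior draws satisfy t1 < t2 < t3")
  out <- out[seq_len(n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Default summary-statistic names (30 statistics, 4 clusters)
#' @return Character vector naming the statistic columns.
#' @export
summary_stat_names <- function() {
  short <- c("T", "W", "E", "C")
  pairs <- c("TW", "TE", "TC", "WE", "WC", "EC")
  c(paste0("NAL_", short), paste0("HET_", short), paste0("VAR_", short),
    paste0("FST_", pairs), paste0("DAS_", pairs), paste0("DM2_", pairs))
}

#' Summary statistics of a microsatellite dataset for ABC
#'
#' The default 30-statistic set: per cluster the mean number of alleles,
#' mean unbiased expected heterozygosity and mean allele-size variance; per
#' cluster pair the multi-locus Weir-Cockerham theta, the mean shared-allele
#' distance between individuals, and Goldstein's (delta-mu)^2. Missing
#' genotypes (allele 0) are excluded.
#'
#' @param G a [genotype_matrix()].
#' @param groups factor/character of cluster membership per individual with
#'   levels in the order Thrace, West, East, CentralAnatolia; defaults to the
#'   population labels of `G`.
#' @return Named numeric vector of length 30.
#' @export
msat_summary_stats <- function(G, groups = NULL) {
  groups <- groups %||% G$pop_labels
  groups <- as.character(groups)
  # canonical cluster order when the labels are the built-in clusters
  lev <- if (all(groups %in% CLUSTERS)) CLUSTERS[CLUSTERS %in% groups] else
    unique(groups)
  if (length(lev) != 4) stop("need exactly four clusters, got ", length(lev))
  ord <- order(match(groups, lev))
  n_ind <- length(groups)
  al <- matrix(0L, 2 * n_ind, length(G$locus_names))
  al[seq(1, 2 * n_ind, 2), ] <- G$a1[ord, , drop = FALSE]
  al[seq(2, 2 * n_ind, 2), ] <- G$a2[ord, , drop = FALSE]
  gsize <- as.integer(table(factor(groups, levels = lev)))
  setNames(summary_stats_cpp(al, gsize), summary_stat_names())
}

#' Build an ABC reference table
#'
#' Draws parameters from the priors for each scenario, simulates a
#' microsatellite dataset per draw with the compiled coalescent engine, and
#' records the summary statistics. Simulations yielding an undefined
#' statistic are re-simulated (fresh randomness, same parameters).
#'
#' @param spec a [prior_spec()].
#' @param scenarios integer vector of hypothesis ids (default `1:3`).
#' @param n_per_scenario simulations per scenario.
#' @param sample_sizes individuals per cluster (length 4).
#' @param n_loci number of loci.
#' @param seed RNG seed.
#' @param bounds allele bounds (repeat units).
#' @param root_allele root allele size.
#' @param missing_rate genotype drop-out rate applied to every simulated
#'   dataset before summarizing, to emulate the observation process of a
#'   dataset with missing genotypes (0 = complete data).
#' @return A list of class `reference_table`: `params` (data frame with a
#'   `scenario` column), `stats` (matrix, columns [summary_stat_names()]),
#'   `sample_sizes`, `n_loci`, `seed`.
#' @export
abc_reference_table <- function(spec, scenarios = 1:3, n_per_scenario = 1000,
                                sample_sizes = c(8, 20, 40, 28), n_loci = 13,
                                seed = NULL, bounds = c(10L, 49L),
                                root_allele = 30L, missing_rate = 0) {
  if (!is.null(seed)) set.seed(seed)
  params <- NULL
  stats <- NULL
  for (s in scenarios) {
    p <- draw_priors(spec, n_per_scenario)
    st <- ref_table_cpp(as.integer(s), as.matrix(p),
                        as.integer(sample_sizes), as.integer(n_loci),
                        as.integer(bounds[1]), as.integer(bounds[2]),
                        as.integer(root_allele), 10L, missing_rate)
    params <- rbind(params, cbind(scenario = s, p))
    stats <- rbind(stats, st)
  }
  colnames(stats) <- summary_stat_names()
  structure(list(params = params, stats = stats, sample_sizes = sample_sizes,
                 n_loci = n_loci, seed = seed, missing_rate = missing_rate),
            class = "reference_table")
}

# median/MAD standardization over the reference table; statistics with
# MAD = 0 are dropped from the distance (reported in `dropped`)
standardize_stats <- function(stats, observed) {
  med <- apply(stats, 2, median)
  madv <- apply(stats, 2, mad)
  keep <- madv > 0
  list(z = sweep(sweep(stats[, keep, drop = FALSE], 2, med[keep]), 2,
                 madv[keep], "/"),
       z_obs = (observed[keep] - med[keep]) / madv[keep],
       keep = keep, dropped = colnames(stats)[!keep])
}

#' ABC rejection step
#'
#' Standardizes every statistic by its reference-table median and MAD,
#' computes Euclidean distances to the observed vector, and retains the
#' `ceiling(tolerance * n)` closest simulations.
#'
#' @param observed named statistic vector (same columns as the table).
#' @param table a [abc_reference_table()].
#' @param tolerance fraction of the table to retain (default 0.01).
#' @return A list of class `abc_rejection`: `index` (row indices of the
#'   retained simulations, closest first), `distance` (their distances),
#'   `z`, `z_obs` (standardized retained statistics and observed vector),
#'   `scenario` (retained scenario ids), `dropped` (statistics with zero
#'   MAD, excluded from the distance).
#' @export
abc_reject <- function(observed, table, tolerance = 0.01) {
  stopifnot(inherits(table, "reference_table"), tolerance > 0, tolerance <= 1)
  std <- standardize_stats(table$stats, observed[colnames(table$stats)])
  d <- sqrt(rowSums(sweep(std$z, 2, std$z_obs)^2))
  keep_n <- ceiling(tolerance * nrow(table$stats))
  o <- order(d)[seq_len(keep_n)]
  structure(list(index = o, distance = d[o],
                 z = std$z[o, , drop = FALSE], z_obs = std$z_obs,
                 scenario = table$params$scenario[o],
                 dropped = std$dropped),
            class = "abc_rejection")
}

#' Direct (frequency) model choice
#'
#' Posterior probability of each scenario as its frequency among the `k`
#' closest simulations, with normal-approximation binomial confidence
#' intervals.
#'
#' @param rejection an [abc_reject()] result (or any object with `scenario`
#'   ordered by distance).
#' @param scenarios scenario ids to report.
#' @param k number of closest points (uses all retained if fewer).
#' @return Data frame `scenario`, `posterior`, `lo`, `hi`, plus attribute
#'   `n_used`.
#' @export
choose_model_direct <- function(rejection, scenarios = 1:3, k = 1000) {
  sc <- rejection$scenario
  n_used <- min(k, length(sc))
  sc <- sc[seq_len(n_used)]
  p <- vapply(scenarios, function(s) mean(sc == s), numeric(1))
  se <- sqrt(pmax(p * (1 - p), 0) / n_used)
  out <- data.frame(scenario = scenarios, posterior = p,
                    lo = pmax(p - qnorm(0.975) * se, 0),
                    hi = pmin(p + qnorm(0.975) * se, 1))
  attr(out, "n_used") <- n_used
  out
}

#' Weighted multinomial-logistic model choice
#'
#' Multinomial logistic regression of the scenario indicator on the
#' standardized summary statistics over the retained simulations, with
#' Epanechnikov weights `1 - (d/d_max)^2`, evaluated at the observed
#' statistics. Confidence intervals come from the delta method on the
#' linear predictors; on numerical failure (e.g. complete separation) the
#' fit is retried with a small weight-decay penalty and flagged.
#'
#' @param rejection an [abc_reject()] result.
#' @param scenarios scenario ids to report.
#' @return Data frame `scenario`, `posterior`, `lo`, `hi`; attribute
#'   `regularized` marks the ridge fallback.
#' @export
choose_model_logistic <- function(rejection, scenarios = 1:3) {
  sc <- factor(rejection$scenario, levels = scenarios)
  if (length(unique(rejection$scenario)) < 2)
    stop("need at least two scenarios among the retained simulations")
  dmax <- max(rejection$distance)
  w <- if (dmax > 0) 1 - (rejection$distance / dmax)^2 else
    rep(1, length(rejection$distance))
  w <- pmax(w, 1e-8)
  df <- data.frame(scenario = sc, rejection$z, check.names = FALSE)
  newd <- as.data.frame(as.list(rejection$z_obs), check.names = FALSE)
  fit_once <- function(decay) {
    suppressWarnings(nnet::multinom(
      scenario ~ ., data = df, weights = w, decay = decay, trace = FALSE,
      maxit = 500, MaxNWts = 5000))
  }
  regularized <- FALSE
  fit <- fit_once(0)
  pr <- tryCatch(predict(fit, newdata = newd, type = "probs"),
                 error = function(e) NULL)
  ci <- multinom_ci(fit, newd, scenarios)
  if (is.null(pr) || any(!is.finite(pr)) || is.null(ci)) {
    regularized <- TRUE
    fit <- fit_once(0.01)
    pr <- predict(fit, newdata = newd, type = "probs")
    ci <- multinom_ci(fit, newd, scenarios)
  }
  # map fitted classes back onto the full scenario set (a scenario absent
  # from the retained simulations gets posterior 0)
  lev_used <- fit$lev
  full <- setNames(rep(0, length(scenarios)), as.character(scenarios))
  if (length(lev_used) == 2) {
    p2 <- as.numeric(pr)[1]        # two-class predict gives P(second level)
    full[lev_used] <- c(1 - p2, p2)
  } else {
    full[lev_used] <- as.numeric(pr)
  }
  full <- full / sum(full)
  lo <- hi <- rep(NA_real_, length(scenarios))
  if (!is.null(ci) && length(ci$lo) == length(lev_used)) {
    lo[match(lev_used, names(full))] <- ci$lo
    hi[match(lev_used, names(full))] <- ci$hi
  }
  out <- data.frame(scenario = scenarios, posterior = unname(full),
                    lo = lo, hi = hi)
  attr(out, "regularized") <- regularized
  out
}

# delta-method CI on multinomial posterior probabilities at one point
multinom_ci <- function(fit, newd, scenarios) {
  out <- tryCatch({
    V <- vcov(fit)
    co <- coef(fit)
    if (is.null(dim(co))) co <- matrix(co, nrow = 1)
    x <- c(1, as.numeric(newd[1, ]))
    eta <- as.numeric(co %*% x)
    p <- c(1, exp(eta)) / (1 + sum(exp(eta)))
    m <- length(eta)
    # d p / d beta_(r,c) ; beta stacked row-major as in vcov(multinom)
    J <- matrix(0, length(p), m * length(x))
    for (r in seq_len(m)) {
      idx <- (r - 1) * length(x) + seq_along(x)
      for (i in seq_along(p)) {
        ind <- as.numeric(i == r + 1)
        J[i, idx] <- p[i] * (ind - p[r + 1]) * x
      }
    }
    se <- sqrt(pmax(diag(J %*% V %*% t(J)), 0))
    list(lo = pmax(p - qnorm(0.975) * se, 0),
         hi = pmin(p + qnorm(0.975) * se, 1), p = p)
  }, error = function(e) NULL)
  out  # CIs for the classes the fit models; caller aligns to the scenario set
}

#' Regression-adjusted parameter estimation
#'
#' Local linear regression in the Beaumont style: each parameter is mapped
#' to the real line by a logit transform to its prior bounds, regressed on
#' the standardized statistics with Epanechnikov weights over the retained
#' simulations of the chosen scenario, and the regression-adjusted values
#' are transformed back (guaranteeing draws inside the prior bounds).
#'
#' @param rejection an [abc_reject()] result.
#' @param table the [abc_reference_table()] used for the rejection.
#' @param spec the [prior_spec()] (for the transform bounds).
#' @param scenario the scenario whose parameters are estimated; retained
#'   rows from other scenarios are ignored.
#' @param parameters which parameters to summarize (default all 10).
#' @return Data frame `parameter`, `median`, `mean`, `q025`, `q975`, plus
#'   attribute `n_used`; attribute `degenerate` flags a fallback to the
#'   unadjusted rejection posterior (zero-variance design).
#' @export
estimate_parameters <- function(rejection, table, spec, scenario,
                                parameters = names(spec)) {
  sel <- rejection$scenario == scenario
  if (!any(sel)) stop("no retained simulations for scenario ", scenario)
  idx <- rejection$index[sel]
  z <- rejection$z[sel, , drop = FALSE]
  dmax <- max(rejection$distance)
  w <- if (dmax > 0) pmax(1 - (rejection$distance[sel] / dmax)^2, 1e-8) else
    rep(1, sum(sel))
  X <- sweep(z, 2, rejection$z_obs)  # centred at the observed point
  degenerate <- all(abs(X) < 1e-12) || nrow(X) <= ncol(X) + 1
  rows <- lapply(parameters, function(pm) {
    b <- spec[[pm]]
    x <- table$params[[pm]][idx]
    u <- (x - b[1]) / (b[2] - b[1])
    u <- pmin(pmax(u, 1e-8), 1 - 1e-8)
    y <- log(u / (1 - u))
    if (!degenerate) {
      fit <- tryCatch(lm(y ~ ., data = data.frame(y = y, X, check.names = FALSE),
                         weights = w),
                      error = function(e) NULL)
      if (!is.null(fit) && all(is.finite(coef(fit)))) {
        beta <- coef(fit)[-1]
        beta[is.na(beta)] <- 0  # singular design: ridge-like drop
        y <- y - as.numeric(as.matrix(X) %*% beta)
      }
    }
    adj <- b[1] + (b[2] - b[1]) / (1 + exp(-y))
    q <- weighted_quantile(adj, w, c(0.5, 0.025, 0.975))
    data.frame(parameter = pm, median = q[1],
               mean = sum(adj * w) / sum(w), q025 = q[2], q975 = q[3])
  })
  out <- do.call(rbind, rows)
  attr(out, "n_used") <- sum(sel)
  attr(out, "degenerate") <- degenerate
  out
}

#' Validation with pseudo-observed datasets (PODs)
#'
#' Simulates PODs with known scenario and parameters, runs model choice for
#' each against a reference table, and reports per-scenario type I error
#' (PODs from the scenario not assigned to it), type II error (PODs from
#' other scenarios assigned to it), and—optionally—per-parameter relative
#' median absolute errors (RMAE) for PODs of `rmae_scenario`.
#'
#' @param table a [abc_reference_table()].
#' @param spec the [prior_spec()] used for the table.
#' @param n_pods PODs per scenario.
#' @param seed RNG seed.
#' @param method `"direct"` or `"logistic"`.
#' @param tolerance rejection tolerance.
#' @param k closest points for the direct method.
#' @param rmae_scenario scenario for parameter-error assessment (NULL =
#'   skip).
#' @return A list of class `pod_report`: `errors` (data frame scenario,
#'   type1, type2), `assignments` (matrix truth x assigned), `rmae`
#'   (data frame or NULL).
#' @export
pod_validation <- function(table, spec, n_pods = 100, seed = NULL,
                           method = c("direct", "logistic"), tolerance = 0.01,
                           k = 1000, rmae_scenario = NULL) {
  method <- match.arg(method)
  if (!is.null(seed)) set.seed(seed)
  scenarios <- sort(unique(table$params$scenario))
  ns <- length(scenarios)
  assign_mat <- matrix(0L, ns, ns, dimnames = list(truth = scenarios,
                                                   assigned = scenarios))
  rmae_list <- list()
  for (si in seq_along(scenarios)) {
    s <- scenarios[si]
    pars <- draw_priors(spec, n_pods)
    for (r in seq_len(n_pods)) {
      sc <- scenario_spec(s, as.numeric(pars[r, c("N_T", "N_W", "N_E", "N_C")]),
                          pars$t1[r], pars$t2[r], pars$t3[r], pars$ra[r])
      mm <- mutation_model(pars$mu[r], pars$P[r])
      G <- simulate_msat_dataset(sc, mm, table$sample_sizes, table$n_loci)
      obs <- msat_summary_stats(G)
      rej <- abc_reject(obs, table, tolerance)
      post <- if (method == "direct") choose_model_direct(rej, scenarios, k)
              else choose_model_logistic(rej, scenarios)
      pick <- scenarios[which.max(post$posterior)]
      assign_mat[si, match(pick, scenarios)] <-
        assign_mat[si, match(pick, scenarios)] + 1L
      if (!is.null(rmae_scenario) && s == rmae_scenario) {
        est <- tryCatch(
          estimate_parameters(rej, table, spec, scenario = s),
          error = function(e) NULL)
        if (!is.null(est)) {
          truth <- as.numeric(pars[r, est$parameter])
          err <- ifelse(truth != 0, abs(est$median - truth) / abs(truth),
                        abs(est$median - truth))
          rmae_list[[length(rmae_list) + 1L]] <-
            setNames(err, est$parameter)
        }
      }
    }
  }
  type1 <- 1 - diag(assign_mat) / n_pods
  type2 <- vapply(seq_along(scenarios), function(i)
    sum(assign_mat[-i, i]) / (n_pods * (ns - 1)), numeric(1))
  rmae <- NULL
  if (length(rmae_list)) {
    em <- do.call(rbind, rmae_list)
    rmae <- data.frame(parameter = colnames(em),
                       rmae = apply(em, 2, median), row.names = NULL)
  }
  structure(list(errors = data.frame(scenario = scenarios, type1 = type1,
                                     type2 = type2),
                 assignments = assign_mat, rmae = rmae),
            class = "pod_report")
}

#' PCA goodness-of-fit projection
#'
#' Principal components of the standardized reference-table statistics, with
#' the observed vector (and optionally posterior-predictive simulations)
#' projected into the same space.
#'
#' @param table a [abc_reference_table()].
#' @param observed named statistic vector.
#' @param posterior_stats optional matrix of posterior-predictive statistic
#'   vectors.
#' @return List with `table_coords`, `observed_coords`, `posterior_coords`
#'   (first two PCs), and the proportion of variance explained.
#' @export
gof_pca <- function(table, observed, posterior_stats = NULL) {
  std <- standardize_stats(table$stats, observed[colnames(table$stats)])
  if (ncol(std$z) < 2) stop("fewer than two informative statistics")
  pc <- prcomp(std$z, center = TRUE, scale. = FALSE)
  proj <- function(zrow) {
    sweep(matrix(zrow, ncol = ncol(std$z), byrow = TRUE), 2, pc$center) %*%
      pc$rotation[, 1:2]
  }
  post <- NULL
  if (!is.null(posterior_stats)) {
    zp <- sweep(sweep(posterior_stats[, std$keep, drop = FALSE], 2,
                      apply(table$stats[, std$keep, drop = FALSE], 2, median)),
                2, apply(table$stats[, std$keep, drop = FALSE], 2, mad), "/")
    post <- sweep(zp, 2, pc$center) %*% pc$rotation[, 1:2]
  }
  list(table_coords = pc$x[, 1:2], observed_coords = proj(std$z_obs),
       posterior_coords = post,
       var_explained = (pc$sdev^2 / sum(pc$sdev^2))[1:2])
}
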