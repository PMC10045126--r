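# Sequence summary statistics. Sites where either sequence of a pair carries
# "N" or "-" are excluded pairwise from distances, d and pi ("pairwise
# deletion"); haplotypes are distinguished over all columns.

pairwise_diff_counts <- function(aln) {
  m <- seq_matrix(aln)
  n <- nrow(m)
  ok <- m == "A" | m == "C" | m == "G" | m == "T"
  diffs <- comp <- matrix(0, n, n)
  for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, n)) {
    use <- ok[i, ] & ok[j, ]
    comp[i, j] <- comp[j, i] <- sum(use)
    diffs[i, j] <- diffs[j, i] <- sum(m[i, use] != m[j, use])
  }
  list(diffs = diffs, comparable = comp)
}

#' Haplotype collapse and diversity indices
#'
#' Computes the standard per-population mtDNA diversity summary: haplotype
#' counts without gaps (`k`, after dropping every column containing a gap)
#' and with gaps (`K`), haplotype diversity `h = n(1 - sum p_i^2)/(n - 1)`,
#' segregating sites `s` (over `A/C/G/T` only), nucleotide diversity per site
#' `pi`, and the mean number of pairwise differences `d` (pairwise deletion).
#'
#' @param aln a [sequence_alignment()].
#' @return A list of class `diversity_summary` with elements `n`, `k`, `K`,
#'   `h`, `s`, `pi`, `d`. With fewer than two sequences `h`, `pi` and `d` are
#'   `NA` and the summary carries `flag = "n<2"`.
#' @export
collapse_and_diversity <- function(aln) {
  n <- n_sequences(aln)
  if (n == 0) stop("empty alignment")
  m <- seq_matrix(aln)
  K <- length(unique(aln$sequences))
  gapless <- m[, !apply(m == "-", 2, any), drop = FALSE]
  k <- length(unique(apply(gapless, 1, paste, collapse = "")))
  site_seg <- apply(m, 2, function(col) {
    b <- col[col %in% c("A", "C", "G", "T")]
    length(unique(b)) >= 2
  })
  s <- sum(site_seg)
  if (n < 2) {
    out <- list(n = n, k = k, K = K, h = NA_real_, s = s, pi = NA_real_,
                d = NA_real_, flag = "n<2")
    class(out) <- "diversity_summary"
    return(out)
  }
  p <- table(aln$sequences) / n
  h <- n * (1 - sum(p^2)) / (n - 1)
  pd <- pairwise_diff_counts(aln)
  ut <- upper.tri(pd$diffs)
  d <- mean(pd$diffs[ut])
  persite <- pd$diffs[ut] / pmax(pd$comparable[ut], 1)
  pi <- mean(persite)
  out <- list(n = n, k = k, K = K, h = h, s = s, pi = pi, d = d, flag = NULL)
  class(out) <- "diversity_summary"
  out
}

#' Kimura two-parameter distance between two aligned sequences
#'
#' `d = -log(1 - 2P - Q)/2 - log(1 - 2Q)/4` where `P` and `Q` are the
#' transition and transversion proportions over comparable sites (both bases
#' in `A/C/G/T`).
#'
#' @param s1,s2 equal-length sequence strings.
#' @return The K2P distance (substitutions/site).
#' @export
k2p_distance <- function(s1, s2) {
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length")
  ok <- a %in% c("A", "C", "G", "T") & b %in% c("A", "C", "G", "T")
  nc <- sum(ok)
  if (nc == 0) stop("no comparable sites")
  a <- a[ok]; b <- b[ok]
  diff <- a != b
  purine <- function(x) x %in% c("A", "G")
  ts <- diff & (purine(a) == purine(b))
  P <- sum(ts) / nc
  Q <- sum(diff & !ts) / nc
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    stop("K2P saturation: 1-2P-Q or 1-2Q is non-positive")
  -log(w1) / 2 - log(w2) / 4
}

#' Pairwise distance matrix for an alignment
#'
#' @param aln a [sequence_alignment()].
#' @param model `"k2p"` (Kimura two-parameter), `"raw"` (differences per
#'   comparable site) or `"diff"` (absolute difference counts).
#' @return Symmetric numeric matrix with sample ids as dimnames.
#' @export
pairwise_dist_matrix <- function(aln, model = c("k2p", "raw", "diff")) {
  model <- match.arg(model)
  n <- n_sequences(aln)
  out <- matrix(0, n, n, dimnames = list(aln$sample_ids, aln$sample_ids))
  if (model == "k2p") {
    for (i in seq_len(max(n - 1, 0))) for (j in seq(i + 1, n))
      out[i, j] <- out[j, i] <- k2p_distance(aln$sequences[i], aln$sequences[j])
  } else {
    pd <- pairwise_diff_counts(aln)
    out <- if (model == "diff") pd$diffs else pd$diffs / pmax(pd$comparable, 1)
    dimnames(out) <- list(aln$sample_ids, aln$sample_ids)
  }
  out
}

# Tajima (1989) constants for sample size n
tajima_constants <- function(n) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D
#'
#' `D = (d - s/a1) / sqrt(e1 s + e2 s (s-1))` with the Tajima (1989)
#' constants; `d` is the mean number of pairwise differences and `s` the
#' number of segregating sites. With `s = 0` the statistic is undefined and
#' `NA` is returned (never 0).
#'
#' @param aln a [sequence_alignment()] with at least 2 sequences.
#' @return Tajima's D, or `NA_real_` when undefined.
#' @export
tajimas_d <- function(aln) {
  n <- n_sequences(aln)
  if (n < 2) return(NA_real_)
  dv <- collapse_and_diversity(aln)
  s <- dv$s
  if (s == 0) return(NA_real_)
  cst <- tajima_constants(n)
  v <- cst$e1 * s + cst$e2 * s * (s - 1)
  if (!is.finite(v) || v <= 0) return(NA_real_)  # degenerate variance (n = 2)
  (dv$d - s / cst$a1) / sqrt(v)
}

# log unsigned Stirling numbers of the first kind, row n (k = 1..n), by the
# recurrence |S(n,k)| = |S(n-1,k-1)| + (n-1)|S(n-1,k)| carried in log space
log_stirling_row <- function(n) {
  row <- 0  # n = 1: |S(1,1)| = 1
  if (n == 1) return(row)
  for (m in 2:n) {
    prev <- row
    row <- numeric(m)
    row[1] <- log(m - 1) + prev[1]
    if (m > 2)
      for (k in 2:(m - 1))
        row[k] <- logsumexp(c(prev[k - 1], log(m - 1) + prev[k]))
    row[m] <- prev[m - 1]
  }
  row
}

# P(K = k | theta, n) for k = 1..n under the Ewens sampling distribution
ewens_k_pmf <- function(n, theta) {
  ls <- log_stirling_row(n)
  lp <- ls + seq_len(n) * log(theta) - sum(log(theta + 0:(n - 1)))
  exp(lp - logsumexp(lp))  # guard rounding; exact up to numerics
}

#' Fu's Fs
#'
#' `Fs = log(S'/(1 - S'))` where `S' = P(K >= k_obs | theta, n)` under the
#' Ewens sampling distribution, with `theta` estimated by the mean number of
#' pairwise differences `d` (Fu 1997 convention). Undefined when `d = 0`;
#' `S'` hitting 0 or 1 numerically yields a signed infinity.
#'
#' @param aln a [sequence_alignment()].
#' @param k_obs observed number of distinct haplotypes; defaults to the
#'   with-gap haplotype count of `aln`.
#' @param theta optional override of the `theta` estimate.
#' @return Fu's Fs (possibly `Inf`/`-Inf`), or `NA_real_` when undefined.
#' @export
fus_fs <- function(aln, k_obs = NULL, theta = NULL) {
  n <- n_sequences(aln)
  if (n < 2) return(NA_real_)
  dv <- collapse_and_diversity(aln)
  theta <- theta %||% dv$d
  k_obs <- k_obs %||% dv$K
  if (!is.finite(theta) || theta <= 0) return(NA_real_)
  pmf <- ewens_k_pmf(n, theta)
  sprime <- sum(pmf[k_obs:n])
  if (sprime >= 1) return(Inf)
  if (sprime <= 0) return(-Inf)
  log(sprime / (1 - sprime))
}

#' Per-population diversity and neutrality table
#'
#' @param aln a [sequence_alignment()] with population labels.
#' @return Data frame with one row per population (first-appearance order):
#'   `N`, `k`, `K`, `h`, `s`, `pi`, `d`, `tajima_d`, `fu_fs`.
#' @export
diversity_table <- function(aln) {
  pops <- unique(aln$pop_labels)
  rows <- lapply(pops, function(p) {
    sub <- subset_alignment(aln, aln$pop_labels == p)
    dv <- collapse_and_diversity(sub)
    data.frame(pop = p, N = dv$n, k = dv$k, K = dv$K, h = dv$h, s = dv$s,
               pi = dv$pi, d = dv$d,
               tajima_d = if (dv$n >= 2) tajimas_d(sub) else NA_real_,
               fu_fs = if (dv$n >= 2) fus_fs(sub) else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
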