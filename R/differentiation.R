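# Population differentiation: distance-based Phi-ST from an AMOVA on squared
# haplotype distances, and the Weir-Cockerham theta estimator of F-ST for
# microsatellites. Negative estimates are reported as computed (not truncated)
# so downstream bootstraps see the full estimator distribution.

# AMOVA variance components for a set of populations, from a full squared
# distance matrix. Populations of size 1 contribute no within-group pairs.
amova_phist <- function(d2, groups) {
  groups <- as.character(groups)
  sizes <- table(groups)[unique(groups)]
  N <- length(groups)
  K <- length(sizes)
  ss_t <- sum(d2[upper.tri(d2)]) / N
  ss_w <- 0
  for (g in names(sizes)) {
    idx <- which(groups == g)
    if (length(idx) > 1)
      ss_w <- ss_w + sum(d2[idx, idx][upper.tri(d2[idx, idx])]) / length(idx)
  }
  ss_a <- ss_t - ss_w
  df_a <- K - 1
  df_w <- N - K
  if (df_w <= 0) return(list(phist = NA_real_, sigma_a = NA_real_,
                             sigma_w = NA_real_, flag = "no within-group pairs"))
  ms_w <- ss_w / df_w
  ms_a <- ss_a / df_a
  n_prime <- (N - sum(sizes^2) / N) / df_a
  sigma_a <- (ms_a - ms_w) / n_prime
  sigma_w <- ms_w
  denom <- sigma_a + sigma_w
  phist <- if (denom == 0) 0 else sigma_a / denom
  list(phist = phist, sigma_a = sigma_a, sigma_w = sigma_w,
       flag = if (any(sizes == 1)) "population of size 1" else NULL)
}

#' Pairwise Phi-ST matrix from haplotype distances
#'
#' For every population pair, Phi-ST is the among-population fraction of
#' molecular variance from an AMOVA on squared inter-haplotype distances
#' (K2P by default). Negative values are reported as computed. Optional
#' permutation p-values shuffle individuals between the two populations.
#'
#' @param aln a [sequence_alignment()] with >= 2 populations.
#' @param model distance model passed to [pairwise_dist_matrix()]; `"diff"`
#'   uses raw difference counts, `"haplotype"` scores 0/1 haplotype identity
#'   (frequency-based F-ST).
#' @param n_perm permutations per pair for p-values (0 = none).
#' @param seed optional RNG seed for the permutations.
#' @return A list with `phist` (symmetric matrix, populations in
#'   first-appearance order) and `p` (matrix of permutation p-values or NULL).
#' @export
phist_matrix <- function(aln, model = c("k2p", "raw", "diff", "haplotype"),
                         n_perm = 0, seed = NULL) {
  model <- match.arg(model)
  pops <- unique(aln$pop_labels)
  if (length(pops) < 2) stop("need at least two populations")
  if (!is.null(seed)) set.seed(seed)
  d <- if (model == "haplotype") {
    outer(aln$sequences, aln$sequences, `!=`) * 1
  } else {
    pairwise_dist_matrix(aln, model)
  }
  d2 <- d^2
  K <- length(pops)
  phi <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  diag(phi) <- 0
  pmat <- if (n_perm > 0) phi else NULL
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    idx <- which(aln$pop_labels %in% pops[c(i, j)])
    g <- aln$pop_labels[idx]
    sub <- d2[idx, idx, drop = FALSE]
    obs <- amova_phist(sub, g)$phist
    phi[i, j] <- phi[j, i] <- obs
    if (n_perm > 0) {
      cnt <- 0L
      for (r in seq_len(n_perm)) {
        perm <- amova_phist(sub, sample(g))$phist
        if (!is.na(perm) && perm >= obs) cnt <- cnt + 1L
      }
      pmat[i, j] <- pmat[j, i] <- (cnt + 1) / (n_perm + 1)
    }
  }
  list(phist = phi, p = pmat)
}

#' Per-population microsatellite summaries
#'
#' Observed heterozygosity is the fraction of scored genotypes that are
#' heterozygous; expected heterozygosity is the unbiased
#' `2n/(2n-1) (1 - sum p_i^2)` averaged over scored loci;
#' `FIS = 1 - Ho/He` (undefined when `He = 0`). Missing genotypes are
#' excluded locus-wise.
#'
#' @param G a [genotype_matrix()].
#' @return Data frame with one row per population: `pop`, `N`, `Na` (total
#'   alleles), `mean_alleles` (per locus), `Ho`, `He`, `FIS`.
#' @export
msat_summaries <- function(G) {
  pops <- populations(G)
  rows <- lapply(pops, function(p) {
    idx <- which(G$pop_labels == p)
    ho <- he <- rep(NA_real_, length(G$locus_names))
    nal <- rep(NA_real_, length(G$locus_names))
    all_alleles <- integer(0)
    for (l in seq_along(G$locus_names)) {
      a1 <- G$a1[idx, l]; a2 <- G$a2[idx, l]
      sc <- a1 != 0L
      if (!any(sc)) next
      alleles <- c(a1[sc], a2[sc])
      all_alleles <- union(all_alleles, alleles)
      nal[l] <- length(unique(alleles))
      ho[l] <- mean(a1[sc] != a2[sc])
      nc <- length(alleles)
      if (nc >= 2) {
        pr <- table(alleles) / nc
        he[l] <- nc / (nc - 1) * (1 - sum(pr^2))
      }
    }
    Ho <- mean(ho, na.rm = TRUE)
    He <- mean(he, na.rm = TRUE)
    data.frame(pop = p, N = length(idx), Na = length(all_alleles),
               mean_alleles = mean(nal, na.rm = TRUE), Ho = Ho, He = He,
               FIS = if (is.finite(He) && He > 0) 1 - Ho / He else NA_real_,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Weir-Cockerham (1984) variance components for one allele at one locus in
# two populations; n1, n2 = scored individuals, p = allele freqs, h = observed
# heterozygote-carrier frequencies.
wc_components <- function(n1, n2, p1, p2, h1, h2) {
  nbar <- (n1 + n2) / 2
  nc <- (n1 + n2) - (n1^2 + n2^2) / (n1 + n2)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / nbar
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - s2 / 2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - s2 / 2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c <- hbar / 2
  c(a = a, b = b, c = c)
}

# multi-locus WC theta for one population pair within a genotype matrix
wc_theta_pair <- function(G, idx1, idx2) {
  sum_a <- sum_abc <- 0
  scored <- FALSE
  for (l in seq_along(G$locus_names)) {
    s1 <- which(G$a1[idx1, l] != 0L)
    s2 <- which(G$a1[idx2, l] != 0L)
    n1 <- length(s1); n2 <- length(s2)
    if (n1 < 2 || n2 < 2) next
    g1 <- cbind(G$a1[idx1[s1], l], G$a2[idx1[s1], l])
    g2 <- cbind(G$a1[idx2[s2], l], G$a2[idx2[s2], l])
    alleles <- sort(unique(c(g1, g2)))
    if (length(alleles) < 2) { scored <- TRUE; next }
    scored <- TRUE
    for (A in alleles) {
      p1 <- mean(g1 == A); p2 <- mean(g2 == A)
      h1 <- mean((g1[, 1] == A) != (g1[, 2] == A))
      h2 <- mean((g2[, 1] == A) != (g2[, 2] == A))
      comp <- wc_components(n1, n2, p1, p2, h1, h2)
      sum_a <- sum_a + comp["a"]
      sum_abc <- sum_abc + sum(comp)
    }
  }
  if (!scored) return(NA_real_)         # no co-scored locus
  if (sum_abc == 0) return(0)           # monomorphic throughout
  unname(sum_a / sum_abc)
}

#' Pairwise Weir-Cockerham F-ST matrix for microsatellites
#'
#' Multi-locus ratio-of-sums theta estimator (Weir & Cockerham 1984);
#' missing genotypes are excluded per locus; a pair with no co-scored locus
#' gets `NA`.
#'
#' @param G a [genotype_matrix()] with >= 2 populations.
#' @return Symmetric matrix of theta estimates, populations in
#'   first-appearance order.
#' @export
wc_fst <- function(G) {
  pops <- populations(G)
  if (length(pops) < 2) stop("need at least two populations")
  K <- length(pops)
  th <- matrix(NA_real_, K, K, dimnames = list(pops, pops))
  diag(th) <- 0
  for (i in seq_len(K - 1)) for (j in seq(i + 1, K)) {
    th[i, j] <- th[j, i] <-
      wc_theta_pair(G, which(G$pop_labels == pops[i]),
                    which(G$pop_labels == pops[j]))
  }
  th
}
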