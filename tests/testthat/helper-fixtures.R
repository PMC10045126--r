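# In-code fixtures shared across the suite.

# small alignment from explicit sequence strings
toy_alignment <- function(seqs, pops = "pop1", ids = NULL) {
  ids <- ids %||% paste0("s", seq_along(seqs))
  sequence_alignment(ids, seqs, pops)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# random related alignment: sequences derived from a shared root with a
# small per-sequence substitution rate (keeps K2P far from saturation)
random_alignment <- function(n, L, seed = 1, gap_rate = 0, pops = "pop1",
                             mut = 0.03) {
  set.seed(seed)
  alpha <- c("A", "C", "G", "T")
  root <- sample(alpha, L, replace = TRUE)
  m <- matrix(root, n, L, byrow = TRUE)
  hit <- matrix(runif(n * L) < mut, n, L)
  if (any(hit)) m[hit] <- sample(alpha, sum(hit), replace = TRUE)
  if (gap_rate > 0) m[runif(n * L) < gap_rate] <- "-"
  toy_alignment(apply(m, 1, paste, collapse = ""), pops)
}

# write a GenePop toy file: list of populations, each a named list of
# genotype-string vectors (3-digit coding)
write_genepop_text <- function(path, loci, pops, eol = "\n") {
  lines <- c("toy data", loci)
  for (p in names(pops)) {
    lines <- c(lines, "Pop")
    for (id in names(pops[[p]]))
      lines <- c(lines, paste0(id, " , ", paste(pops[[p]][[id]], collapse = " ")))
  }
  con <- file(path, "wb")
  writeBin(charToRaw(paste0(paste(lines, collapse = eol), eol)), con)
  close(con)
  path
}

# four-population scenario with all sizes equal (panmictic when times ~ 0)
flat_scenario <- function(N = 5000, t1 = 1e-6, t2 = 2e-6, t3 = 3e-6, ra = 0.5,
                          hyp = 2) {
  scenario_spec(hyp, N = rep(N, 4), t1 = t1, t2 = t2, t3 = t3, ra = ra)
}

# brute-force Ewens P(K = k) via polynomial expansion of the rising
# factorial theta (theta+1) ... (theta+n-1): an independent oracle for the
# log-space Stirling recurrence inside fus_fs()
ewens_pmf_bruteforce <- function(n, theta) {
  co <- 1  # coefficients of the polynomial in theta, constant first
  for (m in 0:(n - 1)) co <- c(0, co) + c(co * m, 0)  # multiply by (theta + m)
  k <- seq_len(n)
  stirling <- co[k + 1]  # |S(n, k)| = coefficient of theta^k
  p <- stirling * theta^k / prod(theta + 0:(n - 1))
  p / sum(p)
}

fs_bruteforce <- function(n, k_obs, theta) {
  p <- ewens_pmf_bruteforce(n, theta)
  sp <- sum(p[k_obs:n])
  log(sp / (1 - sp))
}
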