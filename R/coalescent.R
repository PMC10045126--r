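# R surface over the compiled coalescent engine, plus the haploid mtDNA
# simulator (pure R; sample sizes are small). Populations follow the fixed
# cluster order Thrace, West, East, CentralAnatolia; East carries the
# ancestral lineage after the final merge.

#' Demographic scenario for the four-population system
#'
#' Encodes one of the three divergence/admixture hypotheses (backwards in
#' time):
#' * hypothesis 1: Central Anatolia formed by admixture at `t1`
#'   (West fraction `ra`), West merges into East at `t2`, Thrace at `t3`;
#' * hypothesis 2: admixture at `t1`, then Thrace and West both merge into
#'   East simultaneously at `t3` (`t2` unused);
#' * hypothesis 3: admixture at `t1`, Thrace merges into West at `t2`,
#'   West into East at `t3`.
#'
#' @param hypothesis 1, 2 or 3.
#' @param N diploid effective sizes, length 4, order Thrace, West, East,
#'   CentralAnatolia.
#' @param t1,t2,t3 event times in generations, `0 < t1 < t2 < t3`.
#' @param ra admixture fraction contributed by West, in `[0, 1]`.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(hypothesis, N, t1, t2, t3, ra) {
  stopifnot(hypothesis %in% 1:3, length(N) == 4, all(N > 0),
            t1 > 0, t2 > t1, t3 > t2 || (hypothesis == 2 && t3 > t1),
            ra >= 0, ra <= 1)
  structure(list(hypothesis = as.integer(hypothesis), N = as.numeric(N),
                 t1 = t1, t2 = t2, t3 = t3, ra = ra,
                 populations = CLUSTERS),
            class = "scenario_spec")
}

#' Microsatellite mutation model
#'
#' Strict stepwise (SMM, +-1 repeat) or generalized stepwise (GSM, step
#' length `1 + Geometric(P)`, mean `1/(1-P)`), symmetric in direction, with
#' allele sizes reflected into `[bounds[1], bounds[2]]` (40 contiguous
#' states by default).
#'
#' @param mu mutation rate per locus per generation.
#' @param P geometric parameter in `[0, 1)`; 0 gives the strict SMM.
#' @param bounds allele bounds in repeat units.
#' @return An object of class `mutation_model`.
#' @export
mutation_model <- function(mu, P = 0, bounds = c(10L, 49L)) {
  stopifnot(mu >= 0, P >= 0, P < 1, length(bounds) == 2, bounds[1] < bounds[2])
  structure(list(kind = if (P == 0) "smm" else "gsm", mu = mu, P = P,
                 bounds = as.integer(bounds)),
            class = "mutation_model")
}

#' Simulate one genealogy under a scenario
#'
#' Backwards-in-time structured coalescent: within each population, pairs
#' coalesce at rate `1/(2N)` per generation; splits move lineages to the
#' receiving population; the admixture event assigns each Central Anatolian
#' lineage to West with probability `ra`, else East.
#'
#' @param scenario a [scenario_spec()].
#' @param sample_copies sampled gene copies per population (length 4).
#' @param seed optional RNG seed.
#' @return A list: `parent` (0-based parent index per node, -1 at the root),
#'   `time` (node times in generations), `leaf_pop` (0-based population per
#'   leaf), `n_leaves`.
#' @export
simulate_genealogy <- function(scenario, sample_copies, seed = NULL) {
  stopifnot(inherits(scenario, "scenario_spec"), length(sample_copies) == 4)
  if (sum(sample_copies) < 2) stop("need at least two sampled lineages")
  if (!is.null(seed)) set.seed(seed)
  sim_genealogy_cpp(scenario$hypothesis, scenario$N, scenario$t1, scenario$t2,
                    scenario$t3, scenario$ra, as.integer(sample_copies))
}

#' Drop microsatellite mutations on a genealogy
#'
#' Poisson(`mu` x branch length) mutations per branch; each mutation steps
#' the allele by +-1 (SMM) or +-(1 + Geometric(P)) (GSM), reflected at the
#' allele bounds.
#'
#' @param genealogy result of [simulate_genealogy()].
#' @param model a [mutation_model()].
#' @param root_allele allele size at the root.
#' @param seed optional RNG seed.
#' @return Integer vector of allele sizes, one per leaf.
#' @export
mutate_microsat <- function(genealogy, model, root_allele = 30L, seed = NULL) {
  stopifnot(inherits(model, "mutation_model"))
  if (!is.null(seed)) set.seed(seed)
  mutate_msat_cpp(genealogy$parent, genealogy$time, genealogy$n_leaves,
                  model$mu, model$P, as.integer(root_allele),
                  model$bounds[1], model$bounds[2])
}

#' Simulate a diploid multi-locus microsatellite dataset
#'
#' Loci are unlinked (independent genealogies); each individual carries two
#' independent gene copies.
#'
#' @param scenario a [scenario_spec()].
#' @param model a [mutation_model()].
#' @param sample_sizes individuals per population (length 4, order Thrace,
#'   West, East, CentralAnatolia).
#' @param n_loci number of loci.
#' @param seed optional RNG seed.
#' @param root_allele root allele size.
#' @return A [genotype_matrix()] with the cluster names as population labels.
#' @export
simulate_msat_dataset <- function(scenario, model, sample_sizes, n_loci = 13,
                                  seed = NULL, root_allele = 30L) {
  stopifnot(inherits(scenario, "scenario_spec"),
            inherits(model, "mutation_model"), length(sample_sizes) == 4)
  if (!is.null(seed)) set.seed(seed)
  al <- sim_msat_dataset_cpp(scenario$hypothesis, scenario$N, scenario$t1,
                             scenario$t2, scenario$t3, scenario$ra, model$mu,
                             model$P, as.integer(n_loci),
                             as.integer(sample_sizes), model$bounds[1],
                             model$bounds[2], as.integer(root_allele))
  n_ind <- sum(sample_sizes)
  a1 <- al[seq(1, 2 * n_ind, 2), , drop = FALSE]
  a2 <- al[seq(2, 2 * n_ind, 2), , drop = FALSE]
  pops <- rep(CLUSTERS, times = sample_sizes)
  genotype_matrix(sprintf("ind%04d", seq_len(n_ind)),
                  sprintf("locus%02d", seq_len(n_loci)), a1, a2, pops)
}

# --- haploid mtDNA simulator -------------------------------------------------

# Kingman coalescent node times in mutational units (1 unit = 1/(2u)
# generations): pair rate 1/theta1 until `tau`, then 1/theta0 (constant size:
# rate 1/theta throughout). Returns parent/time arrays like the msat engine.
mtdna_tree <- function(n, theta, expansion = NULL) {
  parent <- rep(-1L, 2L * n - 1L)
  time <- numeric(2L * n - 1L)
  act <- seq_len(n) - 1L
  t <- 0
  nxt <- n
  change <- if (is.null(expansion)) Inf else expansion[1]
  th_now <- if (is.null(expansion)) theta else expansion[3]
  th_old <- if (is.null(expansion)) theta else expansion[2]
  while (length(act) > 1) {
    k <- length(act)
    th <- if (t < change) th_now else th_old
    if (th <= 0) { dt <- 0 } else {
      rate <- k * (k - 1) / 2 / th
      dt <- rexp(1, rate)
    }
    if (t < change && t + dt > change && th_old != th_now) {
      t <- change  # re-draw under the pre-expansion rate (memorylessness)
      next
    }
    t <- t + dt
    pick <- sample.int(k, 2)
    parent[act[pick] + 1L] <- nxt
    time[nxt + 1L] <- t
    act <- c(act[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time, n_leaves = n)
}

#' Simulate an mtDNA alignment under a constant-size or sudden-expansion
#' coalescent
#'
#' Haploid coalescent in mutational time units: under constant size the
#' scaled parameter `theta` is the expected number of pairwise differences;
#' under `expansion = c(tau, theta0, theta1)` the pair coalescence rate is
#' `1/theta1` more recently than `tau` and `1/theta0` beyond. Mutations are
#' Poisson(branch length / 2) per branch, placed on distinct positions of an
#' `L`-site sequence (infinite sites; positions are reused with a warning
#' once exhausted), with transition:transversion odds `tstv`:1.
#'
#' @param n number of sequences.
#' @param theta scaled mutation parameter (constant-size model).
#' @param expansion optional `c(tau, theta0, theta1)` overriding `theta`.
#' @param L sequence length (bp).
#' @param seed optional RNG seed.
#' @param tstv transition:transversion odds (default 10, Cyt-b-like).
#' @param root_seq optional ancestral sequence string (length `L`); random
#'   when omitted.
#' @param pop population label for the sampled sequences.
#' @param id_prefix prefix for sample ids.
#' @return A [sequence_alignment()].
#' @export
simulate_mtdna <- function(n, theta = NULL, expansion = NULL, L = 1014,
                           seed = NULL, tstv = 10, root_seq = NULL,
                           pop = "pop1", id_prefix = "seq") {
  if (is.null(theta) && is.null(expansion)) stop("give theta or expansion")
  if (!is.null(expansion)) stopifnot(length(expansion) == 3, all(expansion >= 0))
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  root <- if (is.null(root_seq)) sample(bases, L, replace = TRUE) else {
    r <- strsplit(toupper(root_seq), "")[[1]]
    stopifnot(length(r) == L)
    r
  }
  if (n == 1) {
    return(sequence_alignment(paste0(id_prefix, 1), paste(root, collapse = ""), pop))
  }
  tr <- mtdna_tree(n, theta, expansion)
  m <- 2L * n - 1L
  seqs <- vector("list", m)
  seqs[[m]] <- root
  unused <- sample.int(L)  # random site order for infinite-sites placement
  upos <- 1L
  exhausted <- FALSE
  for (node in (m - 1L):1L) {
    par <- tr$parent[node] + 1L
    len <- tr$time[par] - tr$time[node]
    s <- seqs[[par]]
    nm <- rpois(1, len / 2)
    for (mu in seq_len(nm)) {
      if (upos <= L) {
        site <- unused[upos]; upos <- upos + 1L
      } else {
        site <- sample.int(L, 1); exhausted <- TRUE
      }
      b <- s[site]
      s[site] <- if (runif(1) < tstv / (tstv + 1)) transition[[b]] else
        sample(setdiff(bases, c(b, transition[[b]])), 1)
    }
    seqs[[node]] <- s
  }
  if (exhausted)
    warning("more mutations than sites: positions re-used")
  sequence_alignment(paste0(id_prefix, seq_len(n)),
                     vapply(seqs[seq_len(n)], paste, "", collapse = ""), pop)
}
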