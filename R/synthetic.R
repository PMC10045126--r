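# Study-shaped synthetic data: 16 populations grouped into the four genetic
# clusters (Thrace: pop 1; West: pops 2-5; East: pops 9-14; Central Anatolia:
# pops 6-8, 15, 16), mtDNA under per-population sudden-expansion coalescents
# from a shared ancestral sequence, microsatellites under a divergence/
# admixture scenario truth, uniform missingness, and an optional divergent
# contaminant haplogroup.

# cluster membership of the 16 populations
POP_CLUSTER <- c("Thrace", "West", "West", "West", "West",
                 "CentralAnatolia", "CentralAnatolia", "CentralAnatolia",
                 "East", "East", "East", "East", "East", "East",
                 "CentralAnatolia", "CentralAnatolia")

#' Configuration of a study-shaped synthetic dataset
#'
#' Defaults emulate the 16-population design: per-population mtDNA sample
#' sizes of 9-22 sequences (277 in total) of 1014 bp, 347 diploid
#' individuals at 13 microsatellite loci with a 22\% uniform missing rate,
#' a contaminant haplogroup at frequency 23/277, and a simultaneous-
#' divergence truth scenario (hypothesis 2; `t3 = 12600`, `t1 = 2140`
#' generations, `ra = 0.5`).
#'
#' @param n_populations number of populations (fixed at 16 for the default
#'   cluster map).
#' @param mtdna_n per-population mtDNA sample sizes.
#' @param msat_n per-population microsatellite sample sizes.
#' @param n_loci microsatellite loci.
#' @param L mtDNA sequence length (bp).
#' @param missing_rate uniform genotype missingness rate.
#' @param contamination_fraction fraction of mtDNA sequences replaced by the
#'   contaminant haplogroup.
#' @param contaminant_divergence substitutions separating the contaminant
#'   ancestor from the native ancestral sequence.
#' @param scenario truth [scenario_spec()] for the microsatellites.
#' @param mutation truth [mutation_model()].
#' @param mtdna_expansion per-population `c(tau, theta0, theta1)` rows
#'   (matrix 16 x 3) for the mtDNA coalescent.
#' @param pop_divergence mean private substitutions at each population's
#'   founding (Poisson), on top of the shared ancestral sequence.
#' @param seed RNG seed.
#' @return A list of class `study_config`.
#' @export
study_config <- function(n_populations = 16,
                         mtdna_n = c(16, 9, 20, 22, 22, 20, 3, 20, 20, 20,
                                     20, 4, 20, 21, 20, 20),
                         msat_n = c(17, 21, 19, 27, 19, 22, 6, 22, 28, 28,
                                    28, 8, 28, 28, 23, 23),
                         n_loci = 13, L = 1014, missing_rate = 0.22,
                         contamination_fraction = 23 / 277,
                         contaminant_divergence = 30,
                         scenario = scenario_spec(2,
                           N = c(1500, 8000, 12000, 10000),
                           t1 = 2140, t2 = 8000, t3 = 12600, ra = 0.5),
                         mutation = mutation_model(5e-4, P = 0.15),
                         mtdna_expansion = NULL,
                         pop_divergence = 4, seed = 1L) {
  stopifnot(n_populations == length(mtdna_n), n_populations == length(msat_n),
            missing_rate >= 0, missing_rate <= 1,
            contamination_fraction >= 0, contamination_fraction <= 1,
            all(mtdna_n > 0), all(msat_n > 0))
  if (n_populations != 16)
    stop("the default cluster map requires 16 populations")
  if (is.null(mtdna_expansion))
    mtdna_expansion <- cbind(tau = rep(1.5, 16), theta0 = 0.5, theta1 = 50)
  structure(list(n_populations = n_populations, mtdna_n = mtdna_n,
                 msat_n = msat_n, n_loci = n_loci, L = L,
                 missing_rate = missing_rate,
                 contamination_fraction = contamination_fraction,
                 contaminant_divergence = contaminant_divergence,
                 scenario = scenario, mutation = mutation,
                 mtdna_expansion = mtdna_expansion,
                 pop_divergence = pop_divergence, seed = as.integer(seed)),
            class = "study_config")
}

# 16 coordinates on a 4x4 grid spanning a Tuerkiye-like bounding box
default_popmap <- function() {
  lon <- rep(seq(27, 43, length.out = 4), each = 4)
  lat <- rep(seq(36.5, 41.5, length.out = 4), times = 4)
  population_map(sprintf("pop%02d", 1:16), sprintf("pop%02d", 1:16), lon, lat)
}

mutate_sequence <- function(seq_chars, n_subs, tstv = 10) {
  bases <- c("A", "C", "G", "T")
  transition <- c(A = "G", G = "A", C = "T", T = "C")
  sites <- sample.int(length(seq_chars), min(n_subs, length(seq_chars)))
  for (s in sites) {
    b <- seq_chars[s]
    seq_chars[s] <- if (runif(1) < tstv / (tstv + 1)) transition[[b]] else
      sample(setdiff(bases, c(b, transition[[b]])), 1)
  }
  seq_chars
}

#' Generate a study-shaped synthetic dataset bundle
#'
#' Simulates the microsatellites under the truth scenario at cluster level
#' (individuals are exchangeable within a cluster and are assigned to its
#' populations), the mtDNA per population under sudden-expansion coalescents
#' rooted in a shared ancestral sequence, applies uniform missingness, and
#' injects the contaminant haplogroup. The truth record is sufficient to
#' regenerate the bundle bit-identically.
#'
#' @param config a [study_config()].
#' @return A list of class `study_bundle`: `mtdna` ([sequence_alignment()]
#'   with a logical `contaminant` attribute), `msat` ([genotype_matrix()]),
#'   `popmap` ([population_map()]), `truth` (list of every latent
#'   parameter, including the seed).
#' @export
generate_study_like <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  set.seed(config$seed)
  pops <- sprintf("pop%02d", seq_len(config$n_populations))
  clusters <- POP_CLUSTER

  # microsatellites: simulate at cluster level, then assign to populations
  cl_sizes <- vapply(CLUSTERS, function(cl)
    sum(config$msat_n[clusters == cl]), numeric(1))
  G <- simulate_msat_dataset(config$scenario, config$mutation,
                             as.integer(cl_sizes), config$n_loci)
  pop_of_ind <- character(sum(config$msat_n))
  for (cl in CLUSTERS) {
    idx <- which(G$pop_labels == cl)
    pop_of_ind[idx] <- rep(pops[clusters == cl],
                           times = config$msat_n[clusters == cl])
  }
  G$pop_labels <- pop_of_ind
  G$individual_ids <- rownames(G$a1) <- rownames(G$a2) <-
    paste0(pop_of_ind, "_", sprintf("i%03d", seq_along(pop_of_ind)))
  if (config$missing_rate > 0) {
    drop <- matrix(runif(length(G$a1)) < config$missing_rate, nrow(G$a1))
    G$a1[drop] <- 0L
    G$a2[drop] <- 0L
  }

  # mtDNA: shared ancestral sequence, per-population private founding drift
  root <- sample(c("A", "C", "G", "T"), config$L, replace = TRUE)
  parts <- lapply(seq_along(pops), function(p) {
    anc <- mutate_sequence(root, rpois(1, config$pop_divergence))
    ex <- config$mtdna_expansion[p, ]
    simulate_mtdna(config$mtdna_n[p], expansion = as.numeric(ex),
                   L = config$L, root_seq = paste(anc, collapse = ""),
                   pop = pops[p], id_prefix = paste0(pops[p], "_s"))
  })
  aln <- sequence_alignment(unlist(lapply(parts, `[[`, "sample_ids")),
                            unlist(lapply(parts, `[[`, "sequences")),
                            unlist(lapply(parts, `[[`, "pop_labels")))
  aln <- inject_contamination(aln, config$contamination_fraction,
                              config$contaminant_divergence,
                              root_seq = paste(root, collapse = ""))

  truth <- list(seed = config$seed, scenario = config$scenario,
                mutation = config$mutation,
                mtdna_expansion = config$mtdna_expansion,
                missing_rate = config$missing_rate,
                contamination_fraction = config$contamination_fraction,
                contaminant_divergence = config$contaminant_divergence,
                config = config)
  structure(list(mtdna = aln, msat = G, popmap = default_popmap(),
                 truth = truth),
            class = "study_bundle")
}

#' Inject a divergent contaminant haplogroup into an alignment
#'
#' Replaces `round(fraction * n)` randomly chosen sequences with descendants
#' of a contaminant ancestor placed `divergence` substitutions away from the
#' native ancestral sequence (each descendant carries a small Poisson number
#' of private substitutions). The logical attribute `contaminant` labels the
#' replaced sequences.
#'
#' @param aln a [sequence_alignment()].
#' @param fraction fraction of sequences to replace, in `[0, 1]`.
#' @param divergence substitutions from the native root to the contaminant
#'   ancestor.
#' @param seed optional RNG seed.
#' @param root_seq native ancestral sequence (string); defaults to the first
#'   sequence of `aln`.
#' @return The alignment with attribute `contaminant` (logical per sample).
#' @export
inject_contamination <- function(aln, fraction, divergence, seed = NULL,
                                 root_seq = NULL) {
  stopifnot(fraction >= 0, fraction <= 1)
  if (!is.null(seed)) set.seed(seed)
  n <- n_sequences(aln)
  n_cont <- round(fraction * n)
  labels <- rep(FALSE, n)
  if (n_cont > 0) {
    root <- strsplit(root_seq %||% aln$sequences[1], "")[[1]]
    anc <- mutate_sequence(root, divergence)
    pick <- sample.int(n, n_cont)
    labels[pick] <- TRUE
    for (i in pick) {
      aln$sequences[i] <- paste(mutate_sequence(anc, rpois(1, 1)),
                                collapse = "")
    }
  }
  attr(aln, "contaminant") <- labels
  aln
}

#' Contamination rate from truth labels
#'
#' @param labels logical (or 0/1) contaminant label per sequence.
#' @return List with `percent` (rounded to the nearest whole percent, for
#'   report display) and `unrounded` (exact percentage).
#' @export
contamination_rate <- function(labels) {
  if (!length(labels)) stop("empty label vector")
  pct <- 100 * mean(as.logical(labels))
  list(percent = round(pct), unrounded = pct)
}
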