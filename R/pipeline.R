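# End-to-end pipeline runner: synthetic (or file-based) inputs -> diversity
# and differentiation tables -> mismatch/expansion dating -> scaled-down ABC
# model choice -> barrier detection. All randomness flows from one seed.

#' Run the full demographic-inference pipeline
#'
#' Executes the workflow stages (sequence statistics, mismatch/expansion
#' dating, ABC model choice, barrier detection) on synthetic or file-based
#' inputs and writes CSV/JSON outputs under `out_dir`.
#'
#' @param config a list (or path to a JSON file) with elements:
#'   `synthetic` (logical; TRUE simulates a study-shaped bundle), `seed`,
#'   `out_dir`, and optionally `fasta`, `genepop`, `popmap` (input paths
#'   when `synthetic` is FALSE), `n_sims` (ABC simulations per scenario,
#'   default 2000), `tolerance` (default 0.01), `abc_sample_sizes`
#'   (individuals per cluster for the reference table), `n_boot_barrier`
#'   (default 25), `run_abc`, `run_barrier` (logicals, default TRUE).
#' @return A list of class `run_report`: `outputs` (named file paths, all
#'   existing on success), `seed`, `stages` (status per stage).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- jsonlite::fromJSON(config, simplifyVector = TRUE)
  }
  seed <- as.integer(config$seed %||% 1L)
  out_dir <- config$out_dir %||% stop("config$out_dir is required")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  set.seed(seed)
  stages <- character(0)
  outputs <- list()
  note <- function(stage) message("[", stage, "] ",
                                  format(Sys.time(), "%H:%M:%S"))

  note("inputs")
  if (isTRUE(config$synthetic)) {
    bundle <- generate_study_like(study_config(seed = seed))
    aln <- bundle$mtdna
    G <- bundle$msat
    popmap <- bundle$popmap
  } else {
    for (f in c("fasta", "genepop", "popmap"))
      if (is.null(config[[f]]) || !file.exists(config[[f]]))
        stop("missing input file: ", config[[f]] %||% paste0("config$", f))
    popmap <- read_popmap(config$popmap)
    G <- read_genepop(config$genepop)
    aln <- read_fasta(config$fasta)
  }
  stages["inputs"] <- "ok"

  note("stats")
  div <- diversity_table(aln)
  outputs$diversity <- file.path(out_dir, "diversity.csv")
  write.csv(div, outputs$diversity, row.names = FALSE)
  keep <- aln$pop_labels %in% names(which(table(aln$pop_labels) >= 2))
  phi <- phist_matrix(subset_alignment(aln, keep), model = "diff")$phist
  outputs$phist <- file.path(out_dir, "phist.csv")
  write.csv(phi, outputs$phist)
  msum <- msat_summaries(G)
  outputs$msat_summary <- file.path(out_dir, "msat_summary.csv")
  write.csv(msum, outputs$msat_summary, row.names = FALSE)
  fst <- wc_fst(G)
  outputs$fst <- file.path(out_dir, "fst.csv")
  write.csv(fst, outputs$fst)
  stages["stats"] <- "ok"

  note("mismatch")
  mt <- mismatch_table(aln, n_boot = as.integer(config$n_boot_mismatch %||% 0))
  outputs$mismatch <- file.path(out_dir, "mismatch_expansion.csv")
  write.csv(mt, outputs$mismatch, row.names = FALSE)
  stages["mismatch"] <- "ok"

  if (!isFALSE(config$run_abc)) {
    note("abc")
    spec <- prior_spec()
    szs <- as.integer(config$abc_sample_sizes %||% c(8, 20, 40, 28))
    tab <- abc_reference_table(
      spec, n_per_scenario = as.integer(config$n_sims %||% 2000),
      sample_sizes = szs, n_loci = length(G$locus_names))
    cl <- POP_CLUSTER[as.integer(factor(G$pop_labels,
                                        levels = sprintf("pop%02d", 1:16)))]
    obs_G <- G
    # observed clusters at the reference-table sample sizes: subsample
    idx <- unlist(lapply(seq_along(CLUSTERS), function(ci) {
      pool <- which(cl == CLUSTERS[ci])
      sample(pool, min(szs[ci], length(pool)))
    }))
    idx <- idx[order(match(cl[idx], CLUSTERS))]
    obs <- msat_summary_stats(
      genotype_matrix(G$individual_ids[idx], G$locus_names,
                      G$a1[idx, , drop = FALSE], G$a2[idx, , drop = FALSE],
                      cl[idx]))
    rej <- abc_reject(obs, tab, as.numeric(config$tolerance %||% 0.01))
    direct <- choose_model_direct(rej)
    logistic <- tryCatch(choose_model_logistic(rej), error = function(e) NULL)
    best <- direct$scenario[which.max(direct$posterior)]
    est <- tryCatch(estimate_parameters(rej, tab, spec, best),
                    error = function(e) NULL)
    outputs$abc <- file.path(out_dir, "abc_model_choice.json")
    jsonlite::write_json(list(direct = direct, logistic = logistic,
                              chosen_scenario = best, parameters = est),
                         outputs$abc, auto_unbox = TRUE, digits = NA,
                         na = "null")
    stages["abc"] <- "ok"
  }

  if (!isFALSE(config$run_barrier)) {
    note("barrier")
    keep2 <- aln$pop_labels %in% names(which(table(aln$pop_labels) >= 3))
    sub <- subset_alignment(aln, keep2)
    mats <- bootstrap_phist_matrices(sub,
                                     n_boot = as.integer(config$n_boot_barrier %||% 25))
    pm <- popmap[popmap$id %in% unique(sub$pop_labels), ]
    obs_phi <- phist_matrix(sub, model = "diff")$phist
    bs <- barrier_support(pm, mats, observed = obs_phi)
    outputs$barrier <- file.path(out_dir, "barrier.json")
    jsonlite::write_json(list(edges = bs$edges, n_matrices = bs$n_matrices),
                         outputs$barrier, auto_unbox = TRUE, digits = NA)
    stages["barrier"] <- "ok"
  }

  ok <- all(vapply(outputs, file.exists, logical(1)))
  if (!ok) stop("pipeline finished but an output file is missing")
  structure(list(outputs = outputs, seed = seed, stages = stages),
            class = "run_report")
}
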