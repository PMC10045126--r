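#!/usr/bin/env Rscript
# Stage 5: Monmonier barrier detection on the Delaunay triangulation of the
# 16 sampling sites, using the Phi-ST matrix of the native mtDNA sequences,
# with bootstrap support from simulated Phi-ST matrices.

suppressPackageStartupMessages(library(chukardemog))

seed <- as.integer(Sys.getenv("CHUKAR_SEED", "1"))
dir.create("results", showWarnings = FALSE)

samples <- read.csv("results/data/mtdna_samples.csv")
aln <- read_fasta("results/data/mtdna.fasta")
aln <- set_populations(aln, setNames(samples$pop, samples$sample))
native <- subset_alignment(aln, !samples$contaminant[
  match(aln$sample_ids, samples$sample)])
popmap <- read_popmap("results/data/popmap.csv")

keep <- native$pop_labels %in% names(which(table(native$pop_labels) >= 3))
sub <- subset_alignment(native, keep)
pm <- popmap[popmap$id %in% unique(sub$pop_labels), ]
phi <- phist_matrix(sub, model = "diff")$phist

tri <- delaunay_graph(pm)
point <- trace_barrier(tri, phi, n_barriers = 2)
cat("barrier 1 crosses", nrow(point$barriers[[1]]), "edges; barrier 2 crosses",
    nrow(point$barriers[[2]]), "edges\n")

mats <- bootstrap_phist_matrices(sub, n_boot = 100, seed = seed)
sup <- barrier_support(pm, mats, observed = phi)
cat("point-estimate barrier with bootstrap support (%):\n")
print(sup$edges, digits = 3)

jsonlite::write_json(
  list(barrier1 = point$barriers[[1]], barrier2 = point$barriers[[2]],
       support = sup$edges, n_matrices = sup$n_matrices),
  "results/barrier_results.json", auto_unbox = TRUE, digits = NA)
cat("wrote results/barrier_results.json\n")
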