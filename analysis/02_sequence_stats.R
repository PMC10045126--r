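#!/usr/bin/env Rscript
# Stage 2: per-population diversity indices and neutrality tests on the
# mtDNA alignment (contaminant sequences excluded, as in any downstream
# demographic analysis), plus pairwise Phi-ST matrices.

suppressPackageStartupMessages(library(chukardemog))

dir.create("results", showWarnings = FALSE)
samples <- read.csv("results/data/mtdna_samples.csv")
aln <- read_fasta("results/data/mtdna.fasta",
                  pop_labels = samples$pop[match(samples$sample, samples$sample)])
aln <- set_populations(aln, setNames(samples$pop, samples$sample))
native <- subset_alignment(aln, !samples$contaminant[
  match(aln$sample_ids, samples$sample)])

div <- diversity_table(native)
write.csv(div, "results/diversity_neutrality.csv", row.names = FALSE)
cat("Diversity and neutrality by population (natives only):\n")
print(div, digits = 3)

expanding <- div$pop[!is.na(div$fu_fs) & div$fu_fs < 0]
cat("\npopulations with Fu's Fs < 0 (expansion signal):",
    paste(expanding, collapse = ", "), "\n")

keep <- native$pop_labels %in% names(which(table(native$pop_labels) >= 3))
sub <- subset_alignment(native, keep)
phi <- phist_matrix(sub, model = "diff")
write.csv(phi$phist, "results/phist_matrix.csv")
cat("\nwrote results/phist_matrix.csv; largest pairwise Phi-ST:",
    sprintf("%.3f", max(phi$phist, na.rm = TRUE)), "\n")

gm <- read_genepop("results/data/msat.gen")
pm <- read_popmap("results/data/popmap.csv")
gm$pop_labels <- pm$id[as.integer(factor(gm$pop_labels,
                                         levels = unique(gm$pop_labels)))]
ms <- msat_summaries(gm)
write.csv(ms, "results/msat_summaries.csv", row.names = FALSE)
fst <- wc_fst(gm)
write.csv(fst, "results/msat_fst.csv")
cat("wrote microsatellite summaries; mean He =",
    sprintf("%.3f", mean(ms$He, na.rm = TRUE)), "\n")
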