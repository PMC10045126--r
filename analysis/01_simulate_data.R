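#!/usr/bin/env Rscript
# Stage 1: generate the study-shaped synthetic dataset (16 populations,
# 277 Cyt-b-like sequences of 1014 bp, 347 diploid individuals at 13
# microsatellite loci with ~22% missingness, contaminant haplogroup at
# 23/277) and write it in the exchange formats the rest of the workflow
# reads back.

suppressPackageStartupMessages(library(chukardemog))

seed <- as.integer(Sys.getenv("CHUKAR_SEED", "1"))
out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cfg <- study_config(seed = seed)
bundle <- generate_study_like(cfg)

write_fasta(bundle$mtdna, file.path(out, "mtdna.fasta"))
write.csv(data.frame(sample = bundle$mtdna$sample_ids,
                     pop = bundle$mtdna$pop_labels,
                     contaminant = attr(bundle$mtdna, "contaminant")),
          file.path(out, "mtdna_samples.csv"), row.names = FALSE)
write_genepop(bundle$msat, file.path(out, "msat.gen"))
write_popmap(bundle$popmap, file.path(out, "popmap.csv"))
jsonlite::write_json(list(seed = cfg$seed,
                          scenario_hypothesis = cfg$scenario$hypothesis,
                          t1 = cfg$scenario$t1, t2 = cfg$scenario$t2,
                          t3 = cfg$scenario$t3, ra = cfg$scenario$ra,
                          N = cfg$scenario$N, mu = cfg$mutation$mu,
                          P = cfg$mutation$P,
                          missing_rate = cfg$missing_rate,
                          contamination_fraction = cfg$contamination_fraction),
                     file.path(out, "truth.json"), auto_unbox = TRUE,
                     digits = NA)

cr <- contamination_rate(attr(bundle$mtdna, "contaminant"))
cat(sprintf("wrote %s: %d mtDNA sequences (%d contaminant, %.1f%%), %d
individuals x %d loci (%.1f%% missing)\n", out,
            n_sequences(bundle$mtdna),
            sum(attr(bundle$mtdna, "contaminant")), cr$unrounded,
            length(bundle$msat$individual_ids),
            length(bundle$msat$locus_names),
            100 * mean(bundle$msat$a1 == 0L)))
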