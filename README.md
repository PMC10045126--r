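# chukardemog

Demographic inference for chukar partridge (*Alectoris chukar*)
phylogeography — and for any study system with the same shape: multiple
populations sampled for an mtDNA marker and a panel of microsatellites,
where the questions are *when did populations expand*, *which
divergence/admixture scenario explains the nuclear data*, and *where do the
genetic barriers run*.

The package implements the full analysis battery as tested, reusable R
functions over a compiled coalescent engine, plus a synthetic-data generator
emulating a 16-population Anatolian sampling design so that every stage runs
and validates offline.

## What it computes

**mtDNA demography.** Diversity indices (haplotype counts with/without gaps,
haplotype diversity `h = n(1 − Σp²)/(n−1)`, segregating sites, nucleotide
diversity, mean pairwise differences, all with pairwise deletion of `N`/`-`
sites); Kimura two-parameter distances
`d = −½ln(1−2P−Q) − ¼ln(1−2Q)`; Tajima's D; Fu's Fs from the Ewens
sampling distribution `P(K=k) ∝ |S(n,k)|θᵏ` (log-space Stirling numbers);
mismatch-distribution analysis under the sudden-expansion model

    F_j(τ,θ₀,θ₁) = F̂_j(θ₁) + e^{−τ(θ₁+1)/θ₁} Σ_{i≤j} [F̂_i(θ₀) − F̂_i(θ₁)] τ^{j−i}/(j−i)!

fitted by bounded multi-start least squares, with Harpending's raggedness,
SSD, parametric-bootstrap p-values, and dating through `τ = 2µt` with a
calibrated clock (2·µ_site·L = 4.3008×10⁻⁴ per generation, 3.9 yr/gen).

**Differentiation.** Distance-based Φ_ST (AMOVA on squared haplotype
distances, permutation p-values) and the Weir–Cockerham multi-locus θ for
microsatellites; per-population Ho/He/F_IS tables.

**ABC model choice.** A continuous-time structured coalescent (C++) over
three divergence/admixture hypotheses for the Thrace / West / East /
Central-Anatolia clusters, generalized stepwise microsatellite mutation,
30 summary statistics, rejection with median/MAD standardization, direct and
weighted multinomial-logistic model choice, Beaumont-style logit-transformed
local-linear parameter estimation, and POD-based type-I/II error and RMAE
validation.

**Barriers.** Monmonier's maximum-difference algorithm on a Delaunay
triangulation of the sampling sites with bootstrap edge support from
replicate Φ_ST matrices.

## Worked example

Generate a study-shaped dataset and date the expansions:

```r
library(chukardemog)

bundle <- generate_study_like(study_config(seed = 1))
bundle$msat
#> genotype_matrix: 347 individuals x 13 loci, 16 population(s); 22.7% missing genotypes
contamination_rate(attr(bundle$mtdna, "contaminant"))$unrounded
#> [1] 8.303249        # 23 contaminant sequences of 277, i.e. 8%

native <- subset_alignment(bundle$mtdna, !attr(bundle$mtdna, "contaminant"))
head(diversity_table(native), 3)
#>     pop  N  k  K     h  s      pi    d tajima_d  fu_fs
#> 1 pop01 14 10 10 0.890 12 0.00169 1.71    -2.17 -7.510
#> 2 pop02  9  7  7 0.917  8 0.00175 1.78    -1.80 -4.200
#> 3 pop03 18  9  9 0.824 12 0.00167 1.69    -1.90 -4.445
```

Negative Fu's Fs in 15 of 16 populations flags the simulated post-glacial
expansions. Fit the sudden-expansion model and convert τ to calendar time:

```r
pop8 <- subset_alignment(native, native$pop_labels == "pop08")
fit <- fit_sudden_expansion(observed_mismatch(pop8))
fit
#> sudden-expansion fit: tau=2.6068 theta0=0.0000 theta1=100.0000 ssd=0.00068 hri=0.0347
expansion_time(fit$tau)
#> [1] 23.64           # kyBP under the calibrated clock
expansion_time(2.5)   # the clock on a reference tau
#> [1] 22.67
gens_to_years(c(12600, 2140))
#> [1] 49140  8346     # generations -> years at 3.9 yr/generation
```

ABC model choice on the same bundle (hypothesis 2 — simultaneous divergence
with later Central-Anatolian admixture — is the generator's truth):

```r
spec <- validation_priors()
tab  <- abc_reference_table(spec, n_per_scenario = 30000,
                            sample_sizes = c(8, 20, 40, 28), seed = 1)
# ... abc_reject() on the observed statistics, then:
# choose_model_logistic() concentrates the posterior on hypothesis 2 and
# estimate_parameters() returns an admixture fraction ra near 0.5
```

The numbered drivers under `analysis/` run these stages end to end
(`CHUKAR_SEED` and `CHUKAR_NSIMS` control the seed and the reference-table
size) and write their tables under `results/`.

## Layout

```
R/                  package code (io, statistics, mismatch, coalescent,
                    ABC, barriers, synthetic data, pipeline)
src/                coalescent + summary-statistic engine (Rcpp)
analysis/           numbered workflow drivers writing results/
scripts/acceptance.R  headline-quantity reproduction script
tests/testthat/     unit, property and end-to-end suites
vignettes/          methods vignette (models, parameters, design choices)
```
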