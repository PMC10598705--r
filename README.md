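# phenoflux

Multispectral single-turnover chlorophyll-*a* fluorescence phenotyping for
photosynthetic symbionts, in R.

Coral photosymbionts (family Symbiodiniaceae) differ enormously in how
they harvest and dissipate light, and those differences underpin coral
thermal tolerance. Single-turnover fluorometers resolve the microsecond
closure and reopening of PSII reaction centers, and driving them through a
variable actinic light protocol at several excitation wavelengths turns one
coral fragment into a "high-content" phenotype: hundreds of time- and
wavelength-resolved photophysiology metrics. phenoflux is for researchers
who want to analyse such data — or to validate analysis choices on
synthetic cohorts with known ground truth before trusting them on real
ones.

The package implements the full chain:

1. **Kinetics** — forward model and nonlinear fit of single-turnover
   induction/relaxation transients. Fluorescence follows the
   connected-units yield `F = F0 + (Fm − F0)·C(1−ρ)/(1−ρC)`; flashlet
   excitation closes centers with cross-section σ_PSII (Å² quanta⁻¹), and
   relaxation reopens them biexponentially (τ1: Qa→Qb transfer; τ2:
   plastoquinone-pool reoxidation). `st_fit()` is a classed two-stage
   bounded Levenberg–Marquardt fit with `print`, `summary`, `coef`,
   `predict`, `residuals`, `simulate` and `plot` methods.
2. **Protocol engine** — the 660-s dark/300/50/600/dark actinic protocol,
   34 timepoints × 5 wavelengths × 5 repeats, and derivation of the eight
   metrics (Φ_PSII, σ_PSII, ρ, NPQ, ABQ, qP, τ1, τ2) into a per-sample
   cube of 8 × 5 × 34 = 1,360 values.
3. **Synthetic cohort** — 20 colonies × 3 fragments, four light-response
   archetypes, six ITS2 symbiont types, planted trait–photophysiology
   correlations and genus copy-number bias, fully reproducible from a
   seed.
4. **Symbiont typing** — ITS2 counts normalized by rDNA copies per cell
   (Cladocopium 2119 : Durusdinium 362) and dominant-type calls at a
   strict >70 % threshold.
5. **Phenotype clustering** — ANOVA/Kruskal–Wallis metric screening,
   Z-scoring, correlation-distance clustering with multiscale-bootstrap
   (approximately-unbiased) node support, the k = 4 phenotype cut, and
   driver-metric ranking.
6. **Group statistics** — repeated-measures mixed-model contrasts across
   phenotypes and wavelengths; trait comparisons with compact letter
   displays.
7. **Trait network** — colony-level Pearson correlations between the
   1,360 metrics and cellular traits, thresholded at |r| > 0.6, exported
   as GraphML/edge lists.

## Worked example

Fit one simulated transient and recover its parameters:

```r
library(phenoflux)
set.seed(42)
truth <- st_params(F0 = 1000, Fm = 3000, sigma_PSII = 600, rho = 0.5,
                   alpha = 0.6, tau1_us = 600, tau2_us = 15000)
pair <- simulate_st_pair(truth, wavelength_nm = 442, noise_cv = 0.01)
st_fit(pair, dark = TRUE)
#> Single-turnover fluorescence fit (442 nm)
#>   converged ; residual RMS 24.3 instrument units
#>   F0 = 1009.9  Fm = 2988.5  Phi_PSII = 0.662
#>   sigma_PSII = 611.4 A^2 q^-1  rho = 0.514  C0 = 0.000
#>   alpha = 0.591  tau1 = 585 us  tau2 = 14222 us
```

At 1 % flashlet noise the fit lands within ~2 % of the generating values
(σ 611 vs 600, ρ 0.514 vs 0.5, τ1 585 vs 600 µs); τ2, the weakly
identified slow component, is within ~5 %.

Cluster a full synthetic cohort into light-response phenotypes:

```r
coh  <- generate_cohort(cohort_config(), seed = 1, level = "metrics")
dom  <- call_dominant_types(coh$its2)       # copy-number-normalized calls
wide <- cubes_to_wide(coh$cubes)            # 60 samples x 1,360 metrics
scr  <- screen_metrics(wide, dom$dominant_type[match(rownames(wide),
                                                     dom$sample_id)])
sum(scr$kept)
#> [1] 1276                                  # metrics kept by the screen
zmat <- zscore_matrix(t(wide[, scr$metric[scr$kept]]))
dend <- bootstrap_cluster(zmat, n_boot = 1000, seed = 1)
cut_phenotypes(dend, k = 4)
#> Phenotype assignment: k = 4
#> phenotype
#>  1  2  3  4
#> 15 15 15 15
```

The four recovered phenotypes match the planted archetypes exactly
(adjusted Rand index 1). `level = "traces"` runs the same chain from raw
flashlet traces through `fit_cohort()` — about two minutes for the
10,200 fits of a full cohort. `run_pipeline(outdir, seed)` executes every
stage and writes all tables, the Newick dendrogram, the GraphML network
and a hash manifest; `inst/scripts/phenoflux.R` wraps it for the shell.

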