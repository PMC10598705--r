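---
title: "Models and methods behind phenoflux"
author: "phenoflux authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phenoflux}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

phenoflux implements a fluorescence-based phenomics pipeline for
photosynthetic symbionts measured *in hospite*: it simulates and fits
single-turnover chlorophyll-*a* fluorescence transients acquired under a
multispectral variable actinic light protocol, derives a per-sample cube of
1,360 photophysiological metrics, clusters samples into light-response
phenotypes with bootstrap support, normalizes ITS2 amplicon counts for
genus-level rDNA copy-number bias, and correlates the photophysiology with
cellular traits. This vignette documents the models, the tunable parameters
and the numerical choices, and states what the bundled synthetic cohort
does and does not demonstrate.

## The single-turnover forward model

A single-turnover acquisition has two phases. During **induction**, a train
of 1.3-microsecond excitation flashlets separated by 3.4-microsecond dark
gaps progressively closes PSII reaction centers (32 flashlets at 420, 442
and 458 nm; 40 at 505 and 525 nm, where the functional cross-section is
smaller). During **relaxation**, sparse probe flashlets with geometrically
growing dark gaps (first gap 59 microseconds, 300 ms total) track the
reopening of the closed centers.

Fluorescence yield follows the connected-units model. With a fraction $C$
of centers closed, minimal and maximal fluorescence $F_0$ and $F_m$, and
excitonic connectivity $\rho$ (the probability that an exciton arriving at
a closed center migrates to an open neighbour),

$$F(C) = F_0 + (F_m - F_0)\,\frac{C\,(1-\rho)}{1 - \rho C}.$$

Within a flashlet delivering dose $D$ (quanta per square Angstrom), closure
accumulates as $dC/dD = \sigma_{PSII}\,(1-C)/(1-\rho C)$, whose implicit
solution $-(1-\rho)\log(1-C) + \rho C = \sigma D + \text{const}$ we invert
with a Newton iteration in $u = -\log(1-C)$ space, where the derivative is
bounded in $[1-\rho, 1]$ and the iteration cannot stall. This makes the
per-flashlet recursion exact rather than a one-step Euler approximation;
the test suite checks agreement with a brute-force fine-step dose
integration to better than 0.5 percent. Expressing dose in quanta per
square Angstrom keeps $\sigma_{PSII}$ in its conventional units (squared
Angstroms per quantum).

Relaxation is biexponential in the closed fraction:
$C(t) = C_{end}\,[\alpha e^{-t/\tau_1} + (1-\alpha)e^{-t/\tau_2}]$, where
$\tau_1$ reflects acceptor-side (Qa to Qb) electron transfer and $\tau_2$
plastoquinone-pool and downstream reoxidation. Because $\tau_2$ comes from
the second exponential component of a single-turnover sequence, it is an
effective constant rather than a literal rate.

Two simplifications are deliberate. Reopening during the 150-190
microsecond induction train is off by default (it contributes under 3
percent for $\tau_1 \ge 400$ microseconds and keeps the induction fit
five-parameter); a flag re-enables it. The actinic effect of the
1.3-microsecond relaxation probes is neglected.

## Fitting

`st_fit()` is a two-stage bounded Levenberg-Marquardt fit
(minpack.lm) with relative residuals, matching the multiplicative character
of instrument noise. Stage one fits the induction train for $F_0$, $F_v$,
$\sigma_{PSII}$, $\rho$, and the initial closure $C_0$ (pinned to 0 for
dark-acclimated acquisitions); stage two holds those values and the implied
end-of-induction closure fixed and fits $\alpha$, $\tau_1$, $\tau_2$ to the
relaxation. Two-stage fitting decouples the $\sigma$-$\rho$ estimation from
the time constants and matches the definition of $\tau_2$ as the second
exponential component.

Initialization and bounds: $F_0$ starts at the first-flashlet value, $F_m$
at 1.05 times the maximum, $\sigma$ from the normalized initial slope,
$\rho$ at 0.3, $\alpha$ at 0.6, $\tau_1$ at 600 microseconds, $\tau_2$ at
20 times that; $\rho \in [0, 0.8]$, $\tau_1 \in [50\,\mu s, 10\,ms]$,
$\tau_2 \in [100\,\mu s, 300\,ms]$. If the first solution fails or pins
$\rho$ or $\sigma$ at a bound, the fit restarts from alternative $\rho$
values and keeps the lowest-deviance solution; bound-pinned solutions are
reported with `converged = FALSE`.

Degenerate relaxation solutions are never passed downstream as a second
time constant: if the fitted $\tau_2$ is under twice $\tau_1$, if either
amplitude falls below 0.05, or if $\tau_2$ pins at the 300 ms span bound,
the relaxation is refit as a single exponential and $\tau_2$ is reported
missing. Flat induction traces (relative range below 2 percent) are flagged
not converged with all parameters missing. Non-converged fits propagate as
missing metric values, never as fabricated numbers.

At light-adapted timepoints, $F_0'$ and $C_0$ are nearly exchangeable in
the induction likelihood (a higher baseline with fewer closed centers looks
much like a lower baseline with more). The pipeline breaks this degeneracy
by pinning $F_0'$ to the Oxborough-Baker estimate
$F_o' = F_o/(F_v/F_m + F_o/F_m')$, built from the dark reference fit and a
provisional $F_m'$ taken from the trace plateau. The instrument protocol
has no far-red $F_o'$ measurement, so this standard estimator is also used
by the qP derivation.

## The actinic protocol and the metric cube

The default protocol is 660 s: 30 s dark, 300 umol photons m^-2 s^-1 for
3.5 min, 50 for 1.5 min, 600 for 3.5 min, and about 2 min of dark recovery.
Thirty-four acquisition timepoints are spaced evenly (660/34 or about 19.4
s apart; the protocol fixes the count, and even spacing is our design
choice), and each timepoint is acquired five times
sequentially per wavelength. The five repeats are averaged flashlet-wise
into one trace and fitted once — signal accumulation before the nonlinear
fit, which is how repeated acquisitions are normally treated; per-repeat
fitting remains available for diagnostics.

Eight metrics are derived at each of 5 wavelengths and 34 timepoints (8 x 5
x 34 = 1,360 values per sample): $\Phi_{PSII} = (F_m'-F')/F_m'$ with $F'$
the fitted induction baseline (the steady-state fluorescence under actinic
light; of the two common light-adapted conventions, $F_q'/F_m'$ and
$(F_m'-F_o')/F_m'$, we adopt the former);
$\sigma_{PSII}$, $\rho$, $\tau_1$, $\tau_2$ passed through from the fit;
Stern-Volmer NPQ $= (F_m - F_m')/F_m'$ against the dark-acclimated first
timepoint; $qP = (F_m'-F')/(F_m'-F_o')$ with the Oxborough-Baker $F_o'$;
and antenna-bed quenching ABQ $= (\sigma - \sigma')/\sigma$, the fractional
loss of functional cross-section. ABQ has no single agreed formula;
quenching localized in the antenna bed manifests as
cross-section loss, so this definition is our declared stand-in.

The cube flattens deterministically (metric-major, then wavelength, then
timepoint, names `metric_wavelength_timepoint`), and flattening is a
bijection tested by round trip.

## The synthetic cohort

The generator stands in for instrument and sequence data: 20
colonies x 3 replicate fragments, six dominant ITS2 types (C1, C3, C15,
C21, C26, D1), four light-response archetypes, and a growth-environment
label (indoor/outdoor) that is generated but has no effect by default —
light-history effects are left to the user to configure.

Archetype dynamics are piecewise first-order: within each actinic segment,
every quenching variable relaxes exponentially toward an asymptote
$A\,I/(I+I_{50})$ set by the segment irradiance — the simplest dynamics
that reproduce the characteristic trajectory shapes of coral-symbiont
light-response phenotypes without inventing mechanism. The defaults encode
qualitative orderings, not measured curves: archetype 1 (C15-like) has the largest NPQ
amplitude, slowest $\tau_2$ and lowest dark quantum yield; archetype 2
(D1-like) the smallest NPQ amplitude, deepest sustained qP depression,
larger cells and less chlorophyll per cell; archetypes 3 and 4 sit between
them with distinct qP kinetics and $\tau_2$. qP depression recovers almost
instantly when the light goes off (reaction centers reopen within
milliseconds in darkness) while NPQ relaxes over minutes; $\sigma_{PSII}$
declines from blue to green excitation and NPQ responds more strongly in
the blue.

Noise has three planted levels: multiplicative Gaussian noise per flashlet
(1 percent default), and lognormal colony- and fragment-level random
effects on archetype parameters (CV 5 and 2 percent). Generation is exactly
reproducible from a seed. Two paths exist: `level = "traces"` runs the full
forward model (the full emulation used for end-to-end recovery), and
`level = "metrics"` evaluates the true metric trajectories directly with 2
percent multiplicative measurement noise — a fast path that isolates the
post-fit stages.

Cellular traits are linear-Gaussian on the log scale (positivity plus
controllable Pearson structure): atomic N:P loads negatively on mean
$\Phi_{PSII}$ and positively on mean $\tau_2$; C:P positively on NPQ
amplitude and mean qP; granularity broadly; cell size, chlorophyll and
lipids carry archetype offsets; two control traits are independent noise.
The loading noise is solved so the planted pairwise Pearson correlation
equals the 0.75 target given the realized coupling between latents, and
elemental contents per cell are derived from the planted ratios and a
lognormal P-per-cell baseline, so ratios are always recomputable from
elements. Note a statistical ceiling: with a true correlation of 0.75 over
20 colonies, the sample correlation exceeds the 0.6 network threshold in
about 88 percent of draws — the recovery rate reported by the acceptance
script is therefore an average over the three planted relations, each of
which benefits from the multiplicity of metrics in its family.

ITS2 counts are drawn multinomially after multiplying cell proportions by
genus rDNA copies per cell (Cladocopium 2119, Durusdinium 362), so
copy-number normalization is genuinely required to recover truth: a
Durusdinium-dominated sample with a Cladocopium secondary type drops below
the 70 percent dominance threshold on raw read shares but not after
normalization. Each sample's dominant type has cell-level proportion 0.9 by
default, with a cross-genus secondary type.

What passing tests do **not** show about real data: the generator has no
host optical effects, no instrument drift or baseline wander, no
non-Gaussian noise, archetypes are exactly four and well separated at the
default noise levels, and the trait correlations are planted, not
biological. Recovery results bound what the pipeline can do when its model
family is correct; they say nothing about model misspecification.

## Symbiont typing

Counts are divided by genus copy number and renormalized; the dominance
threshold (strictly greater than 0.70) is applied to normalized abundances
by default, with a flag for raw read shares, because dominance feeds
biology-level grouping; applying it to raw read shares instead reproduces
the copy-number bias on purpose. Unknown genera fall back to 1,000 copies per cell with
a loud warning rather than failing.

## Screening, clustering and phenotypes

Screening is univariate and deliberately uncorrected for multiplicity (it
is a screen, not inference): per metric, Shapiro-Wilk on group-centered
residuals at alpha 0.05 gates between one-way ANOVA and Kruskal-Wallis
across dominant symbiont types, and metrics with p < 0.05 are kept.
Constant metrics are dropped with a reason. The type-I rate of the screen
is checked on simulated null metrics.

Kept metrics are Z-scored per metric (missing values ignored in the
moments, retained as missing) and samples are clustered by average-linkage
agglomeration on 1 minus the Pearson correlation between sample metric
profiles — the default family of the established bootstrap-clustering
tools in this area, declared here as our choice. Node support uses a multiscale bootstrap
implemented in this package: metrics are resampled with replacement at
relative sizes 0.5 to 1.4, the bootstrap probability of each original node
is recorded per scale, and the approximately-unbiased p-value comes from
the weighted fit $qnorm(1-BP_r) = v\sqrt{r} + c/\sqrt{r}$ with
$AU = 1 - \Phi(v - c)$. Nodes recovered in essentially every replicate at
every scale (or none) are assigned support 1 (or 0) directly, where the
signed-distance fit is degenerate. The 1,000 bootstrap iterations are split
evenly across the ten scales. Tight two-sample nodes can draw high support
even on structureless data — a known property of bootstrap support on small
tight clusters — so calibration checks are scoped to nodes of three or more
samples.

Phenotypes are the k = 4 largest clustering groups (`cutree` at the height
yielding exactly k groups), relabelled by decreasing size with ties broken
by first sample id. Samples with more than 20 percent missing metrics are
excluded before clustering; correlations are pairwise-complete when missing
values are present. Driver metrics are ranked by their one-way
between-phenotype F statistic on the Z-scored values, aggregated per metric
family by the median F — a transparent, testable choice of driver
statistic.

## Group statistics

Metric trajectories are compared with the repeated-measures linear mixed
model `value ~ group + timepoint + (1 | fragment)` fit by REML (lmerTest),
with all pairwise group contrasts Bonferroni-adjusted (multcomp) — the
stricter of the common post-hoc conventions. Timepoint enters as a
categorical fixed effect with no group-by-time interaction by default (the
interaction is available behind a flag); this minimal model is a declared
design choice. Singular or failed fits fall back to pairwise Welch tests on per-fragment
means, flagged in the output. Note that fragments of one colony are treated
as replicates, matching the emulated design; colony-level random variation
therefore inflates apparent significance for colony-structured traits — a
property of the design, not of the implementation.

Cellular traits use the same Shapiro-Wilk gate, then ANOVA with Tukey HSD
or Kruskal-Wallis with Bonferroni-adjusted pairwise Wilcoxon tests, and a
compact letter display computed by insert-and-absorb on the pairwise
significance graph, so phenotypes share a letter exactly when no
significant difference separates them.

## Trait network

Metric cubes are averaged to colony level (missing-aware means, n
recorded), correlated against colony-level traits with Pearson r, and
edges retained when |r| strictly exceeds the threshold (default 0.6; a
looser 0.55 display threshold is also exposed). No multiplicity correction
is applied, by design; with 1,360 metrics
against roughly a dozen traits at n = 20 colonies this unavoidably admits
some spurious edges, which is why the synthetic cohort carries zero-loading
control traits as negative controls. Exports are GraphML (igraph) and a
tab-delimited edge list; dendrograms export as Newick (ape) with AU support
as node labels.

## Problem sizes and runtimes

The test suite and acceptance script use the full-scale default cohort (60
fragments, 5 wavelengths, 34 timepoints, 5 repeats — 10,200 averaged fits
per pipeline run) for the end-to-end phenotype recovery, 50 seeded
transients for parameter recovery, 1,200 simulated null metrics for screen
calibration, and 50 cohort seeds for network recovery; bootstrap support
uses the full 1,000 iterations. Smaller cohorts (8 colonies x 2 fragments,
10 timepoints) back the per-module unit tests.

## Known limitations

- $\sigma_{PSII}$ and $\rho$ trade off in the induction fit; the package
  bounds $\rho$ and multistarts, and a dedicated test asserts that fixing
  $\rho$ at truth improves $\sigma$ recovery (the trade-off is handled,
  not hidden), but strongly quenched light timepoints still estimate
  $\sigma'$ (and hence ABQ) with several-fold larger error than dark ones.
- $\tau_2$ is weakly identified over a 300 ms relaxation window; values
  approaching the window length are reported but soft.
- The AU p-values are asymptotic; with 100 bootstrap replicates per scale
  their resolution is limited, and saturated nodes are special-cased.
- The mixed model has no colony random effect by design (fragments are the
  replicates); inference on colony-structured traits is anticonservative.
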