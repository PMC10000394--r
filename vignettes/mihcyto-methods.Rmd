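---
title: "Methods: gating, proximity and survival analysis of multiplexed IHC cell tables"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gating, proximity and survival analysis of multiplexed IHC cell tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mihcyto)
```

`mihcyto` treats per-cell measurements from multiplexed
immunohistochemistry the way a flow cytometrist treats events: each
segmented cell carries a position (µm) and one intensity per marker
(arbitrary units, a single value per marker taken as the mean over the
marker's compartment — nuclear for DAPI and FOXP3, cytoplasmic for the
rest). This vignette documents the models, the tunable parameters, the
numerical conventions, and what the synthetic cohort generator does and
does not emulate.

## Threshold gating

For each marker the positivity threshold is an empirical upper quantile of
that marker's intensities on a negative-control sample, on which no true
staining is present. The defaults are:

* **quantile = 0.99.** By construction this concedes a ~1% false-positive
  rate among truly negative cells; pushing it higher trades false
  positives for false negatives on dim positive populations. It is a
  per-cohort setting: one threshold set, estimated once from the control,
  is applied to every core, mirroring workflows where gates are "examined
  across all tissue samples". Per-slide thresholds would be a caller-side
  loop over `estimate_thresholds()`.
* **Quantile interpolation is type 7** (R's default), so thresholds are
  reproducible across implementations to documented semantics.
* **Strict inequality.** A cell is positive iff intensity `>` threshold.
  This makes the constant-control corner case well defined (a control
  whose intensities all equal *c* yields threshold *c* and calls nothing
  positive) and matches the reading of a threshold as the top of the
  negative distribution.
* **DAPI is the exception**: the counterstain is present on the negative
  control too, so its gate is not control-derived; the default threshold
  is 0 (any cell with a detected nucleus counts). DAPI-negative rows are
  dropped, with a logged count, before phenotyping.

Fewer than 20 control cells triggers a warning, not an error — thresholds
remain computable but noisy.

## Hierarchical phenotypes

Phenotype assignment is a deterministic function of the positivity vector,
in the order a sequential FACS gate would apply it:

1. tumor-marker⁺ → `Tumor`, refined to `PD-L1_Tumor` when PD-L1⁺;
2. else CD3⁺ → `Cytotoxic_T` when CD8⁺ (refined to
   `Exhausted_cytotoxic_T` when PD-1⁺), `Treg` when FOXP3⁺, else `T_cell`;
3. else CD68⁺ → `Macrophage`, refined to `PD-L1_Macrophage` when PD-L1⁺;
4. else `Other`.

Contradictory vectors are resolved by precedence rather than rejected: the
tumor marker outranks immune markers, CD3 outranks CD68 (a CD3⁺CD68⁺ cell
is a T cell), and CD8 outranks FOXP3 within CD3⁺. PD-1 on non-CD8 cells
and PD-L1 on T cells are recorded in the positivity vector but create no
label, because the downstream statistics only use PD-1⁺CD8⁺, PD-L1⁺CD68⁺
and PD-L1⁺ tumor cells. The labels partition every DAPI⁺ cell: one cell,
one label.

## Quantification

Densities are counts over tissue area. When the metadata supplies no area,
the default denominator is the convex hull of the sample's cells
(converted to mm²), with the nominal core disc π(d/2)² available via
`area_method = "disc"`; the hull adapts to partially filled cores, the
disc to uniformly covered ones. Subset proportions with a zero denominator
(for example p(PD-L1⁺CD68⁺ | CD68⁺) in a core without macrophages) are
reported as `NA` and excluded from group statistics — never imputed as
zero, which would fabricate signal in sparse cores. Group comparisons
default to the classic equal-variance two-tailed Student t-test (Welch by
flag); no multiple-testing correction is applied across panels, and raw
p-values are reported. The cross-method correlation operation (Pearson r
plus least-squares line with a 95% CI on the slope) is used here to
compare gating-derived densities against densities recomputed from
ground-truth labels; with real data it would compare two independent
phenotyping routes.

## Proximity bands

The spatial statistic is nearest-reference binning: each query cell is
counted once, in the half-open 10 µm band `[lo, hi)` containing the
distance to its *nearest* reference cell, over `[0, 100)` µm (ten bands;
a distance of exactly 100 µm falls outside). Percentages are band counts
over all query cells in the sample, so they sum to at most 100. An
alternative reading — counting every query–reference pair per band — is
implemented behind `metric = "pairs"`, since platform proximity modules
are ambiguous between the two; the nearest-neighbor form is the default
because its percentages are bounded and per-cell interpretable. Per-band
cross-sample comparisons use the unweighted mean of per-sample percentages
with SEM and a two-tailed t-test; bands with fewer than two defined values
in a group are skipped with a log entry.

The nearest-neighbor search sorts reference points by x and expands
outward from each query's insertion point, pruning once the x-gap alone
exceeds the best squared distance. It is exact — the test suite asserts
equality with an O(n²) brute-force oracle over randomized configurations —
and near O(n log n) for spatially spread points. An empty reference set
yields `NA` distances (undefined, not zero).

## Survival layer

Stratification is at the cohort median: `high` means strictly above, so
ties at the median go to `low`, and an all-identical statistic is a
degeneracy error rather than an arbitrary split. Kaplan–Meier estimation,
the (unweighted) log-rank test and its k-group generalization, and the
multivariate Cox model are delegated to the `survival` package, with Efron
tie handling in the Cox partial likelihood; the package's wrappers are
verified against hand-computed product-limit fixtures and an independent
observed-minus-expected log-rank computation. The four-group cluster
crosses the two functional proportions; the Cox model encodes it by
default as the binary high/high-versus-rest indicator (the 4-level factor
is available by building the model from `four_group_split()` directly),
with age in years, a male indicator, and ordinal stage 1–4 alongside.
Stage-stratified log-rank analyses dichotomize stage as 1–2 versus 3–4.

For the 1-year ROC, the outcome is death before 12 months versus survival
past 12 months; patients censored before the horizon carry no 1-year
outcome and are excluded with a logged count (a time-dependent ROC would
use them, but is out of scope). The AUC is the trapezoidal/Mann–Whitney
statistic via `pROC`, with the direction fixed so that an uninformative
score gives 0.5 and inverse predictors fall below 0.5.

## The synthetic cohort generator

The generator exists so every stage above can be tested against planted
truth. Its layers:

* **Geometry.** Circular 1.5 mm cores; phenotype counts Poisson with mean
  density × area; cells uniform on the disc.
* **Intensities.** Two-component log-normal mixtures per marker; the
  default negative component has meanlog log(100) and sdlog 0.5, and the
  positive component is 20× brighter at equal spread. Fluorescence is
  right-skewed, hence log-normal; the 20× separation makes gating errors
  rare but non-zero (~1% false positives at the 0.99 gate, by
  construction).
* **Spatial attraction.** A Thomas-like displacement process: a fraction
  κ/(1+κ) of PD-1⁺CD8⁺ cells is re-placed at Gaussian offsets (sd σ,
  default 15 µm) around randomly chosen PD-L1⁺CD68⁺ macrophages, with
  offsets rejected-resampled onto the disc. κ = 0 leaves the subset
  completely spatially random (verified by a Clark–Evans comparison
  against directly simulated uniform points, sharing the edge-effect
  bias). A constructive parent–offspring process was chosen over a Gibbs
  interaction model: it is cheap, and it provably plants the near-band
  contrast the proximity analysis is supposed to detect.
* **Patient coupling.** Per-patient true p(PD-1⁺|CD8⁺) and
  p(PD-L1⁺|CD68⁺) are drawn from a bivariate normal on the logit scale
  (sd 0.5, correlation ρ = 0.8), so the two proportions covary across the
  cohort; per-phenotype densities get log-normal jitter (sdlog 0.3) per
  patient.
* **Survival.** Exponential proportional hazards — hazard
  λ₀·exp(βᵀ(z−z_ref)) with λ₀ = 0.035/month at the reference patient
  (proportions at their preset means, age 65, female, stage 2), β = (2, 2)
  on the two true proportions, 0.02/year on age, 0.3 per stage — with
  exponential censoring (0.035/month) truncated at 60 months. The
  exponential form means a Cox fit on the generated data is correctly
  specified, which is what makes parameter-recovery tests meaningful.
* **Presets.** `"pdac-like"`: 84 tumor cores, adjacent-normal cores for 73
  patients, one 2,000-cell negative control; tumor composition (cells/mm²:
  tumor 1200, CD3⁺CD8⁻ 120, CD3⁺CD8⁺ 100, Treg 35, CD68⁺ 150, other 800)
  giving a CD8-of-CD3 share near 39%, against ~55% in adjacent normal
  (115/175/30), with the T-cell pool depressed and the CD68/CD3 and
  FOXP3/CD8 ratios elevated in tumor; functional fractions 0.35/0.30/0.15
  in tumor and 0.15/0.10/0.05 in normal; attraction κ = 10, σ = 15 µm.
  `"null"` is identical with all survival coefficients and the attraction
  set to zero — the calibration condition. Randomness flows through
  per-sample substreams derived from one seed, so cohorts are exactly
  reproducible and adding a sample leaves the others' draws unchanged.

**What the generator does not emulate:** raw images and segmentation error,
staining artifacts and spectral spillover, tumor/stroma tissue regions,
spatial structure in any population other than the planted PD-1⁺CD8⁺
attraction, non-proportional hazards, and informative censoring. Passing
tests therefore demonstrate that the *pipeline machinery* is correct and
calibrated under its stated model — not that real tissue satisfies that
model. Intensity mixture parameters are free choices exposed in
`intensity_model()`, not estimates from data; whether a platform exports
mean, total or max compartment intensity is likewise fixed here as "mean"
by convention.

## Problem sizes and numerical conventions in the test suite

The suite exercises the statistical properties at the scales the package
is meant for: oracle equivalence over 50 random configurations of up to
300 query and reference cells; gating recovery pooled over 20 default
cores against one 2,000-cell control; log-rank type-I error over 1,000
null cohorts of n = 84; Cox recovery of a planted hazard ratio of 2 over
200 cohorts of n = 300 (generated under the null model plus the planted
effect, so the fit is correctly specified); planted-structure recovery
over 100 (correlation) and 50 + 50 (attraction and its null) cohorts of 84
tumor cores. Spatial equality checks are exact (same IEEE arithmetic on
both paths); quantile and log-rank oracle comparisons use tolerances of
1e-12 to absorb algebraically equivalent but differently ordered floating
point expressions.

## Known limitations

Thresholds are global per cohort; slide-to-slide staining drift is not
modeled or corrected. The hierarchy discards information in genuinely
co-positive cells (a CD3⁺CD68⁺ doublet is simply a T cell). Proximity
percentages ignore reference-cell multiplicity in the default metric
(a query with five nearby macrophages counts once). The 1-year ROC
exclusion of early-censored patients is slightly optimistic when censoring
is informative. Multiple testing across the ten bands and across panels is
deliberately uncorrected, matching common practice in this literature;
consumers should treat per-band stars as descriptive.
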