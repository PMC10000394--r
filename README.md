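# mihcyto

Image-cytometry analysis of multiplexed immunohistochemistry (mIHC) tissue
microarrays in R: flow-cytometry-like threshold gating of per-cell
intensity tables, tumor-microenvironment quantification, nearest-neighbor
distance-band proximity analysis, and median-cutoff survival
stratification — plus a synthetic TMA cohort generator so the entire
pipeline is testable end to end without patient data.

## Who this is for

Computational pathology and tumor-immunology groups who have per-cell
exports from a segmentation platform (one row per cell: coordinates in µm
and one fluorescence intensity per marker) for an eight-marker panel —
DAPI, CD3, CD8, FOXP3, CD68, PD-1, PD-L1 and a tumor marker
(PanCK/SOX10) — and want to reproduce, on their own cohorts, the style of
analysis in which immune-checkpoint biology is read off cell *subset
proportions* and *spatial neighborhoods* rather than raw densities.

## What it computes

1. **Gating.** Positivity thresholds are upper quantiles (default 99th) of
   each marker's intensity on a negative-control slide; a cell is positive
   iff intensity strictly exceeds the threshold. Cells are then assigned
   hierarchically: tumor-marker⁺ → Tumor (PD-L1⁺ → PD-L1 Tumor); else
   CD3⁺ → Cytotoxic T if CD8⁺ (Exhausted if additionally PD-1⁺), Treg if
   FOXP3⁺, else T cell; else CD68⁺ → Macrophage (PD-L1⁺ → PD-L1
   Macrophage); else Other.
2. **Quantification.** Per-sample densities (cells/mm²), subset
   proportions — p(CD8⁺|CD3⁺), p(PD-1⁺CD8⁺|CD8⁺), p(PD-L1⁺CD68⁺|CD68⁺),
   … — and CD68/CD3, FOXP3/CD8 ratios; Student t comparisons between
   tissue classes; Pearson correlation between densities computed by two
   routes.
3. **Spatial proximity.** For each sample, every query cell (e.g.
   PD-1⁺CD8⁺ T cell) is binned by the distance to its nearest reference
   cell (e.g. PD-L1⁺CD68⁺ macrophage) into ten half-open 10 µm bands
   covering 0–100 µm; band percentages are compared between query
   phenotypes by per-band t-tests. The nearest-neighbor search is an exact
   sorted-axis expanding search in C++.
4. **Survival.** Median-cutoff high/low stratification, Kaplan–Meier
   curves with log-rank tests (via the `survival` package, Efron ties in
   Cox), the four-group cluster crossing two proportions, a multivariate
   Cox model of the high/high cluster indicator with age, sex and stage,
   and 1-year ROC/AUC (via `pROC`).
5. **Synthetic cohorts.** Poisson phenotype counts on a 1.5 mm disc,
   two-component log-normal intensity mixtures, Thomas-like attraction of
   PD-1⁺CD8⁺ cells toward PD-L1⁺CD68⁺ macrophages, correlated per-patient
   functional proportions (logit-scale bivariate normal), and exponential
   proportional-hazards survival with censoring.

## Worked example

```r
library(mihcyto)
res <- run_pipeline(tma_preset("pdac-like"), seed = 1)
print(res)
#> <mihcyto_run> preset pdac-like seed 1
#>   84 tumor / 73 adjacent-normal samples
#>   median CD8-of-CD3: tumor 39.0%, normal 51.1%
#>   cross-patient r[p(PD-1+|CD8+), p(PD-L1+|CD68+)] = 0.744
#>   near bands [0,20): PD-1+ 27.2% vs PD-1- 2.7% (min p 1e-92)
#>   cluster (high/high) Cox HR = 1.81 [0.97-3.36], p = 0.0625
```

Reading the output: the CD8 share of the CD3 T-cell pool is depressed in
tumor cores relative to adjacent normal tissue; across patients the
exhausted fraction of cytotoxic T cells moves together with the PD-L1⁺
fraction of macrophages (r = 0.744); PD-1⁺CD8⁺ cells sit far more often
within 20 µm of a PD-L1⁺ macrophage than their PD-1⁻ counterparts; and
patients high on both proportions carry a hazard ratio near 2. The Cox
table itself:

```r
print(res$cox)
#> <cox_fit> n = 84 events = 45
#>      term   coef   hr hr_lo hr_hi      p
#> 1 cluster 0.5909 1.81 0.970  3.36 0.0625
#> 2     age 0.0118 1.01 0.981  1.04 0.4568
#> 3    sexM 0.4413 1.55 0.834  2.90 0.1652
#> 4   stage 0.3007 1.35 0.977  1.87 0.0685
```

Individual stages are plain functions (`simulate_cohort()`,
`estimate_thresholds()`, `gate_cells()`, `summarize_samples()`,
`proximity_profiles()`, `compare_profiles()`, `median_split()`,
`km_estimate()`, `logrank_test()`, `cox_fit()`, `roc_1yr()`), so any step
can be run on its own — including on real per-cell CSV exports read with
`read_cell_table()`.

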