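#' Per-sample density, proportion and ratio summaries
#'
#' For each sample, counts cells by phenotype and by the marker combinations
#' the analysis tracks, converts counts to densities (cells/mm^2) using the
#' sample's tissue area, and computes the subset proportions and
#' density ratios: p(CD8+|CD3+), p(PD-1+CD8+|CD8+), p(PD-L1+CD68+|CD68+),
#' p(PD-L1+|tumor), p(PD-1+CD8+|all), p(PD-L1+CD68+|all), CD68/CD3 and
#' FOXP3/CD8. Proportions with a zero denominator are reported as `NA`
#' (undefined, never zero-filled) and excluded from downstream group
#' statistics.
#'
#' Tissue area comes from the metadata (`area_method = "meta"`), from the
#' convex hull of the sample's cells (`"chull"`), or from the nominal core
#' disc `pi (d/2)^2` (`"disc"`); `"meta"` falls back to the convex hull when
#' the metadata area is missing.
#'
#' @param gated output of [gate_cells()] (needs `sample_id`, coordinates,
#'   positivity columns and `phenotype`).
#' @param meta per-sample metadata data.frame (from a [cell_table()]).
#' @param area_method `"meta"`, `"chull"` or `"disc"`.
#' @return data.frame, one row per sample: counts `n_*`, `tissue_area_mm2`,
#'   densities `density_*`, proportions `p_*`, ratios `ratio_*`.
#' @export
summarize_samples <- function(gated, meta,
                              area_method = c("meta", "chull", "disc")) {
  area_method <- match.arg(area_method)
  ids <- meta$sample_id[meta$tissue_class != "negative_control"]
  ids <- intersect(ids, unique(gated$sample_id))
  row_ix <- split(seq_len(nrow(gated)), gated$sample_id)
  rows <- lapply(ids, function(sid) {
    g <- gated[row_ix[[sid]], ]
    m <- meta[meta$sample_id == sid, ]
    area <- switch(area_method,
                   meta = if (is.finite(m$tissue_area_mm2))
                     m$tissue_area_mm2 else .chull_area_mm2(g),
                   chull = .chull_area_mm2(g),
                   disc = pi * (m$core_diameter_mm / 2)^2)
    if (!is.finite(area) || area <= 0) {
      stop("zero or undefined tissue area for sample ", sid, call. = FALSE)
    }
    ph <- table(g$phenotype)
    n_total <- nrow(g)
    n_cd3 <- sum(ph[c("T_cell", "Cytotoxic_T", "Exhausted_cytotoxic_T",
                      "Treg")])
    n_cd8 <- sum(ph[c("Cytotoxic_T", "Exhausted_cytotoxic_T")])
    n_treg <- ph[["Treg"]]
    n_cd68 <- sum(ph[c("Macrophage", "PD-L1_Macrophage")])
    n_tumor <- sum(ph[c("Tumor", "PD-L1_Tumor")])
    n_pd1_cd8 <- ph[["Exhausted_cytotoxic_T"]]
    n_pdl1_cd68 <- ph[["PD-L1_Macrophage"]]
    n_pdl1_tumor <- ph[["PD-L1_Tumor"]]
    prop <- function(num, den) if (den > 0) num / den else NA_real_
    rat <- function(num, den) if (den > 0) num / den else NA_real_
    data.frame(
      sample_id = sid, patient_id = m$patient_id,
      tissue_class = m$tissue_class, tissue_area_mm2 = area,
      n_total = n_total, n_cd3 = n_cd3, n_cd8 = n_cd8, n_treg = n_treg,
      n_cd68 = n_cd68, n_tumor = n_tumor, n_pd1_cd8 = n_pd1_cd8,
      n_pdl1_cd68 = n_pdl1_cd68, n_pdl1_tumor = n_pdl1_tumor,
      density_cd3 = n_cd3 / area, density_cd8 = n_cd8 / area,
      density_treg = n_treg / area, density_cd68 = n_cd68 / area,
      density_tumor = n_tumor / area,
      density_pd1_cd8 = n_pd1_cd8 / area,
      density_pdl1_cd68 = n_pdl1_cd68 / area,
      p_cd8_cd3 = prop(n_cd8, n_cd3),
      p_pd1cd8_cd8 = prop(n_pd1_cd8, n_cd8),
      p_pdl1cd68_cd68 = prop(n_pdl1_cd68, n_cd68),
      p_pdl1_tumor = prop(n_pdl1_tumor, n_tumor),
      p_pd1cd8_all = prop(n_pd1_cd8, n_total),
      p_pdl1cd68_all = prop(n_pdl1_cd68, n_total),
      ratio_cd68_cd3 = rat(n_cd68, n_cd3),
      ratio_foxp3_cd8 = rat(n_treg, n_cd8),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

.chull_area_mm2 <- function(g) {
  if (nrow(g) < 3L) return(NA_real_)
  h <- chull(g$x_um, g$y_um)
  x <- g$x_um[h]
  y <- g$y_um[h]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2 / 1e6
}

#' Two-group comparison of per-sample statistics
#'
#' Two-tailed Student's t-test (classic equal-variance form by default,
#' Welch via `var_equal = FALSE`) with group means and standard errors, as
#' used for tumor versus adjacent-normal panel comparisons. Undefined
#' (`NA`) values are dropped per group.
#'
#' @param values_a,values_b numeric vectors of per-sample statistics.
#' @param var_equal pool the variance (classic Student) or not (Welch).
#' @param paired paired test (requires equal lengths, pairs with any `NA`
#'   dropped).
#' @return list: `t`, `df`, `p`, `mean_a`, `mean_b`, `sem_a`, `sem_b`,
#'   `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b, var_equal = TRUE,
                           paired = FALSE) {
  if (paired) {
    stopifnot(length(values_a) == length(values_b))
    ok <- complete.cases(values_a, values_b)
    values_a <- values_a[ok]
    values_b <- values_b[ok]
  } else {
    values_a <- values_a[!is.na(values_a)]
    values_b <- values_b[!is.na(values_b)]
  }
  if (length(values_a) < 2L || length(values_b) < 2L) {
    stop("each group needs at least 2 defined values", call. = FALSE)
  }
  sem <- function(v) sd(v) / sqrt(length(v))
  res <- tryCatch(
    t.test(values_a, values_b, var.equal = var_equal, paired = paired),
    error = function(e) NULL)
  if (is.null(res)) {
    # degenerate zero-variance case: identical constants in both groups
    eq <- isTRUE(all.equal(mean(values_a), mean(values_b)))
    res <- list(statistic = c(t = if (eq) 0 else Inf),
                parameter = c(df = length(values_a) + length(values_b) - 2L),
                p.value = if (eq) 1 else 0)
  }
  list(t = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, mean_a = mean(values_a), mean_b = mean(values_b),
       sem_a = sem(values_a), sem_b = sem(values_b),
       n_a = length(values_a), n_b = length(values_b))
}

#' Cross-method density correlation
#'
#' Pearson correlation plus least-squares line (with 95% CI of the slope)
#' between per-sample densities computed by two routes — in this package,
#' gating-derived densities versus densities from ground-truth labels, the
#' internal stand-in for comparing an image-cytometry workflow against a
#' platform's own phenotyping counts.
#'
#' @param densities_a,densities_b paired numeric vectors (length >= 3).
#' @return list: `r`, `p`, `slope`, `intercept`, `slope_ci` (length 2),
#'   `n`. With zero variance in either vector, `r` is `NA` and a warning is
#'   raised.
#' @export
cross_method_correlation <- function(densities_a, densities_b) {
  ok <- complete.cases(densities_a, densities_b)
  a <- densities_a[ok]
  b <- densities_b[ok]
  if (length(a) < 3L) stop("need at least 3 complete pairs", call. = FALSE)
  if (sd(a) == 0 || sd(b) == 0) {
    warning("zero variance: correlation undefined", call. = FALSE)
    return(list(r = NA_real_, p = NA_real_, slope = NA_real_,
                intercept = NA_real_, slope_ci = c(NA_real_, NA_real_),
                n = length(a)))
  }
  ct <- cor.test(a, b, method = "pearson")
  fit <- lm(b ~ a)
  ci <- confint(fit, "a", level = 0.95)
  list(r = unname(ct$estimate), p = ct$p.value,
       slope = unname(coef(fit)[["a"]]),
       intercept = unname(coef(fit)[["(Intercept)"]]),
       slope_ci = as.numeric(ci), n = length(a))
}
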