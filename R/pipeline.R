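#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end run: simulate a TMA cohort, estimate thresholds from the
#' negative control, gate every cell, quantify per-sample densities /
#' proportions / ratios, compare tumor against adjacent normal, correlate
#' gating-derived densities with ground-truth densities, build the
#' PD-1+/-CD8+ versus PD-L1+/-CD68+ proximity band profiles, and fit the
#' survival layer (median splits with Kaplan-Meier/log-rank, the four-group
#' cluster, 1-year ROC/AUC, multivariate Cox). Identical `preset` + `seed`
#' give identical outputs.
#'
#' @param preset a [tma_preset()].
#' @param seed integer RNG seed for the whole run.
#' @param out_dir optional directory; when given, per-sample summaries,
#'   thresholds, profiles, band tests, the Cox table, a results JSON and a
#'   short text report are written there.
#' @param gating_quantile negative-control quantile for
#'   [estimate_thresholds()].
#' @param spec a [band_spec()] for the proximity analysis.
#' @param proximity_metric `"nearest"` or `"pairs"` (see
#'   [proximity_profiles()]).
#' @param area_method density denominator, see [summarize_samples()].
#' @return A list of class `mihcyto_run`; see the individual stage
#'   functions for the element contracts.
#' @export
run_pipeline <- function(preset = tma_preset(), seed = 1, out_dir = NULL,
                         gating_quantile = 0.99, spec = band_spec(),
                         proximity_metric = "nearest",
                         area_method = "meta") {
  sim <- simulate_cohort(preset, seed)
  meta <- sim$tables$meta
  thresholds <- estimate_thresholds(sim$tables, quantile = gating_quantile)
  gated <- gate_cells(sim$tables, thresholds)
  summaries <- summarize_samples(gated, meta, area_method = area_method)
  tumor <- summaries[summaries$tissue_class == "tumor", ]
  normal <- summaries[summaries$tissue_class == "adjacent_normal", ]

  cmp_vars <- c("density_cd3", "density_cd8", "density_treg",
                "density_cd68", "ratio_cd68_cd3", "ratio_foxp3_cd8",
                "p_cd8_cd3", "p_pd1cd8_cd8")
  group_tests <- lapply(setNames(cmp_vars, cmp_vars), function(v) {
    tryCatch(compare_groups(tumor[[v]], normal[[v]]),
             error = function(e) NULL)
  })

  truth_dens <- .truth_densities(sim$truth, meta)
  cm_vars <- c(cd3 = "density_cd3", cd8 = "density_cd8",
               treg = "density_treg", cd68 = "density_cd68",
               tumor = "density_tumor", pd1_cd8 = "density_pd1_cd8",
               pdl1_cd68 = "density_pdl1_cd68")
  cross_method <- lapply(setNames(names(cm_vars), names(cm_vars)),
                         function(k) {
    m <- match(summaries$sample_id, truth_dens$sample_id)
    cross_method_correlation(summaries[[cm_vars[[k]]]],
                             truth_dens[[cm_vars[[k]]]][m])
  })

  prop_corr <- cross_method_correlation(tumor$p_pd1cd8_cd8,
                                        tumor$p_pdl1cd68_cd68)

  gated_t <- gated[gated$sample_id %in% tumor$sample_id, ]
  prof_pd1pos <- proximity_profiles(gated_t, "Exhausted_cytotoxic_T",
                                    "PD-L1_Macrophage", spec,
                                    metric = proximity_metric)
  prof_pd1neg <- proximity_profiles(gated_t, "Cytotoxic_T",
                                    "PD-L1_Macrophage", spec,
                                    metric = proximity_metric)
  band_tests <- compare_profiles(prof_pd1pos, prof_pd1neg)
  prof_pd1pos_nref <- proximity_profiles(gated_t, "Exhausted_cytotoxic_T",
                                         "Macrophage", spec,
                                         metric = proximity_metric)
  prof_pd1neg_nref <- proximity_profiles(gated_t, "Cytotoxic_T",
                                         "Macrophage", spec,
                                         metric = proximity_metric)
  band_tests_negref <- compare_profiles(prof_pd1pos_nref, prof_pd1neg_nref)

  surv_df <- data.frame(
    patient_id = tumor$patient_id,
    time = meta$survival_months[match(tumor$sample_id, meta$sample_id)],
    event = meta$event[match(tumor$sample_id, meta$sample_id)],
    age = meta$age[match(tumor$sample_id, meta$sample_id)],
    sexM = as.integer(meta$sex[match(tumor$sample_id,
                                     meta$sample_id)] == "M"),
    stage = meta$stage[match(tumor$sample_id, meta$sample_id)],
    stringsAsFactors = FALSE)
  split_vars <- c("p_pd1cd8_cd8", "p_pdl1cd68_cd68", "p_pd1cd8_all",
                  "p_pdl1cd68_all", "density_cd3", "density_cd8",
                  "density_treg", "density_cd68", "density_pd1_cd8",
                  "density_pdl1_cd68")
  km_splits <- lapply(setNames(split_vars, split_vars), function(v) {
    tryCatch({
      g <- median_split(tumor[[v]])
      lr <- logrank_test(surv_df$time, surv_df$event, g)
      list(cutoff = attr(g, "cutoff"), group = g, logrank = lr,
           km = lapply(split(seq_along(g), g), function(ix)
             km_estimate(surv_df$time[ix], surv_df$event[ix])))
    }, error = function(e) NULL)
  })

  cluster <- four_group_split(tumor$p_pd1cd8_cd8, tumor$p_pdl1cd68_cd68)
  cluster_lr <- logrank_test(surv_df$time, surv_df$event, cluster)
  cl_ind <- cluster_indicator(cluster)
  early <- surv_df$stage <= 2
  stage_strat <- list(
    early = tryCatch(logrank_test(surv_df$time[early], surv_df$event[early],
                                  cl_ind[early]), error = function(e) NULL),
    advanced = tryCatch(logrank_test(surv_df$time[!early],
                                     surv_df$event[!early], cl_ind[!early]),
                        error = function(e) NULL))

  cox_data <- cbind(surv_df, cluster = cl_ind)
  cox <- cox_fit(cox_data, c("cluster", "age", "sexM", "stage"))

  roc <- lapply(list(cluster = cl_ind, age = surv_df$age,
                     sexM = surv_df$sexM, stage = surv_df$stage),
                function(sc) roc_1yr(sc, surv_df$time, surv_df$event))

  res <- structure(list(
    seed = seed, preset = preset, gating_quantile = gating_quantile,
    spec = spec, proximity_metric = proximity_metric,
    patients = sim$patients, thresholds = thresholds,
    summaries = summaries, group_tests = group_tests,
    cross_method = cross_method, prop_corr = prop_corr,
    profiles = list(pd1pos = prof_pd1pos, pd1neg = prof_pd1neg,
                    pd1pos_negref = prof_pd1pos_nref,
                    pd1neg_negref = prof_pd1neg_nref),
    band_tests = band_tests, band_tests_negref = band_tests_negref,
    surv_df = surv_df, km_splits = km_splits, cluster = cluster,
    cluster_logrank = cluster_lr, stage_stratified = stage_strat,
    cox = cox, roc = roc), class = "mihcyto_run")
  if (!is.null(out_dir)) .write_run(res, out_dir)
  res
}

# per-sample lineage densities implied by the ground-truth labels
.truth_densities <- function(truth, meta) {
  ids <- unique(truth$sample_id)
  row_ix <- split(seq_len(nrow(truth)), truth$sample_id)
  rows <- lapply(ids, function(sid) {
    tr <- truth[row_ix[[sid]], ]
    area <- meta$tissue_area_mm2[match(sid, meta$sample_id)]
    data.frame(sample_id = sid,
               density_cd3 = sum(tr$cd3) / area,
               density_cd8 = sum(tr$cd3 & tr$cd8) / area,
               density_treg = sum(tr$cd3 & tr$foxp3) / area,
               density_cd68 = sum(tr$cd68) / area,
               density_tumor = sum(tr$tumor_marker) / area,
               density_pd1_cd8 = sum(tr$cd3 & tr$cd8 & tr$pd1) / area,
               density_pdl1_cd68 = sum(tr$cd68 & tr$pdl1) / area,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

.write_run <- function(res, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wp <- function(df, f) write.csv(df, file.path(out_dir, f),
                                  row.names = FALSE)
  wp(res$summaries, "summaries.csv")
  wp(data.frame(marker = names(unclass(res$thresholds)),
                threshold = as.numeric(res$thresholds)), "thresholds.csv")
  wp(res$patients, "patients.csv")
  wp(rbind(res$profiles$pd1pos, res$profiles$pd1neg), "profiles.csv")
  wp(res$band_tests, "band_tests.csv")
  wp(res$cox$table, "cox_table.csv")
  js <- list(
    seed = res$seed, preset = res$preset$name,
    gating_quantile = res$gating_quantile,
    proximity_metric = res$proximity_metric,
    proportion_correlation_r = res$prop_corr$r,
    proportion_correlation_p = res$prop_corr$p,
    cross_method_r = lapply(res$cross_method, `[[`, "r"),
    logrank_p = lapply(res$km_splits, function(s)
      if (is.null(s)) NA else s$logrank$p),
    cluster_logrank_p = res$cluster_logrank$p,
    cox = res$cox$table, auc_1yr = lapply(res$roc, `[[`, "auc"))
  jsonlite::write_json(js, file.path(out_dir, "results.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  rep <- c(
    sprintf("mihcyto pipeline run (preset %s, seed %d)",
            res$preset$name, res$seed),
    sprintf("samples: %d tumor, %d adjacent normal",
            sum(res$summaries$tissue_class == "tumor"),
            sum(res$summaries$tissue_class == "adjacent_normal")),
    sprintf("median CD8-of-CD3: tumor %.1f%%, normal %.1f%%",
            100 * median(res$summaries$p_cd8_cd3[
              res$summaries$tissue_class == "tumor"], na.rm = TRUE),
            100 * median(res$summaries$p_cd8_cd3[
              res$summaries$tissue_class == "adjacent_normal"],
              na.rm = TRUE)),
    sprintf("p(PD-1+|CD8+) vs p(PD-L1+|CD68+) across patients: r = %.3f",
            res$prop_corr$r),
    sprintf("four-group cluster log-rank p = %.3g", res$cluster_logrank$p),
    sprintf("Cox cluster HR = %.2f [%.2f-%.2f], p = %.3g",
            res$cox$table$hr[1L], res$cox$table$hr_lo[1L],
            res$cox$table$hr_hi[1L], res$cox$table$p[1L]))
  writeLines(rep, file.path(out_dir, "report.txt"))
  invisible(out_dir)
}

#' @export
print.mihcyto_run <- function(x, ...) {
  cat("<mihcyto_run> preset", x$preset$name, "seed", x$seed, "\n")
  cat(sprintf("  %d tumor / %d adjacent-normal samples\n",
              sum(x$summaries$tissue_class == "tumor"),
              sum(x$summaries$tissue_class == "adjacent_normal")))
  tum <- x$summaries$tissue_class == "tumor"
  cat(sprintf("  median CD8-of-CD3: tumor %.1f%%, normal %.1f%%\n",
              100 * median(x$summaries$p_cd8_cd3[tum], na.rm = TRUE),
              100 * median(x$summaries$p_cd8_cd3[!tum], na.rm = TRUE)))
  cat(sprintf("  cross-patient r[p(PD-1+|CD8+), p(PD-L1+|CD68+)] = %.3f\n",
              x$prop_corr$r))
  nb <- x$band_tests[x$band_tests$band <= 2, ]
  cat(sprintf("  near bands [0,20): PD-1+ %.1f%% vs PD-1- %.1f%% (min p %.2g)\n",
              mean(nb$mean_a), mean(nb$mean_b), min(nb$p)))
  cat(sprintf("  cluster (high/high) Cox HR = %.2f [%.2f-%.2f], p = %.3g\n",
              x$cox$table$hr[1L], x$cox$table$hr_lo[1L],
              x$cox$table$hr_hi[1L], x$cox$table$p[1L]))
  invisible(x)
}
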