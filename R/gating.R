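#' Hierarchical phenotype labels
#'
#' The lineage labels produced by [assign_phenotypes()], in precedence
#' order: tumor-marker+ cells are `Tumor` (or `PD-L1_Tumor` if also PD-L1+);
#' otherwise CD3+ cells branch to `Cytotoxic_T` when CD8+ (and
#' `Exhausted_cytotoxic_T` when additionally PD-1+), `Treg` when FOXP3+
#' (CD8 outranks FOXP3), else `T_cell`; otherwise CD68+ cells are
#' `Macrophage` (`PD-L1_Macrophage` if PD-L1+); everything else is `Other`.
#'
#' @return Character vector of the nine labels.
#' @export
phenotype_levels <- function() {
  c("Tumor", "PD-L1_Tumor", "T_cell", "Cytotoxic_T",
    "Exhausted_cytotoxic_T", "Treg", "Macrophage", "PD-L1_Macrophage",
    "Other")
}

#' Estimate positivity thresholds from a negative control
#'
#' Flow-cytometry-like gating: for each marker the positivity threshold is
#' an upper empirical quantile (type-7 interpolation) of that marker's
#' intensities on the negative-control cells, on which no true staining is
#' present. The DAPI counterstain is the exception — it is stained on the
#' negative control too, so its threshold is fixed at `dapi_threshold`
#' (default 0: any cell with a detected nucleus is DAPI-positive).
#'
#' @param neg_control a [cell_table()] (its `negative_control` samples are
#'   used; if none are flagged, all cells are used) or a plain cells
#'   data.frame.
#' @param quantile quantile of the negative-control intensity distribution,
#'   in (0, 1]; default 0.99.
#' @param dapi_threshold fixed DAPI threshold (a.u.).
#' @return A named numeric vector of class `threshold_set` (one threshold
#'   per marker) with provenance attributes `quantile`, `n_cells`,
#'   `control_samples`.
#' @export
estimate_thresholds <- function(neg_control, quantile = 0.99,
                                dapi_threshold = 0) {
  stopifnot(quantile > 0, quantile <= 1)
  cells <- if (inherits(neg_control, "cell_table")) {
    nc_ids <- neg_control$meta$sample_id[
      neg_control$meta$tissue_class == "negative_control"]
    if (length(nc_ids) > 0L) {
      neg_control$cells[neg_control$cells$sample_id %in% nc_ids, ]
    } else {
      neg_control$cells
    }
  } else {
    as.data.frame(neg_control)
  }
  if (nrow(cells) == 0L) {
    stop("negative-control table is empty", call. = FALSE)
  }
  if (nrow(cells) < 20L) {
    warning("fewer than 20 negative-control cells; thresholds will be noisy",
            call. = FALSE)
  }
  thr <- vapply(marker_names(), function(m) {
    stats::quantile(cells[[m]], probs = quantile, type = 7, names = FALSE)
  }, numeric(1L))
  thr[["dapi"]] <- dapi_threshold
  structure(thr, class = "threshold_set", quantile = quantile,
            n_cells = nrow(cells),
            control_samples = unique(cells$sample_id))
}

#' @export
print.threshold_set <- function(x, ...) {
  cat("<threshold_set> quantile ", attr(x, "quantile"), " on ",
      attr(x, "n_cells"), " control cells\n", sep = "")
  print(setNames(as.numeric(x), names(unclass(x))))
  invisible(x)
}

#' Call per-cell marker positivity
#'
#' A cell is positive for a marker iff its intensity strictly exceeds the
#' marker's threshold (intensity exactly at the threshold is negative).
#'
#' @param x a [cell_table()] or a cells data.frame.
#' @param thresholds a [estimate_thresholds()] result (or named numeric
#'   vector covering every marker).
#' @return data.frame with `sample_id`, `cell_id` and one logical column per
#'   marker.
#' @export
call_positivity <- function(x, thresholds) {
  cells <- if (inherits(x, "cell_table")) x$cells else as.data.frame(x)
  missing_thr <- setdiff(marker_names(), names(unclass(thresholds)))
  if (length(missing_thr) > 0L) {
    stop("no threshold for marker(s): ",
         paste(missing_thr, collapse = ", "), call. = FALSE)
  }
  out <- cells[, c("sample_id", "cell_id")]
  for (m in marker_names()) out[[m]] <- cells[[m]] > thresholds[[m]]
  out
}

#' Assign hierarchical phenotypes
#'
#' Deterministic precedence over the positivity vector (see
#' [phenotype_levels()]): the tumor marker outranks immune markers, the CD3
#' branch outranks CD68, CD8 outranks FOXP3 within CD3+, and PD-1/PD-L1 only
#' refine labels where the hierarchy reads them (PD-1 on CD8+ T cells,
#' PD-L1 on CD68+ macrophages and tumor cells). DAPI-negative rows carry no
#' nucleus and are dropped with a message.
#'
#' @param positivity output of [call_positivity()].
#' @return data.frame `sample_id`, `cell_id`, `phenotype` (factor over
#'   [phenotype_levels()]), one row per DAPI-positive cell.
#' @export
assign_phenotypes <- function(positivity) {
  p <- positivity
  n_drop <- sum(!p$dapi)
  if (n_drop > 0L) {
    message("dropping ", n_drop, " DAPI-negative cell(s)")
    p <- p[p$dapi, ]
  }
  lab <- rep("Other", nrow(p))
  mac <- !p$tumor_marker & !p$cd3 & p$cd68
  lab[mac] <- ifelse(p$pdl1[mac], "PD-L1_Macrophage", "Macrophage")
  tc <- !p$tumor_marker & p$cd3
  lab[tc] <- "T_cell"
  lab[tc & p$foxp3] <- "Treg"
  cyt <- tc & p$cd8
  lab[cyt] <- ifelse(p$pd1[cyt], "Exhausted_cytotoxic_T", "Cytotoxic_T")
  lab[p$tumor_marker] <- ifelse(p$pdl1[p$tumor_marker], "PD-L1_Tumor",
                                "Tumor")
  data.frame(sample_id = p$sample_id, cell_id = p$cell_id,
             phenotype = factor(lab, levels = phenotype_levels()),
             stringsAsFactors = FALSE)
}

#' Gate a cell table end to end
#'
#' Convenience wrapper: positivity calls plus hierarchical phenotype labels,
#' joined back to the cell coordinates.
#'
#' @param x a [cell_table()].
#' @param thresholds a `threshold_set`.
#' @return data.frame with `sample_id`, `cell_id`, `x_um`, `y_um`, the
#'   per-marker logical positivity columns, and `phenotype`; DAPI-negative
#'   cells are dropped.
#' @export
gate_cells <- function(x, thresholds) {
  stopifnot(inherits(x, "cell_table"))
  pos <- call_positivity(x, thresholds)
  ph <- assign_phenotypes(pos)
  keep <- pos$dapi
  out <- cbind(x$cells[keep, c("sample_id", "cell_id", "x_um", "y_um")],
               pos[keep, marker_names()])
  # assign_phenotypes keeps DAPI+ rows in input order, so rows align
  out$phenotype <- ph$phenotype
  rownames(out) <- NULL
  out
}
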