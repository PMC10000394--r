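#' Distance-band specification
#'
#' Equal-width half-open distance bands partitioning `[0, max_radius_um)`:
#' by default ten 10-micrometre bands `[0,10), [10,20), ..., [90,100)`.
#' A distance exactly at `max_radius_um` falls outside every band.
#'
#' @param max_radius_um outer radius in micrometres (default 100).
#' @param n_bands number of bands (default 10).
#' @return list of class `band_spec` with `edges` (length `n_bands + 1`),
#'   `max_radius_um`, `n_bands`.
#' @export
band_spec <- function(max_radius_um = 100, n_bands = 10) {
  stopifnot(max_radius_um > 0, n_bands >= 1)
  structure(list(max_radius_um = max_radius_um, n_bands = as.integer(n_bands),
                 edges = seq(0, max_radius_um, length.out = n_bands + 1L)),
            class = "band_spec")
}

#' Nearest-reference distances
#'
#' Euclidean distance from each query cell to its nearest reference cell,
#' computed with a sorted-axis expanding search (exact, near O(n log n)).
#' An empty reference set yields `NA` for every query (undefined, not
#' zero).
#'
#' @param query,reference two-column matrices or data.frames of coordinates
#'   in a common micrometre frame (columns `x_um`/`y_um` or the first two
#'   columns).
#' @return numeric vector, one distance per query cell.
#' @export
nearest_reference_distances <- function(query, reference) {
  q <- .coords(query)
  r <- .coords(reference)
  if (nrow(q) == 0L) return(numeric(0L))
  .nn_dist_cpp(q[, 1L], q[, 2L], r[, 1L], r[, 2L])
}

.coords <- function(x) {
  if (is.data.frame(x)) {
    if (all(c("x_um", "y_um") %in% names(x))) {
      x <- cbind(x$x_um, x$y_um)
    } else {
      x <- as.matrix(x[, 1:2])
    }
  }
  x <- as.matrix(x)
  if (nrow(x) > 0L && (!is.numeric(x) || any(!is.finite(x)))) {
    stop("coordinates must be finite numerics", call. = FALSE)
  }
  x
}

#' Band profile of nearest-reference distances
#'
#' Bins each query cell into the half-open band containing its
#' nearest-reference distance and expresses band counts as percentages of
#' all query cells in the sample. Cells farther than the outer radius fall
#' in no band, so percentages sum to at most 100.
#'
#' @param distances output of [nearest_reference_distances()].
#' @param spec a [band_spec()].
#' @param total_query denominator for the percentages (defaults to
#'   `length(distances)`; must be >= 1).
#' @param sample_id,query_phenotype,reference_phenotype identifiers carried
#'   into the output.
#' @param total_reference reference-cell count carried into the output.
#' @return data.frame, one row per band: `sample_id`, `query_phenotype`,
#'   `reference_phenotype`, `band`, `band_lo`, `band_hi`, `count`,
#'   `percentage`, `total_query`, `total_reference`.
#' @export
band_profile <- function(distances, spec = band_spec(),
                         total_query = length(distances), sample_id = NA,
                         query_phenotype = "query",
                         reference_phenotype = "reference",
                         total_reference = NA_integer_) {
  stopifnot(inherits(spec, "band_spec"))
  if (total_query < 1L) {
    stop("profile undefined: no query cells", call. = FALSE)
  }
  d <- distances[!is.na(distances)]
  idx <- findInterval(d, spec$edges)           # [lo, hi) half-open bands
  counts <- tabulate(idx[idx >= 1L & idx <= spec$n_bands],
                     nbins = spec$n_bands)
  data.frame(sample_id = sample_id, query_phenotype = query_phenotype,
             reference_phenotype = reference_phenotype,
             band = seq_len(spec$n_bands),
             band_lo = spec$edges[-length(spec$edges)],
             band_hi = spec$edges[-1L], count = counts,
             percentage = 100 * counts / total_query,
             total_query = total_query, total_reference = total_reference,
             stringsAsFactors = FALSE)
}

#' Per-sample proximity profiles between two phenotypes
#'
#' For every sample in a gated cell table, computes the band profile of the
#' query phenotype's distances to its nearest reference-phenotype cell.
#' Two metrics are available: `"nearest"` (default; each query cell counted
#' once, in the band of its nearest reference cell — percentages sum to at
#' most 100) and `"pairs"` (every query-reference pair counted in the band
#' of its distance; percentages are pair counts over
#' `total_query * total_reference`).
#'
#' @param gated output of [gate_cells()].
#' @param query_phenotype,reference_phenotype character vectors of
#'   [phenotype_levels()] selecting the two populations (e.g.
#'   `"Exhausted_cytotoxic_T"` for PD-1+CD8+ T cells and
#'   `"PD-L1_Macrophage"` for PD-L1+CD68+ macrophages).
#' @param spec a [band_spec()].
#' @param metric `"nearest"` or `"pairs"`.
#' @return data.frame of stacked [band_profile()] rows; samples without
#'   query or without reference cells are skipped with a message.
#' @export
proximity_profiles <- function(gated, query_phenotype, reference_phenotype,
                               spec = band_spec(),
                               metric = c("nearest", "pairs")) {
  metric <- match.arg(metric)
  ids <- unique(gated$sample_id)
  out <- vector("list", length(ids))
  skipped <- character(0L)
  qlab <- paste(query_phenotype, collapse = "|")
  rlab <- paste(reference_phenotype, collapse = "|")
  row_ix <- split(seq_len(nrow(gated)), gated$sample_id)
  for (i in seq_along(ids)) {
    g <- gated[row_ix[[ids[i]]], ]
    q <- g[g$phenotype %in% query_phenotype, c("x_um", "y_um")]
    r <- g[g$phenotype %in% reference_phenotype, c("x_um", "y_um")]
    if (nrow(q) == 0L || nrow(r) == 0L) {
      skipped <- c(skipped, ids[i])
      next
    }
    if (metric == "nearest") {
      d <- nearest_reference_distances(q, r)
      out[[i]] <- band_profile(d, spec, total_query = nrow(q),
                               sample_id = ids[i], query_phenotype = qlab,
                               reference_phenotype = rlab,
                               total_reference = nrow(r))
    } else {
      dd <- sqrt(outer(q$x_um, r$x_um, "-")^2 +
                   outer(q$y_um, r$y_um, "-")^2)
      idx <- findInterval(as.numeric(dd), spec$edges)
      counts <- tabulate(idx[idx >= 1L & idx <= spec$n_bands],
                         nbins = spec$n_bands)
      out[[i]] <- data.frame(
        sample_id = ids[i], query_phenotype = qlab,
        reference_phenotype = rlab, band = seq_len(spec$n_bands),
        band_lo = spec$edges[-length(spec$edges)],
        band_hi = spec$edges[-1L], count = counts,
        percentage = 100 * counts / (nrow(q) * nrow(r)),
        total_query = nrow(q), total_reference = nrow(r),
        stringsAsFactors = FALSE)
    }
  }
  if (length(skipped) > 0L) {
    message("skipped ", length(skipped),
            " sample(s) without query or reference cells")
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1L))])
  rownames(res) <- NULL
  res
}

#' Per-band comparison of two sets of proximity profiles
#'
#' For each distance band, compares the per-sample percentages of two query
#' phenotypes (same reference) with a two-tailed Student's t-test; reports
#' per-band group means, standard errors, p-values and the conventional
#' star coding (* p<0.05, ** p<0.01, *** p<0.001). Bands with fewer than
#' two defined values in either group are skipped (`NA` statistics) with a
#' message.
#'
#' @param profiles_a,profiles_b outputs of [proximity_profiles()] for the
#'   two query phenotypes.
#' @param var_equal pooled-variance Student (default) or Welch.
#' @return data.frame, one row per band: `band`, `band_lo`, `band_hi`,
#'   `mean_a`, `sem_a`, `n_a`, `mean_b`, `sem_b`, `n_b`, `t`, `p`, `stars`.
#' @export
compare_profiles <- function(profiles_a, profiles_b, var_equal = TRUE) {
  bands <- sort(unique(profiles_a$band))
  rows <- lapply(bands, function(b) {
    va <- profiles_a$percentage[profiles_a$band == b]
    vb <- profiles_b$percentage[profiles_b$band == b]
    lo <- profiles_a$band_lo[profiles_a$band == b][1L]
    hi <- profiles_a$band_hi[profiles_a$band == b][1L]
    va <- va[!is.na(va)]
    vb <- vb[!is.na(vb)]
    if (length(va) < 2L || length(vb) < 2L) {
      message("band [", lo, ",", hi, ") skipped: fewer than 2 values")
      return(data.frame(band = b, band_lo = lo, band_hi = hi,
                        mean_a = NA_real_, sem_a = NA_real_,
                        n_a = length(va), mean_b = NA_real_,
                        sem_b = NA_real_, n_b = length(vb), t = NA_real_,
                        p = NA_real_, stars = "",
                        stringsAsFactors = FALSE))
    }
    cmp <- compare_groups(va, vb, var_equal = var_equal)
    data.frame(band = b, band_lo = lo, band_hi = hi, mean_a = cmp$mean_a,
               sem_a = cmp$sem_a, n_a = cmp$n_a, mean_b = cmp$mean_b,
               sem_b = cmp$sem_b, n_b = cmp$n_b, t = cmp$t, p = cmp$p,
               stars = p_stars(cmp$p), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Significance stars
#'
#' `***` p < 0.001, `**` p < 0.01, `*` p < 0.05, empty otherwise.
#'
#' @param p numeric vector of p-values.
#' @return character vector.
#' @export
p_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}
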