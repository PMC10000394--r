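#' The mIHC marker panel
#'
#' The eight-marker panel used throughout the package: nuclear counterstain
#' (DAPI), T-cell lineage (CD3, CD8), regulatory T-cell (FOXP3), macrophage
#' (CD68), immune-checkpoint function (PD-1, PD-L1) and an epithelial/tumor
#' marker (PanCK/SOX10, column `tumor_marker`). Thresholding operates on a
#' single per-cell intensity per marker, taken as the mean over the marker's
#' compartment: DAPI and FOXP3 are nuclear, all others cytoplasmic.
#'
#' @return A data.frame with columns `marker` (the intensity column name in a
#'   cell table) and `compartment` (`"nuclear"` or `"cytoplasmic"`).
#' @export
#' @examples
#' marker_panel()
marker_panel <- function() {
  data.frame(
    marker = c("dapi", "cd3", "cd8", "foxp3", "cd68", "pd1", "pdl1",
               "tumor_marker"),
    compartment = c("nuclear", "cytoplasmic", "cytoplasmic", "nuclear",
                    "cytoplasmic", "cytoplasmic", "cytoplasmic",
                    "cytoplasmic"),
    stringsAsFactors = FALSE
  )
}

#' @rdname marker_panel
#' @export
marker_names <- function() marker_panel()$marker

.cell_columns <- function() c("sample_id", "cell_id", "x_um", "y_um",
                              marker_names())

.meta_columns <- function() c("sample_id", "patient_id", "tissue_class",
                              "core_diameter_mm", "tissue_area_mm2",
                              "survival_months", "event", "age", "sex",
                              "stage")

#' Construct and validate a cell table
#'
#' A cell table bundles a per-cell data.frame (one row per segmented cell:
#' sample id, cell id, x/y position in micrometres, and one fluorescence
#' intensity in arbitrary units per marker) with a per-sample metadata
#' data.frame (tissue class, core geometry, and — for patient samples —
#' survival and clinical covariates). It is the container consumed by every
#' downstream stage.
#'
#' Validation enforces the schema invariants: all marker intensities present,
#' finite and nonnegative; coordinates finite; `(sample_id, cell_id)` unique;
#' every cell's `sample_id` present in `meta`.
#'
#' @param cells data.frame with columns `sample_id`, `cell_id`, `x_um`,
#'   `y_um` and one numeric column per marker (see [marker_panel()]).
#' @param meta data.frame of per-sample metadata with at least `sample_id`
#'   and `tissue_class` (`"tumor"`, `"adjacent_normal"` or
#'   `"negative_control"`); patient samples may carry `patient_id`,
#'   `core_diameter_mm`, `tissue_area_mm2`, `survival_months`, `event`,
#'   `age`, `sex`, `stage`.
#' @return An object of class `cell_table`: a list with elements `cells` and
#'   `meta`.
#' @export
cell_table <- function(cells, meta) {
  cells <- as.data.frame(cells, stringsAsFactors = FALSE)
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.cell_columns(), names(cells))
  if (length(missing_cols) > 0L) {
    stop("cell table is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"sample_id" %in% names(meta) || !"tissue_class" %in% names(meta)) {
    stop("sample metadata must have 'sample_id' and 'tissue_class' columns",
         call. = FALSE)
  }
  for (col in setdiff(.meta_columns(), names(meta))) meta[[col]] <- NA
  num_cols <- c("x_um", "y_um", marker_names())
  for (col in num_cols) {
    v <- cells[[col]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v))
      stop("non-numeric value in column '", col, "'",
           if (length(bad)) paste0(" at row ", bad[1L]) else "",
           call. = FALSE)
    }
    if (anyNA(v) || any(!is.finite(v))) {
      stop("non-finite value in column '", col, "' at row ",
           which(!is.finite(v))[1L], call. = FALSE)
    }
  }
  for (col in marker_names()) {
    if (any(cells[[col]] < 0)) {
      stop("negative intensity in column '", col, "' at row ",
           which(cells[[col]] < 0)[1L], call. = FALSE)
    }
  }
  key <- paste(cells$sample_id, cells$cell_id, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- cells[which(duplicated(key))[1L], c("sample_id", "cell_id")]
    stop("duplicate (sample_id, cell_id): (", dup$sample_id, ", ",
         dup$cell_id, ")", call. = FALSE)
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicate sample_id in metadata", call. = FALSE)
  }
  orphan <- setdiff(unique(cells$sample_id), meta$sample_id)
  if (length(orphan) > 0L) {
    stop("cells reference sample_id(s) absent from metadata: ",
         paste(orphan, collapse = ", "), call. = FALSE)
  }
  bad_class <- setdiff(unique(meta$tissue_class),
                       c("tumor", "adjacent_normal", "negative_control"))
  if (length(bad_class) > 0L) {
    stop("unknown tissue_class: ", paste(bad_class, collapse = ", "),
         call. = FALSE)
  }
  structure(list(cells = cells, meta = meta[, .meta_columns()]),
            class = "cell_table")
}

#' @export
print.cell_table <- function(x, ...) {
  cat("<cell_table> ", nrow(x$cells), " cells in ", nrow(x$meta),
      " sample(s)\n", sep = "")
  tc <- table(x$meta$tissue_class)
  cat("  samples:", paste(names(tc), tc, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' Read and write cell tables
#'
#' Plain-CSV serialization of a [cell_table()]. The cell file carries one row
#' per cell with the documented header (`sample_id, cell_id, x_um, y_um,
#' dapi, cd3, cd8, foxp3, cd68, pd1, pdl1, tumor_marker`); the metadata file
#' carries one row per sample. Coordinates are micrometres with the origin at
#' the core bounding-box lower-left and y increasing upward. Because typical
#' segmentation exports use pixel units with y increasing downward, the
#' reader can rescale (`pixel_size_um`) and flip (`flip_y`) on the way in.
#'
#' @param path path of the cell CSV.
#' @param meta_path path of the per-sample metadata CSV.
#' @param pixel_size_um multiply raw coordinates by this factor (default 1:
#'   coordinates already in micrometres).
#' @param flip_y if `TRUE`, negate y and shift so the minimum is 0
#'   (converts image y-down conventions to y-up).
#' @return `read_cell_table()` returns a validated [cell_table()];
#'   `write_cell_table()` invisibly returns the paths written.
#' @export
read_cell_table <- function(path, meta_path, pixel_size_um = 1,
                            flip_y = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (!file.exists(meta_path)) {
    stop("file not found: ", meta_path, call. = FALSE)
  }
  cells <- read.csv(path, stringsAsFactors = FALSE,
                    colClasses = c(sample_id = "character",
                                   cell_id = "character"))
  meta <- read.csv(meta_path, stringsAsFactors = FALSE,
                   colClasses = c(sample_id = "character"))
  if (pixel_size_um != 1) {
    cells$x_um <- cells$x_um * pixel_size_um
    cells$y_um <- cells$y_um * pixel_size_um
  }
  if (flip_y) cells$y_um <- max(cells$y_um) - cells$y_um
  cell_table(cells, meta)
}

#' @param x a [cell_table()].
#' @rdname read_cell_table
#' @export
write_cell_table <- function(x, path, meta_path) {
  stopifnot(inherits(x, "cell_table"))
  write.csv(x$cells[, .cell_columns()], path, row.names = FALSE,
            quote = FALSE)
  write.csv(x$meta, meta_path, row.names = FALSE, quote = FALSE)
  invisible(c(path, meta_path))
}

#' Combine cell tables
#'
#' Row-binds the cells and metadata of several [cell_table()] objects into
#' one (sample ids must not collide).
#'
#' @param ... `cell_table` objects.
#' @return A single validated [cell_table()].
#' @export
bind_cell_tables <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && is.list(xs[[1L]]) && !inherits(xs[[1L]], "cell_table")) {
    xs <- xs[[1L]]
  }
  stopifnot(all(vapply(xs, inherits, logical(1L), "cell_table")))
  cell_table(.rbind_fast(lapply(xs, `[[`, "cells")),
             do.call(rbind, lapply(xs, `[[`, "meta")))
}

# column-wise rbind of structurally identical data.frames (much faster than
# rbind.data.frame for many fragments)
.rbind_fast <- function(dfs) {
  dfs <- dfs[vapply(dfs, function(d) !is.null(d) && nrow(d) > 0L,
                    logical(1L))]
  if (length(dfs) == 0L) return(NULL)
  cols <- lapply(names(dfs[[1L]]), function(cn)
    unlist(lapply(dfs, `[[`, cn), use.names = FALSE))
  names(cols) <- names(dfs[[1L]])
  out <- as.data.frame(cols, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
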