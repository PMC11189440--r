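#' Single-cell Raman spectrum container
#'
#' A `spectrum_set` bundles an intensity matrix (cells x wavenumber
#' channels), the shared wavenumber axis, and one row of per-cell metadata
#' per spectrum. It is the unit every stage of the pipeline consumes and
#' produces.
#'
#' @param axis numeric vector of channel centers in cm^-1; strictly
#'   increasing, finite, length >= 2. After silent-region excision the axis
#'   may contain one internal gap but remains strictly increasing.
#' @param intensities numeric matrix, one row per cell, one column per
#'   channel. Arbitrary counts units; non-negative before baseline
#'   correction, real-valued after.
#' @param meta data.frame of per-cell metadata with columns `cell_id`
#'   (unique), `donor_id`, `batch_id`, `sorted_label` (one of
#'   `"Tconv"`, `"Treg"`, `"FrIII"`), `true_label` (`"Tconv"`, `"Treg"` or
#'   `"unknown"`), `subpop` (`"naive"`, `"effector"` or `"mixed"`) and
#'   `qc_flag` (`"pass"`, `"outlier"` or `"pruned"`). Missing optional
#'   columns are filled with defaults.
#' @return An object of class `spectrum_set`.
#' @export
spectrum_set <- function(axis, intensities, meta) {
  axis <- as.numeric(axis)
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  meta <- .complete_meta(meta, n = nrow(intensities))
  obj <- structure(
    list(axis = axis, intensities = intensities, meta = meta),
    class = "spectrum_set"
  )
  validate_spectrum_set(obj)
  obj
}

.meta_columns <- c("cell_id", "donor_id", "batch_id", "sorted_label",
                   "true_label", "subpop", "qc_flag")

.sorted_levels <- c("Tconv", "Treg", "FrIII")
.true_levels   <- c("Tconv", "Treg", "unknown")
.subpop_levels <- c("naive", "effector", "mixed")
.qc_levels     <- c("pass", "outlier", "pruned")

.complete_meta <- function(meta, n) {
  if (nrow(meta) == 0 && n > 0) {
    meta <- data.frame(cell_id = paste0("cell", seq_len(n)))
  }
  defaults <- list(
    donor_id = "d1", batch_id = "b1", sorted_label = "Tconv",
    true_label = "unknown", subpop = "mixed", qc_flag = "pass"
  )
  for (col in names(defaults)) {
    if (is.null(meta[[col]])) meta[[col]] <- defaults[[col]]
  }
  for (col in .meta_columns) meta[[col]] <- as.character(meta[[col]])
  meta <- meta[, union(.meta_columns, names(meta)), drop = FALSE]
  rownames(meta) <- NULL
  meta
}

#' Validate a spectrum_set's invariants
#'
#' Stops with an informative error if any invariant is violated; returns
#' the object invisibly otherwise.
#'
#' @param x a `spectrum_set`.
#' @return `x`, invisibly.
#' @export
validate_spectrum_set <- function(x) {
  stopifnot(inherits(x, "spectrum_set"))
  axis <- x$axis
  if (length(axis) < 2) stop("axis must have length >= 2")
  if (anyNA(axis) || any(!is.finite(axis))) stop("axis must be finite")
  if (any(diff(axis) <= 0)) stop("axis not increasing")
  if (ncol(x$intensities) != length(axis)) {
    stop(sprintf("intensity columns (%d) != axis length (%d)",
                 ncol(x$intensities), length(axis)))
  }
  if (nrow(x$intensities) != nrow(x$meta)) {
    stop(sprintf("intensity rows (%d) != metadata rows (%d)",
                 nrow(x$intensities), nrow(x$meta)))
  }
  if (anyNA(x$intensities)) {
    bad <- which(is.na(x$intensities), arr.ind = TRUE)[1, ]
    stop(sprintf("missing intensity at row %d, column %d", bad[1], bad[2]))
  }
  m <- x$meta
  if (anyDuplicated(m$cell_id)) {
    stop(sprintf("duplicate cell_id: %s", m$cell_id[duplicated(m$cell_id)][1]))
  }
  .check_levels(m$sorted_label, .sorted_levels, "sorted_label")
  .check_levels(m$true_label, .true_levels, "true_label")
  .check_levels(m$subpop, .subpop_levels, "subpop")
  .check_levels(m$qc_flag, .qc_levels, "qc_flag")
  invisible(x)
}

.check_levels <- function(values, levels, what) {
  bad <- setdiff(unique(values), levels)
  if (length(bad)) {
    stop(sprintf("invalid %s value: %s (allowed: %s)",
                 what, bad[1], paste(levels, collapse = ", ")))
  }
}

#' @export
print.spectrum_set <- function(x, ...) {
  cat(sprintf("spectrum_set: %d cells x %d channels (%.1f-%.1f cm^-1)\n",
              nrow(x$intensities), length(x$axis),
              min(x$axis), max(x$axis)))
  tab <- table(x$meta$sorted_label)
  cat("  sorted labels:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
  cat("  donors:", paste(unique(x$meta$donor_id), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.spectrum_set <- function(x) dim(x$intensities)

#' Subset a spectrum_set by cell
#'
#' @param x a `spectrum_set`.
#' @param i row (cell) index: integer, logical, or character cell ids.
#' @return a `spectrum_set` with the selected cells, axis unchanged.
#' @export
subset_cells <- function(x, i) {
  stopifnot(inherits(x, "spectrum_set"))
  if (is.character(i)) i <- match(i, x$meta$cell_id)
  if (anyNA(i)) stop("unknown cell_id in subset")
  spectrum_set(x$axis, x$intensities[i, , drop = FALSE],
               x$meta[i, , drop = FALSE])
}

#' Subset a spectrum_set by channel
#'
#' @param x a `spectrum_set`.
#' @param j column (channel) index.
#' @return a `spectrum_set` with the selected channels.
#' @export
subset_channels <- function(x, j) {
  stopifnot(inherits(x, "spectrum_set"))
  spectrum_set(x$axis[j], x$intensities[, j, drop = FALSE], x$meta)
}
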