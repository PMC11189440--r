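#' Read a flat spectra table
#'
#' Reads the package's single flat delimited format: one CSV with the
#' per-cell metadata columns first (`cell_id`, `donor_id`, `batch_id`,
#' `sorted_label`, `true_label`, `subpop`, `qc_flag`), followed by one
#' intensity column per channel whose header is the wavenumber in cm^-1.
#'
#' @param path path to a CSV file written by [write_spectra_table()] (or
#'   any file following the same layout).
#' @return a [spectrum_set()].
#' @export
read_spectra_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop("empty file: ", path)
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  n_meta <- length(.meta_columns)
  if (length(header) < n_meta + 2 ||
      !identical(header[seq_len(n_meta)], .meta_columns)) {
    stop("malformed header: expected metadata columns ",
         paste(.meta_columns, collapse = ", "),
         " followed by wavenumber columns")
  }
  axis <- suppressWarnings(as.numeric(header[-seq_len(n_meta)]))
  if (anyNA(axis)) {
    stop("malformed header: non-numeric wavenumber column ",
         which(is.na(axis))[1])
  }
  if (any(diff(axis) <= 0)) stop("axis not increasing")
  body <- lines[-1]
  n <- length(body)
  n_chan <- length(axis)
  intensities <- matrix(0, n, n_chan)
  meta <- vector("list", n)
  for (i in seq_len(n)) {
    fields <- strsplit(body[i], ",", fixed = TRUE)[[1]]
    if (length(fields) != n_meta + n_chan) {
      stop(sprintf("row %d has %d fields, expected %d",
                   i, length(fields), n_meta + n_chan))
    }
    meta[[i]] <- fields[seq_len(n_meta)]
    vals <- suppressWarnings(as.numeric(fields[-seq_len(n_meta)]))
    if (anyNA(vals)) {
      stop(sprintf("row %d: non-numeric intensity in column %d",
                   i, which(is.na(vals))[1]))
    }
    intensities[i, ] <- vals
  }
  meta_df <- if (n == 0) {
    as.data.frame(stats::setNames(rep(list(character(0)), n_meta),
                                  .meta_columns))
  } else {
    as.data.frame(
      matrix(unlist(meta), nrow = n, byrow = TRUE,
             dimnames = list(NULL, .meta_columns)),
      stringsAsFactors = FALSE
    )
  }
  spectrum_set(axis, intensities, meta_df)
}

#' Write a flat spectra table
#'
#' Writes a [spectrum_set()] to the flat CSV layout read by
#' [read_spectra_table()]. Wavenumbers are serialized with 6 decimal
#' places and intensities with 8 significant digits, so a write/read
#' round trip preserves labels exactly and intensities to serialization
#' precision. The write is atomic (temp file + rename) and two writes of
#' the same set are byte-identical.
#'
#' @param set a [spectrum_set()].
#' @param path output file path; overwritten if present.
#' @return `path`, invisibly.
#' @export
write_spectra_table <- function(set, path) {
  validate_spectrum_set(set)
  header <- paste(c(.meta_columns, sprintf("%.6f", set$axis)),
                  collapse = ",")
  n <- nrow(set$intensities)
  rows <- character(n)
  meta <- set$meta[, .meta_columns, drop = FALSE]
  for (i in seq_len(n)) {
    rows[i] <- paste(
      c(unlist(meta[i, ], use.names = FALSE),
        sprintf("%.8g", set$intensities[i, ])),
      collapse = ","
    )
  }
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  con <- file(tmp, open = "wb")  # binary: fixed "\n", byte-stable
  ok <- FALSE
  tryCatch({
    writeLines(c(header, rows), con, sep = "\n")
    ok <- TRUE
  }, finally = close(con))
  if (!ok || !file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not write ", path)
  }
  invisible(path)
}

#' Load a Raman band assignment table
#'
#' A band table lists wavenumber regions with a molecular assignment and
#' the sign the corresponding separation-vector coefficient is expected to
#' take (`negative` = band stronger in Tconv, `positive` = stronger in
#' Treg). Two tables are packaged: `"murine"` (protein-structure and
#' amino-acid residue bands: amide III beta-sheet/alpha-helix, tryptophan,
#' phenylalanine ring modes, ...) and `"human"` (amide III/amide I
#' negatives plus nucleic-acid positives).
#'
#' @param path path to a CSV with columns `center_cm1`, `tol_cm1`,
#'   `assignment`, `sign`; if `NULL`, the packaged table named by
#'   `organism` is loaded.
#' @param organism `"murine"` or `"human"`; used only when `path` is NULL.
#' @return a data.frame of class `band_table` with the four columns above.
#' @export
load_band_table <- function(path = NULL, organism = c("murine", "human")) {
  if (is.null(path)) {
    organism <- match.arg(organism)
    path <- system.file("extdata", paste0("bands_", organism, ".csv"),
                        package = "ramanTreg", mustWork = TRUE)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("center_cm1", "tol_cm1", "assignment", "sign")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols)) {
    stop("band table missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  tab <- tab[, needed, drop = FALSE]
  if (nrow(tab)) {
    stopifnot(all(tab$center_cm1 > 0), all(tab$tol_cm1 > 0),
              all(tab$sign %in% c("negative", "positive")))
  }
  class(tab) <- c("band_table", "data.frame")
  tab
}

#' Write a JSON report
#'
#' Serializes any study/QC/pruning report list to pretty-printed JSON.
#'
#' @param report a named list.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
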