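#' Remove cosmic-ray spikes by median filtering
#'
#' Channels whose positive deviation from a running median exceeds
#' `threshold` times a robust local scale (running median of absolute
#' residuals, MAD-consistent x1.4826) are replaced by the running median.
#' Because a narrow Raman band top also sits above its own running median,
#' a flagged channel must additionally deviate by more than a third of its
#' local peak prominence (height above a wide running median): a
#' single-channel cosmic ray carries essentially all of its prominence in
#' the median residual, while a real band — at least a few channels wide —
#' carries only a small fraction, so band tops are never flagged even in
#' noiseless spectra. Edges are handled by the shrinking-window medians of
#' [stats::runmed()]. Channels not flagged are returned bit-identical.
#'
#' @param set a [spectrum_set()].
#' @param window odd running-median window length in channels, >= 3.
#' @param threshold flag threshold as a multiple of the robust scale.
#' @return list with `set` (despiked) and `spikes`: a data.frame
#'   (`cell_id`, `channel`, `original`, `replacement`) of every replaced
#'   channel.
#' @export
remove_cosmic_rays <- function(set, window = 5, threshold = 8) {
  validate_spectrum_set(set)
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  n_chan <- length(set$axis)
  if (window > n_chan) stop("window larger than axis")
  wloc <- min(max(25L, window), n_chan - (1 - n_chan %% 2))
  if (wloc %% 2 == 0) wloc <- wloc - 1L
  wide <- min(31L, n_chan - (1 - n_chan %% 2))
  if (wide %% 2 == 0) wide <- wide - 1L
  x <- set$intensities
  rep_list <- vector("list", nrow(x))
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    med <- stats::runmed(y, window, endrule = "median")
    resid <- y - med
    # median-filter residuals are exactly 0 wherever the channel is its
    # window's median, so the running MAD alone collapses; floor it with a
    # first-difference noise estimate (robust to smooth structure)
    sigma <- 1.4826 * stats::median(abs(diff(y))) / sqrt(2)
    scale <- pmax(1.4826 * stats::runmed(abs(resid), wloc,
                                         endrule = "median"), sigma)
    prominence <- y - stats::runmed(y, wide, endrule = "median")
    flag <- resid > 0 & resid > threshold * scale & resid > prominence / 3
    if (any(flag)) {
      rep_list[[i]] <- data.frame(
        cell_id = set$meta$cell_id[i], channel = which(flag),
        original = y[flag], replacement = med[flag],
        scale = scale[flag], stringsAsFactors = FALSE
      )
      x[i, flag] <- med[flag]
    }
  }
  spikes <- do.call(rbind, rep_list)
  if (is.null(spikes)) {
    spikes <- data.frame(cell_id = character(0), channel = integer(0),
                         original = numeric(0), replacement = numeric(0),
                         scale = numeric(0))
  }
  list(set = spectrum_set(set$axis, x, set$meta), spikes = spikes)
}

#' Baseline correction by iterative cubic-spline fitting
#'
#' Fits, per spectrum, a cubic B-spline (knots every `knot_spacing` cm^-1)
#' by iteratively reweighted least squares anchored from below: after each
#' fit, channels more than two noise standard deviations above the curve
#' are demoted to near-zero weight, so peaks stop contributing and the
#' spline interpolates the baseline across them from flanking anchor
#' channels, while baseline-level channels (within noise of the curve)
#' keep full weight. The noise scale is estimated once per spectrum from
#' first differences (MAD-consistent), so smooth misfit cannot inflate it
#' and the iteration converges to the baseline rather than a lower
#' envelope. The final curve is subtracted. Output may contain small negatives (no
#' clipping). A pure smooth baseline with no peaks is removed essentially
#' exactly, and re-applying the correction changes a corrected spectrum by
#' well under 1% of its range.
#'
#' @param set a [spectrum_set()].
#' @param knot_spacing spline knot spacing in cm^-1; must exceed the
#'   channel spacing and should be wide relative to band widths.
#' @param n_iterations re-anchoring iterations, >= 1.
#' @return a baseline-corrected [spectrum_set()].
#' @export
correct_baseline <- function(set, knot_spacing = 100, n_iterations = 10) {
  validate_spectrum_set(set)
  axis <- set$axis
  if (knot_spacing <= stats::median(diff(axis))) {
    stop("knot_spacing smaller than channel spacing")
  }
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  lo <- min(axis); hi <- max(axis)
  knots <- seq(lo + knot_spacing, hi - knot_spacing / 2, by = knot_spacing)
  B <- splines::bs(axis, knots = knots, degree = 3, intercept = TRUE,
                   Boundary.knots = c(lo, hi))
  x <- set$intensities
  for (i in seq_len(nrow(x))) {
    y <- x[i, ]
    sigma <- 1.4826 * stats::median(abs(diff(y))) / sqrt(2)
    w <- rep(1, length(y))
    fit <- y
    for (it in seq_len(n_iterations)) {
      fit <- stats::lm.wfit(B, y, w)$fitted.values
      w <- ifelse(y - fit > 2 * sigma, 1e-4, 1)
    }
    x[i, ] <- y - fit
  }
  spectrum_set(axis, x, set$meta)
}

#' Calibrate the wavenumber axis against a reference spectrum
#'
#' Detects the known reference bands in a measured calibration spectrum
#' (window maximum around each known center, refined by parabolic
#' interpolation), fits a monotone map from nominal to true wavenumber —
#' affine for fewer than 4 detected peaks, monotone cubic (Hyman) with
#' linear extrapolation otherwise — and re-interpolates every spectrum
#' onto the canonical axis. After calibration the reference bands land
#' within half a channel spacing of their known positions.
#'
#' @param set a [spectrum_set()]; its axis is the canonical target grid.
#' @param measured_reference numeric vector: the calibration substance
#'   (e.g. ethanol, [ethanol_reference()]) measured on the same nominal
#'   axis as `set`.
#' @param reference_peaks known band centers of the calibration substance
#'   in cm^-1; default [ethanol_peaks()].
#' @param search_halfwidth half-width of the detection window per peak.
#' @return list with `set` (recalibrated) and `report`: detected vs known
#'   peak positions and the mean recovered offset (`observed - known`).
#' @export
calibrate_axis <- function(set, measured_reference,
                           reference_peaks = ethanol_peaks(),
                           search_halfwidth = 20) {
  validate_spectrum_set(set)
  axis <- set$axis
  if (length(measured_reference) != length(axis)) {
    stop("measured_reference length does not match axis")
  }
  ref <- measured_reference
  floor_amp <- 0.1 * max(ref)
  obs <- known <- numeric(0)
  for (k in reference_peaks) {
    idx <- which(abs(axis - k) <= search_halfwidth)
    if (length(idx) < 3) next
    imax <- idx[which.max(ref[idx])]
    if (imax == idx[1] || imax == idx[length(idx)]) next  # edge, not a peak
    if (ref[imax] < floor_amp) next
    # parabolic refinement through the 3 points around the maximum, in
    # the log domain where Lorentzian/Gaussian tops are near-quadratic
    y3 <- ref[(imax - 1):(imax + 1)]
    if (all(y3 > 0)) y3 <- log(y3)
    denom <- y3[1] - 2 * y3[2] + y3[3]
    delta <- if (denom < 0) 0.5 * (y3[1] - y3[3]) / denom else 0
    delta <- max(min(delta, 0.5), -0.5)
    obs <- c(obs, axis[imax] + delta * (axis[imax + 1] - axis[imax]))
    known <- c(known, k)
  }
  if (length(obs) < 2) {
    stop("calibration error: fewer than 2 reference peaks detected")
  }
  map <- .calibration_map(obs, known)
  w_true <- map(axis)
  if (any(diff(w_true) <= 0)) {
    stop("calibration error: fitted map non-monotone")
  }
  x <- set$intensities
  for (i in seq_len(nrow(x))) {
    x[i, ] <- stats::approx(w_true, x[i, ], xout = axis, rule = 2)$y
  }
  report <- list(
    peaks_known = known, peaks_observed = obs,
    recovered_offset = mean(obs - known),
    map_kind = if (length(obs) >= 4) "monotone_cubic" else "affine"
  )
  list(set = spectrum_set(axis, x, set$meta), report = report)
}

.calibration_map <- function(obs, known) {
  if (length(obs) < 4) {
    fit <- stats::lm.fit(cbind(1, obs), known)
    co <- fit$coefficients
    function(w) co[1] + co[2] * w
  } else {
    sf <- stats::splinefun(obs, known, method = "hyman")
    lo <- min(obs); hi <- max(obs)
    slo <- sf(lo, deriv = 1); shi <- sf(hi, deriv = 1)
    function(w) {
      out <- sf(w)
      out[w < lo] <- sf(lo) + slo * (w[w < lo] - lo)
      out[w > hi] <- sf(hi) + shi * (w[w > hi] - hi)
      out
    }
  }
}

#' Excise the biologically silent region
#'
#' Drops all channels with center in `[low, high]` (closed interval;
#' default the 1800-2700 cm^-1 silent region). A no-op if no channel falls
#' in the range; idempotent. On the default [make_axis()] grid exactly 643
#' channels remain.
#'
#' @param set a [spectrum_set()].
#' @param low,high interval bounds in cm^-1.
#' @return a [spectrum_set()] with the channels removed.
#' @export
remove_silent_region <- function(set, low = 1800, high = 2700) {
  validate_spectrum_set(set)
  keep <- !(set$axis >= low & set$axis <= high)
  if (all(keep)) return(set)
  if (sum(keep) < 2) stop("silent-region removal would leave < 2 channels")
  subset_channels(set, which(keep))
}

#' PCA-based outlier removal
#'
#' Projects centered spectra onto the first `n_components` principal
#' components and flags cells whose score on any retained component
#' deviates from the component median by more than `mad_threshold` MADs
#' (MAD-consistent scaling). Flagged cells get `qc_flag = "outlier"` and
#' are removed. Deterministic.
#'
#' @param set a [spectrum_set()].
#' @param n_components number of components, < number of cells.
#' @param mad_threshold robust z-score cutoff.
#' @return list with `set` (kept cells), `removed_ids` and `removed_meta`
#'   (metadata of removed cells with updated `qc_flag`).
#' @export
pca_outlier_filter <- function(set, n_components = 6, mad_threshold = 5) {
  validate_spectrum_set(set)
  n <- nrow(set$intensities)
  if (n <= n_components) stop("fewer cells than components")
  n_components <- min(n_components, length(set$axis))
  pc <- stats::prcomp(set$intensities, center = TRUE, scale. = FALSE,
                      rank. = n_components)
  scores <- pc$x
  out <- rep(FALSE, n)
  for (j in seq_len(ncol(scores))) {
    s <- scores[, j]
    m <- stats::mad(s)
    if (m == 0) next
    out <- out | (abs(s - stats::median(s)) / m > mad_threshold)
  }
  removed_meta <- set$meta[out, , drop = FALSE]
  if (nrow(removed_meta)) removed_meta$qc_flag <- "outlier"
  list(
    set = subset_cells(set, which(!out)),
    removed_ids = set$meta$cell_id[out],
    removed_meta = removed_meta
  )
}

#' Preprocessing chain configuration
#'
#' @param despike list: `enabled`, `window`, `threshold`.
#' @param baseline list: `enabled`, `knot_spacing`, `n_iterations`.
#' @param calibrate list: `enabled`, `reference` (measured reference
#'   spectrum, or NULL to skip), `peaks`, `search_halfwidth`.
#' @param silent list: `enabled`, `low`, `high`.
#' @param outlier list: `enabled`, `n_components`, `mad_threshold`.
#' @return a nested list of class `preprocessing_config`.
#' @export
preprocessing_config <- function(
    despike = list(enabled = TRUE, window = 5, threshold = 8),
    baseline = list(enabled = TRUE, knot_spacing = 100, n_iterations = 10),
    calibrate = list(enabled = TRUE, reference = NULL,
                     peaks = ethanol_peaks(), search_halfwidth = 20),
    silent = list(enabled = TRUE, low = 1800, high = 2700),
    outlier = list(enabled = TRUE, n_components = 6, mad_threshold = 5)) {
  structure(list(despike = despike, baseline = baseline,
                 calibrate = calibrate, silent = silent, outlier = outlier),
            class = "preprocessing_config")
}

#' Run the full preprocessing chain
#'
#' Applies, in order: cosmic-ray removal, baseline correction, wavenumber
#' calibration (skipped with a note when no measured reference is
#' supplied), silent-region excision, and PCA outlier filtering. The QC
#' report records per-stage parameters and counts; disabled stages are
#' marked `skipped`.
#'
#' @param set a [spectrum_set()].
#' @param config a [preprocessing_config()].
#' @return list with `set` (processed) and `qc` (per-stage report).
#' @export
run_preprocessing <- function(set, config = preprocessing_config()) {
  qc <- list()
  cfg <- config
  if (isTRUE(cfg$despike$enabled)) {
    ds <- remove_cosmic_rays(set, cfg$despike$window, cfg$despike$threshold)
    set <- ds$set
    qc$despike <- list(status = "run", window = cfg$despike$window,
                       threshold = cfg$despike$threshold,
                       n_replaced = nrow(ds$spikes),
                       replacements = ds$spikes)
  } else qc$despike <- list(status = "skipped")
  if (isTRUE(cfg$baseline$enabled)) {
    set <- correct_baseline(set, cfg$baseline$knot_spacing,
                            cfg$baseline$n_iterations)
    qc$baseline <- list(status = "run",
                        knot_spacing = cfg$baseline$knot_spacing,
                        n_iterations = cfg$baseline$n_iterations)
  } else qc$baseline <- list(status = "skipped")
  if (isTRUE(cfg$calibrate$enabled) && !is.null(cfg$calibrate$reference)) {
    cal <- calibrate_axis(set, cfg$calibrate$reference,
                          cfg$calibrate$peaks,
                          cfg$calibrate$search_halfwidth)
    set <- cal$set
    qc$calibrate <- c(list(status = "run"), cal$report)
  } else {
    qc$calibrate <- list(
      status = "skipped",
      note = if (isTRUE(cfg$calibrate$enabled)) "no reference supplied"
             else "disabled"
    )
  }
  if (isTRUE(cfg$silent$enabled)) {
    n_before <- length(set$axis)
    set <- remove_silent_region(set, cfg$silent$low, cfg$silent$high)
    qc$silent <- list(status = "run", low = cfg$silent$low,
                      high = cfg$silent$high,
                      n_removed = n_before - length(set$axis),
                      n_channels = length(set$axis))
  } else qc$silent <- list(status = "skipped")
  if (isTRUE(cfg$outlier$enabled)) {
    fo <- pca_outlier_filter(set, cfg$outlier$n_components,
                             cfg$outlier$mad_threshold)
    set <- fo$set
    qc$outlier <- list(status = "run",
                       n_components = cfg$outlier$n_components,
                       mad_threshold = cfg$outlier$mad_threshold,
                       n_removed = length(fo$removed_ids),
                       removed_ids = fo$removed_ids)
  } else qc$outlier <- list(status = "skipped")
  list(set = set, qc = qc)
}
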