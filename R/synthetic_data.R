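#' Build a uniform wavenumber axis
#'
#' The default grid (600-3050 cm^-1, 1016 channels, ~2.41 cm^-1 spacing)
#' spans the biological fingerprint and CH-stretch regions and is chosen so
#' that excising the silent region (1800-2700 cm^-1, closed interval) with
#' [remove_silent_region()] leaves exactly 643 channels.
#'
#' @param start,stop axis limits in cm^-1, `start < stop`.
#' @param n_channels number of channels, >= 2.
#' @return numeric vector: a strictly increasing uniform grid.
#' @export
make_axis <- function(start = 600, stop = 3050, n_channels = 1016) {
  if (!(start < stop)) stop("start must be < stop")
  if (n_channels < 2) stop("n_channels must be >= 2")
  seq(start, stop, length.out = n_channels)
}

#' Describe one Raman band of the generative model
#'
#' @param center band center in cm^-1.
#' @param width half-width at half-maximum in cm^-1 (> 0).
#' @param base_amplitude mean peak amplitude in arbitrary units (>= 0).
#' @param class_effect signed fractional amplitude difference of Treg
#'   relative to Tconv; a Treg cell's mean amplitude is
#'   `base_amplitude * (1 + class_effect)`. The faithful regime keeps
#'   `|class_effect|` well below `cell_cv`.
#' @param cell_cv coefficient of variation of the per-cell amplitude draw
#'   (lognormal, mean preserved; >= 0).
#' @return a one-row data.frame.
#' @export
band_spec <- function(center, width, base_amplitude,
                      class_effect = 0, cell_cv = 0.15) {
  stopifnot(width > 0, base_amplitude >= 0, cell_cv >= 0)
  data.frame(center = center, width = width,
             base_amplitude = base_amplitude,
             class_effect = class_effect, cell_cv = cell_cv)
}

#' Default generative phenotype template
#'
#' Band model for synthetic CD4+ T-cell spectra. Shared bands carry no
#' class information; discriminative bands carry small (3-5%) amplitude
#' differences between Tconv and Treg at the centers and signs of the
#' packaged murine band table (amide III beta-sheet/alpha-helix and
#' tryptophan bands stronger in Tconv; phenylalanine ring, CH deformation
#' and related bands stronger in Treg). Activation bands are added only to
#' effector cells, identically in both classes, as a class-neutral
#' activation nuisance. A low-order polynomial emulates a fluorescence-like
#' baseline, and a global per-cell intensity factor emulates correlated
#' cell-size/density variability.
#'
#' @param profile_kind `"lorentzian"` (conventional for Raman lines) or
#'   `"gaussian"`.
#' @return a list of class `phenotype_template` with elements
#'   `shared_bands`, `discriminative_bands`, `activation_bands`
#'   (data.frames of [band_spec()] rows), `baseline_coefficients`,
#'   `baseline_cell_cv`, `cell_intensity_cv`, `profile_kind`.
#' @export
default_template <- function(profile_kind = c("lorentzian", "gaussian")) {
  profile_kind <- match.arg(profile_kind)
  shared <- rbind(
    band_spec(621, 6, 0.15), band_spec(643, 6, 0.12),
    band_spec(760, 7, 0.35), band_spec(785, 7, 0.40),
    band_spec(828, 7, 0.18), band_spec(898, 8, 0.12),
    band_spec(937, 8, 0.20), band_spec(1095, 9, 0.25),
    band_spec(1127, 8, 0.22), band_spec(1260, 10, 0.35),
    band_spec(1304, 9, 0.30), band_spec(1340, 9, 0.28),
    band_spec(1575, 8, 0.15), band_spec(1660, 12, 0.90),
    band_spec(2855, 15, 0.50), band_spec(2890, 15, 0.60),
    band_spec(2935, 18, 1.00), band_spec(3010, 12, 0.20)
  )
  disc <- rbind(
    band_spec(734, 7, 0.30, -0.05, 0.10),
    band_spec(855, 7, 0.28, -0.04, 0.12),
    band_spec(1233, 9, 0.45, -0.05, 0.08),
    band_spec(1316, 9, 0.40, -0.04, 0.08),
    band_spec(1559, 8, 0.25, -0.03, 0.10),
    band_spec(1008, 6, 0.85, +0.05, 0.08),
    band_spec(1034, 7, 0.45, +0.04, 0.10),
    band_spec(1181, 7, 0.25, +0.03, 0.10),
    band_spec(1410, 8, 0.30, +0.04, 0.10),
    band_spec(1449, 10, 0.75, +0.05, 0.08),
    band_spec(1603, 7, 0.35, +0.05, 0.10),
    band_spec(1735, 9, 0.25, +0.03, 0.12)
  )
  activation <- band_spec(1585, 8, 0.20, 0, 0.15)
  structure(
    list(
      shared_bands = shared,
      discriminative_bands = disc,
      activation_bands = activation,
      baseline_coefficients = c(1.5, -0.8, 0.4),
      baseline_cell_cv = 0.3,
      cell_intensity_cv = 0.25,
      profile_kind = profile_kind
    ),
    class = "phenotype_template"
  )
}

#' Cohort simulation configuration
#'
#' Defaults restate the study design being emulated: 3 donors measured over
#' 3 batches each (9 batches total) with about 21,600 sorted Tconv/Treg
#' cells, Tconv 3x more abundant than Treg, sorting purities 0.92 (Tconv)
#' and 0.82 (Treg), plus a separately collected Fraction III mixture pool
#' of roughly half the labeled-pool size.
#'
#' @param n_donors number of donors.
#' @param cells_per_donor Tconv+Treg sorted cells per donor.
#' @param tconv_to_treg_ratio class imbalance, >= 1.
#' @param purity_tconv,purity_treg sorted-class composition purities in
#'   (0.5, 1]: the expected fraction of a sorted class whose true phenotype
#'   matches the gate.
#' @param frIII_cells_per_donor Fraction III (unlabeled mixture) cells per
#'   donor; 0 disables the pool.
#' @param frIII_fraction_treg planted true-Treg fraction of the Fraction
#'   III pool; scalar or one value per donor.
#' @param effector_fraction fraction of cells tagged `effector` (the rest
#'   `naive`); effector cells additionally express the template's
#'   class-neutral activation bands.
#' @param batches_per_donor acquisition batches per donor.
#' @param batch_intensity_sd sd of the per-batch lognormal global intensity
#'   factor (fractional).
#' @param batch_shift_sd sd of the per-batch rigid wavenumber shift, cm^-1.
#' @param noise_sd additive Gaussian channel noise, arbitrary units.
#' @param cosmic_ray_rate expected cosmic-ray spikes per spectrum
#'   (Poisson).
#' @param cosmic_ray_amplitude spike amplitude as a multiple of `noise_sd`.
#' @param baseline logical: include the fluorescence-like baseline.
#' @param seed integer; fully determines the cohort.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_donors = 3,
                          cells_per_donor = 7200,
                          tconv_to_treg_ratio = 3,
                          purity_tconv = 0.92,
                          purity_treg = 0.82,
                          frIII_cells_per_donor = round(cells_per_donor * 0.48),
                          frIII_fraction_treg = 0.75,
                          effector_fraction = 0.5,
                          batches_per_donor = 3,
                          batch_intensity_sd = 0.05,
                          batch_shift_sd = 0.5,
                          noise_sd = 0.01,
                          cosmic_ray_rate = 0.1,
                          cosmic_ray_amplitude = 30,
                          baseline = TRUE,
                          seed = 1L) {
  cfg <- list(
    n_donors = n_donors, cells_per_donor = cells_per_donor,
    tconv_to_treg_ratio = tconv_to_treg_ratio,
    purity_tconv = purity_tconv, purity_treg = purity_treg,
    frIII_cells_per_donor = frIII_cells_per_donor,
    frIII_fraction_treg = frIII_fraction_treg,
    effector_fraction = effector_fraction,
    batches_per_donor = batches_per_donor,
    batch_intensity_sd = batch_intensity_sd,
    batch_shift_sd = batch_shift_sd,
    noise_sd = noise_sd,
    cosmic_ray_rate = cosmic_ray_rate,
    cosmic_ray_amplitude = cosmic_ray_amplitude,
    baseline = baseline,
    seed = as.integer(seed)
  )
  stopifnot(n_donors >= 1, tconv_to_treg_ratio >= 1,
            purity_tconv > 0.5, purity_tconv <= 1,
            purity_treg > 0.5, purity_treg <= 1,
            effector_fraction >= 0, effector_fraction <= 1,
            batches_per_donor >= 1, noise_sd >= 0,
            cosmic_ray_rate >= 0)
  class(cfg) <- "cohort_config"
  cfg
}

.profile_matrix <- function(centers, widths, axis, kind) {
  out <- matrix(0, length(centers), length(axis))
  for (b in seq_along(centers)) {
    u <- (axis - centers[b]) / widths[b]
    out[b, ] <- if (kind == "gaussian") exp(-log(2) * u^2)
                else 1 / (1 + u^2)
  }
  out
}

# lognormal multiplier with mean exactly 1 and the given cv
.lognormal_factor <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -s^2 / 2, s))
}

.all_bands <- function(template) {
  rbind(template$shared_bands, template$discriminative_bands,
        template$activation_bands)
}

#' Render one synthetic spectrum
#'
#' Sum of band profiles (Lorentzian or Gaussian), with each discriminative
#' band's amplitude scaled by `(1 + class_effect)` if and only if the cell
#' is a Treg, plus the polynomial baseline and additive Gaussian noise.
#' With `cell_draws = NULL` all per-cell factors are at their mean (1), so
#' a single zero-noise band of amplitude A peaks at exactly A at the
#' band-center channel.
#'
#' @param template a [default_template()]-shaped template.
#' @param label `"Tconv"` or `"Treg"`.
#' @param axis wavenumber axis; all band centers must lie inside its range.
#' @param cell_draws optional list with `band_factors` (one multiplicative
#'   draw per band, shared then discriminative then activation),
#'   `cell_scale`, `baseline_scale`.
#' @param subpop `"naive"`, `"effector"` or `"mixed"`; activation bands are
#'   rendered only for `"effector"`.
#' @param noise_sd additive Gaussian noise sd.
#' @param baseline logical; include the polynomial baseline.
#' @param seed optional seed for the noise draw (restores the caller RNG).
#' @return numeric intensity vector along `axis`.
#' @export
render_spectrum <- function(template, label, axis, cell_draws = NULL,
                            subpop = "mixed", noise_sd = 0,
                            baseline = TRUE, seed = NULL) {
  stopifnot(label %in% c("Tconv", "Treg"))
  bands <- .all_bands(template)
  if (any(bands$center < min(axis) | bands$center > max(axis))) {
    stop("band center off-axis")
  }
  n_act <- nrow(template$activation_bands)
  if (is.null(cell_draws)) {
    cell_draws <- list(band_factors = rep(1, nrow(bands)),
                       cell_scale = 1, baseline_scale = 1)
  }
  amp <- bands$base_amplitude * cell_draws$band_factors *
    cell_draws$cell_scale
  if (label == "Treg") amp <- amp * (1 + bands$class_effect)
  if (subpop != "effector" && n_act > 0) {
    amp[seq(nrow(bands) - n_act + 1, nrow(bands))] <- 0
  }
  P <- .profile_matrix(bands$center, bands$width, axis,
                       template$profile_kind)
  y <- drop(amp %*% P)
  if (baseline) {
    y <- y + cell_draws$baseline_scale * .baseline_curve(template, axis)
  }
  if (noise_sd > 0) {
    noise <- if (is.null(seed)) stats::rnorm(length(axis), 0, noise_sd)
             else with_seed(seed, stats::rnorm(length(axis), 0, noise_sd))
    y <- y + noise
  }
  y
}

.baseline_curve <- function(template, axis) {
  x <- (axis - min(axis)) / diff(range(axis))
  drop(outer(x, seq_along(template$baseline_coefficients) - 1, `^`) %*%
         template$baseline_coefficients)
}

#' Planted class-difference profile
#'
#' The expected mean Treg spectrum minus mean Tconv spectrum implied by a
#' template, artifacts and noise aside: the sum over discriminative bands
#' of `base_amplitude * class_effect * profile`.
#'
#' @param template a phenotype template.
#' @param axis wavenumber axis.
#' @return numeric vector along `axis`.
#' @export
planted_effect_profile <- function(template, axis) {
  d <- template$discriminative_bands
  P <- .profile_matrix(d$center, d$width, axis, template$profile_kind)
  drop((d$base_amplitude * d$class_effect) %*% P)
}

#' Corrupt true labels at stated sorting purities
#'
#' Converts sorted-class composition purities (the quantity validated by
#' post-sort Foxp3 staining: the fraction of a sorted tube whose true
#' phenotype matches the gate) into per-true-class flip probabilities, then
#' applies independent per-cell flips. With flip probabilities
#' `a = P(sorted Treg | true Tconv)` and `b = P(sorted Tconv | true Treg)`
#' and true-class ratio `r = n_Treg / n_Tconv`, the composition constraints
#' give the closed form `a = A (r - B) / (1 - A B)`,
#' `b = B (1/r - A) / (1 - A B)` where `A = u_R / (1 - u_R)`,
#' `B = u_T / (1 - u_T)` and `u_T`, `u_R` are the impurities
#' `1 - purity_tconv`, `1 - purity_treg`.
#'
#' @param true_labels character vector of `"Tconv"` / `"Treg"`.
#' @param purity_tconv,purity_treg target sorted-class purities in
#'   (0.5, 1].
#' @param seed optional seed (caller RNG restored); if NULL the current
#'   RNG stream is used.
#' @return list with `sorted_labels` (character) and `flipped` (logical).
#' @export
corrupt_labels <- function(true_labels, purity_tconv, purity_treg,
                           seed = NULL) {
  stopifnot(all(true_labels %in% c("Tconv", "Treg")))
  if (purity_tconv <= 0.5 || purity_treg <= 0.5) {
    stop("purity must exceed 0.5 (labels would be anti-informative)")
  }
  if (purity_tconv > 1 || purity_treg > 1) stop("purity must be <= 1")
  rates <- .flip_rates(sum(true_labels == "Tconv"),
                       sum(true_labels == "Treg"),
                       purity_tconv, purity_treg)
  draw <- function() {
    u <- stats::runif(length(true_labels))
    flipped <- ifelse(true_labels == "Tconv", u < rates$a, u < rates$b)
    sorted_labels <- ifelse(flipped,
                            ifelse(true_labels == "Tconv", "Treg", "Tconv"),
                            true_labels)
    list(sorted_labels = sorted_labels, flipped = flipped)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

.flip_rates <- function(n_tconv, n_treg, purity_tconv, purity_treg) {
  uT <- 1 - purity_tconv
  uR <- 1 - purity_treg
  if (uT == 0 && uR == 0) return(list(a = 0, b = 0))
  if (n_tconv == 0 || n_treg == 0) {
    stop("both true classes must be present to calibrate purities")
  }
  A <- uR / (1 - uR)
  B <- uT / (1 - uT)
  r <- n_treg / n_tconv
  a <- A * (r - B) / (1 - A * B)
  b <- B * (1 / r - A) / (1 - A * B)
  if (a < 0 || b < 0 || a >= 0.5 || b >= 0.5) {
    stop("requested purities are infeasible for this class composition")
  }
  list(a = a, b = b)
}

#' Simulate a multi-donor cohort of synthetic spectra
#'
#' Generates, per donor, sorted Tconv/Treg pools at the configured
#' imbalance plus an optional Fraction III mixture pool, assigns cells to
#' acquisition batches carrying lognormal global-intensity factors and
#' rigid wavenumber shifts, renders band + baseline spectra with per-cell
#' amplitude variability, adds channel noise and single-channel cosmic-ray
#' spikes, and corrupts the sorted labels at the configured purities.
#' Everything planted is returned in the ground-truth object.
#'
#' @param template a [default_template()]-shaped template.
#' @param config a [cohort_config()].
#' @param axis wavenumber axis, default [make_axis()].
#' @param keep_clean logical; if TRUE the noiseless, artifact-free
#'   band-only spectra are kept in the ground truth (memory-heavy).
#' @return list with `set` (a [spectrum_set()]; `sorted_label` carries the
#'   corrupted labels, `true_label` the planted truth) and `truth` (list:
#'   `cells` data.frame with per-cell planted facts incl. `flipped`,
#'   `spikes` data.frame of planted cosmic rays, `effect_profile`,
#'   `batch_effects`, and optionally `clean`).
#' @export
simulate_cohort <- function(template = default_template(),
                            config = cohort_config(),
                            axis = make_axis(),
                            keep_clean = FALSE) {
  cfg <- config
  if (cfg$cells_per_donor < 1) stop("zero cells requested")
  n_lab <- cfg$n_donors * cfg$cells_per_donor
  n_fr <- cfg$n_donors * cfg$frIII_cells_per_donor
  n <- n_lab + n_fr
  frac_treg_fr <- rep_len(cfg$frIII_fraction_treg, cfg$n_donors)

  bands <- .all_bands(template)
  if (any(bands$center < min(axis) | bands$center > max(axis))) {
    stop("band center off-axis")
  }
  n_bands <- nrow(bands)
  n_act <- nrow(template$activation_bands)
  act_idx <- if (n_act > 0) seq(n_bands - n_act + 1, n_bands) else integer(0)

  with_seed(cfg$seed, {
    meta_list <- vector("list", cfg$n_donors)
    for (d in seq_len(cfg$n_donors)) {
      donor <- paste0("d", d)
      n_treg <- round(cfg$cells_per_donor /
                        (1 + cfg$tconv_to_treg_ratio))
      n_tconv <- cfg$cells_per_donor - n_treg
      true_lab <- c(rep("Tconv", n_tconv), rep("Treg", n_treg))
      sorted <- corrupt_labels(true_lab, cfg$purity_tconv, cfg$purity_treg)
      n_tr_fr <- round(cfg$frIII_cells_per_donor * frac_treg_fr[d])
      fr_true <- sample(c(rep("Treg", n_tr_fr),
                          rep("Tconv", cfg$frIII_cells_per_donor - n_tr_fr)))
      md <- data.frame(
        donor_id = donor,
        true_label = c(true_lab, fr_true),
        sorted_label = c(sorted$sorted_labels,
                         rep("FrIII", cfg$frIII_cells_per_donor)),
        flipped = c(sorted$flipped, rep(FALSE, cfg$frIII_cells_per_donor)),
        stringsAsFactors = FALSE
      )
      n_d <- nrow(md)
      md$batch_id <- paste0(donor, "_b",
                            sample(rep_len(seq_len(cfg$batches_per_donor),
                                           n_d)))
      n_eff <- round(n_d * cfg$effector_fraction)
      md$subpop <- sample(c(rep("effector", n_eff),
                            rep("naive", n_d - n_eff)))
      meta_list[[d]] <- md[sample.int(n_d), , drop = FALSE]
    }
    meta <- do.call(rbind, meta_list)
    meta$cell_id <- sprintf("c%06d", seq_len(nrow(meta)))
    meta$qc_flag <- "pass"

    batch_ids <- sort(unique(meta$batch_id))
    batch_scale <- .lognormal_factor(length(batch_ids),
                                     cfg$batch_intensity_sd)
    batch_shift <- stats::rnorm(length(batch_ids), 0, cfg$batch_shift_sd)
    names(batch_scale) <- names(batch_shift) <- batch_ids

    base_curve <- .baseline_curve(template, axis)
    intensities <- matrix(0, nrow(meta), length(axis))
    clean <- if (keep_clean) matrix(0, nrow(meta), length(axis)) else NULL

    # per-cell draws, one pass over all cells in metadata order
    n_cells <- nrow(meta)
    cell_scale <- .lognormal_factor(n_cells, template$cell_intensity_cv)
    band_factors <- matrix(1, n_cells, n_bands)
    for (b in seq_len(n_bands)) {
      band_factors[, b] <- .lognormal_factor(n_cells, bands$cell_cv[b])
    }
    base_scale <- .lognormal_factor(n_cells, template$baseline_cell_cv)

    amp <- sweep(band_factors, 2, bands$base_amplitude, `*`) * cell_scale
    is_treg <- meta$true_label == "Treg"
    amp[is_treg, ] <- sweep(amp[is_treg, , drop = FALSE], 2,
                            1 + bands$class_effect, `*`)
    if (n_act > 0) amp[meta$subpop != "effector", act_idx] <- 0

    for (bid in batch_ids) {
      idx <- which(meta$batch_id == bid)
      P <- .profile_matrix(bands$center + batch_shift[bid], bands$width,
                           axis, template$profile_kind)
      sig <- amp[idx, , drop = FALSE] %*% P
      if (keep_clean) {
        P0 <- .profile_matrix(bands$center, bands$width, axis,
                              template$profile_kind)
        clean[idx, ] <- amp[idx, , drop = FALSE] %*% P0
      }
      if (cfg$baseline) sig <- sig + outer(base_scale[idx], base_curve)
      intensities[idx, ] <- sig * batch_scale[bid]
    }
    if (cfg$noise_sd > 0) {
      intensities <- intensities +
        matrix(stats::rnorm(length(intensities), 0, cfg$noise_sd),
               nrow(intensities))
    }

    spikes <- NULL
    if (cfg$cosmic_ray_rate > 0) {
      k <- stats::rpois(n_cells, cfg$cosmic_ray_rate)
      hit <- which(k > 0)
      if (length(hit)) {
        rows <- rep(hit, k[hit])
        cols <- vapply(rows, function(i) sample.int(length(axis), 1),
                       integer(1))
        amps <- cfg$cosmic_ray_amplitude * cfg$noise_sd *
          stats::runif(length(rows), 0.8, 1.2)
        for (j in seq_along(rows)) {
          intensities[rows[j], cols[j]] <-
            intensities[rows[j], cols[j]] + amps[j]
        }
        spikes <- data.frame(cell_id = meta$cell_id[rows],
                             channel = cols, amplitude = amps,
                             stringsAsFactors = FALSE)
      }
    }
    if (is.null(spikes)) {
      spikes <- data.frame(cell_id = character(0), channel = integer(0),
                           amplitude = numeric(0))
    }

    set <- spectrum_set(
      axis, intensities,
      meta[, c("cell_id", "donor_id", "batch_id", "sorted_label",
               "true_label", "subpop", "qc_flag")]
    )
    truth <- list(
      cells = meta[, c("cell_id", "donor_id", "batch_id", "true_label",
                       "sorted_label", "flipped", "subpop")],
      spikes = spikes,
      effect_profile = planted_effect_profile(template, axis),
      batch_effects = data.frame(batch_id = batch_ids,
                                 intensity_scale = unname(batch_scale),
                                 shift = unname(batch_shift)),
      frIII_fraction_treg = frac_treg_fr
    )
    if (keep_clean) truth$clean <- clean
    list(set = set, truth = truth)
  })
}

#' Known ethanol calibration peak positions
#'
#' Raman band centers (cm^-1) of pure ethanol used for daily wavenumber
#' calibration.
#'
#' @return numeric vector of band centers.
#' @export
ethanol_peaks <- function() c(884, 1054, 1096, 1279, 1454, 2928)

#' Synthetic ethanol calibration reference spectrum
#'
#' Renders a Lorentzian-band ethanol spectrum on an axis, optionally with a
#' planted rigid miscalibration (each band peaks at nominal position
#' `center + shift`) and additive noise — the measured reference a
#' calibration test or pipeline run can feed to [calibrate_axis()].
#'
#' @param axis wavenumber axis.
#' @param shift rigid miscalibration in cm^-1 to plant.
#' @param noise_sd additive Gaussian noise sd.
#' @param seed optional seed for the noise.
#' @return numeric intensity vector.
#' @export
ethanol_reference <- function(axis, shift = 0, noise_sd = 0, seed = NULL) {
  centers <- ethanol_peaks()
  amps <- c(1.0, 0.5, 0.55, 0.25, 0.45, 0.9)
  # narrow widths keep apparent maxima of neighboring bands (1054/1096)
  # at their nominal centers, as calibration requires
  P <- .profile_matrix(centers + shift, rep(6, length(centers)), axis,
                       "lorentzian")
  y <- drop(amps %*% P)
  if (noise_sd > 0) {
    y <- y + if (is.null(seed)) stats::rnorm(length(axis), 0, noise_sd)
             else with_seed(seed, stats::rnorm(length(axis), 0, noise_sd))
  }
  y
}
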