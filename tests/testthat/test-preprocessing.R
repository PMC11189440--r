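test_that("despiking removes planted spikes and nothing else", {
  tpl <- tiny_template()
  ax <- tiny_axis()
  set.seed(5)
  n <- 40
  clean <- t(vapply(seq_len(n), function(i) {
    render_spectrum(tpl, "Tconv", ax, noise_sd = 0.01)
  }, numeric(length(ax))))
  spiked <- clean
  spike_ch <- sample(length(ax), n, replace = TRUE)
  for (i in seq_len(n)) {
    spiked[i, spike_ch[i]] <- spiked[i, spike_ch[i]] + 50 * 0.01
  }
  s <- spectrum_set(ax, spiked, make_meta(n))
  ds <- remove_cosmic_rays(s)
  # every reported replacement really happened, and nothing else changed
  changed <- which(ds$set$intensities != spiked, arr.ind = TRUE)
  reported <- cbind(match(ds$spikes$cell_id, s$meta$cell_id),
                    ds$spikes$channel)
  expect_setequal(paste(changed[, 1], changed[, 2]),
                  paste(reported[, 1], reported[, 2]))
  # planted spikes found, and the residual is near the spike-free truth
  hits <- vapply(seq_len(n), function(i) {
    any(ds$spikes$cell_id == s$meta$cell_id[i] &
          ds$spikes$channel == spike_ch[i])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # replacements stay within the spike-free local value range (the spike
  # shifts the window median by at most one order statistic), and are
  # typically within noise of the spike-free running median
  errs <- vapply(which(hits), function(i) {
    ch <- spike_ch[i]
    win <- max(1, ch - 2):min(length(ax), ch + 2)
    v <- ds$set$intensities[i, ch]
    expect_gte(v, min(clean[i, win]) - 3 * 0.01)
    expect_lte(v, max(clean[i, win]) + 3 * 0.01)
    ref <- stats::runmed(clean[i, ], 5, endrule = "median")[ch]
    abs(v - ref)
  }, numeric(1))
  expect_lt(stats::median(errs), 3 * 0.015)
})

test_that("despiking leaves smooth spectra untouched and handles edges", {
  ax <- tiny_axis()
  smooth <- render_spectrum(tiny_template(), "Tconv", ax)  # noiseless
  s <- spectrum_set(ax, rbind(smooth), make_meta(1))
  ds <- remove_cosmic_rays(s)
  expect_equal(nrow(ds$spikes), 0L)
  expect_identical(ds$set$intensities, s$intensities)

  # spike at the first channel is caught via edge handling
  edge <- smooth
  edge[1] <- edge[1] + 1
  ds2 <- remove_cosmic_rays(spectrum_set(ax, rbind(edge), make_meta(1)))
  expect_true(1L %in% ds2$spikes$channel)

  expect_error(remove_cosmic_rays(s, window = 4), "odd")
  expect_error(remove_cosmic_rays(s, window = 9999), "larger than axis")
})

test_that("baseline correction removes smooth backgrounds, keeps peaks", {
  ax <- tiny_axis()
  x01 <- (ax - min(ax)) / diff(range(ax))
  poly <- 2 + 1.5 * x01 - 0.8 * x01^2 + 0.3 * x01^3
  s <- spectrum_set(ax, rbind(poly), make_meta(1))
  out <- correct_baseline(s)
  expect_lt(max(abs(out$intensities)), 0.01 * diff(range(poly)))

  # all-zero spectrum stays all-zero
  z <- correct_baseline(spectrum_set(ax, matrix(0, 1, length(ax)),
                                     make_meta(1)))
  expect_equal(max(abs(z$intensities)), 0)

  # isolated peaks on a polynomial baseline (knot spacing wide relative
  # to band widths, as the contract requires): heights within 2%
  tpl <- tiny_template()
  tpl$shared_bands <- rbind(band_spec(750, 8, 1.0),
                            band_spec(1100, 8, 0.7),
                            band_spec(1500, 8, 0.5))
  tpl$discriminative_bands <- tpl$shared_bands[0, ]
  tpl$activation_bands <- tpl$shared_bands[0, ]
  set.seed(61)
  peaks <- render_spectrum(tpl, "Tconv", ax, baseline = FALSE)
  noisy <- peaks + poly + rnorm(length(ax), 0, 0.01)
  out2 <- correct_baseline(spectrum_set(ax, rbind(noisy), make_meta(1)))
  for (ctr in tpl$shared_bands$center) {
    i <- which.min(abs(ax - ctr))
    expect_lt(abs(out2$intensities[1, i] - peaks[i]),
              0.02 * max(peaks) + 3 * 0.01)
  }

  # translation equivariance: a constant offset is absorbed
  out3 <- correct_baseline(spectrum_set(ax, rbind(noisy + 5), make_meta(1)))
  expect_lt(max(abs(out3$intensities - out2$intensities)), 0.01 * 5)

  # near-idempotence: a second pass changes < 1% of the range
  out4 <- correct_baseline(out2)
  expect_lt(max(abs(out4$intensities - out2$intensities)),
            0.01 * diff(range(out2$intensities)))

  expect_error(correct_baseline(s, knot_spacing = 1), "channel spacing")
})

test_that("axis calibration recovers planted shifts", {
  ax <- make_axis()
  tpl <- default_template()
  y <- render_spectrum(tpl, "Tconv", ax, baseline = FALSE)
  s <- spectrum_set(ax, rbind(y), make_meta(1))
  half_channel <- diff(ax)[1] / 2

  # identity: an on-grid reference leaves spectra unchanged
  cal0 <- calibrate_axis(s, ethanol_reference(ax))
  expect_lt(abs(cal0$report$recovered_offset), half_channel / 2)
  expect_lt(max(abs(cal0$set$intensities - s$intensities)), 0.03)

  # planted +2 cm^-1 rigid shift is recovered within half a channel
  shifted_ref <- ethanol_reference(ax, shift = 2, noise_sd = 0.005,
                                   seed = 3)
  cal2 <- calibrate_axis(s, shifted_ref)
  expect_lt(abs(cal2$report$recovered_offset - 2), half_channel)

  # a reference with one detectable peak is an error
  lone <- ramanTreg:::.profile_matrix(1054, 9, ax, "lorentzian")[1, ]
  expect_error(calibrate_axis(s, lone), "fewer than 2")
})

test_that("silent-region excision follows the closed-interval convention", {
  s <- spectrum_set(c(1700, 1800, 2000, 2700, 2800),
                    matrix(1:10, 2, 5), make_meta(2))
  cut <- remove_silent_region(s)
  expect_equal(cut$axis, c(1700, 2800))
  expect_identical(remove_silent_region(cut)$axis, cut$axis)  # idempotent

  low <- spectrum_set(c(900, 1000, 1100), matrix(1, 1, 3), make_meta(1))
  expect_identical(remove_silent_region(low)$axis, low$axis)

  sim <- simulate_cohort(default_template(),
                         cohort_config(n_donors = 1, cells_per_donor = 8,
                                       frIII_cells_per_donor = 0, seed = 1))
  expect_length(remove_silent_region(sim$set)$axis, 643)
})

test_that("PCA outlier filter flags planted outliers, spares clean data", {
  sim <- quick_cohort(cells_per_donor = 400, n_donors = 1, seed = 17)
  x <- sim$set$intensities
  x[7, ] <- x[7, ] * 100
  s <- spectrum_set(sim$set$axis, x, sim$set$meta)
  res <- pca_outlier_filter(s)
  expect_true(s$meta$cell_id[7] %in% res$removed_ids)
  expect_true(all(res$removed_meta$qc_flag == "outlier"))

  # homogeneous data: < 1% flagged at 5 MADs (Gaussian tail oracle)
  res2 <- pca_outlier_filter(sim$set)
  expect_lt(length(res2$removed_ids) / nrow(x), 0.01)

  expect_error(pca_outlier_filter(subset_cells(s, 1:2), n_components = 5),
               "fewer cells")
})

test_that("the full chain runs in order, honors skips, and is deterministic", {
  sim <- simulate_cohort(
    default_template(),
    cohort_config(n_donors = 1, cells_per_donor = 60,
                  frIII_cells_per_donor = 0, cosmic_ray_rate = 0.2,
                  seed = 12))
  cfg <- preprocessing_config(
    calibrate = list(enabled = TRUE,
                     reference = ethanol_reference(sim$set$axis, shift = 1),
                     peaks = ethanol_peaks(), search_halfwidth = 20))
  r1 <- run_preprocessing(sim$set, cfg)
  expect_equal(names(r1$qc),
               c("despike", "baseline", "calibrate", "silent", "outlier"))
  expect_equal(r1$qc$silent$n_channels, 643)
  expect_equal(r1$qc$calibrate$status, "run")
  expect_length(r1$set$axis, 643)

  cfg2 <- cfg
  cfg2$baseline$enabled <- FALSE
  r2 <- run_preprocessing(sim$set, cfg2)
  expect_equal(r2$qc$baseline$status, "skipped")

  r3 <- run_preprocessing(sim$set, cfg)
  expect_identical(r1$set$intensities, r3$set$intensities)
})
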