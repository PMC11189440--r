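# Acceptance-criteria measurements.
#
# Each function recomputes one property-based acceptance quantity from
# scratch — simulating the stated cohort, running the pipeline, and
# measuring — and returns a small named list. They are shared by
# tests/testthat/test-acceptance.R (which asserts the stated tolerances)
# and scripts/acceptance.R (which reports the numbers). Sample sizes not
# fixed by the criteria are scaled for a single-CPU budget and noted
# per function.

#' Acceptance measurement: AUC oracle equivalence
#'
#' 200 random score/label instances (n <= 100, tied scores forced):
#' trapezoid AUC must equal brute-force pairwise concordance exactly.
#'
#' @param seed master seed.
#' @return list with `n_instances`, `n_exact`, `max_abs_diff`.
#' @export
acc_auc_oracle <- function(seed = 1) {
  with_seed(seed, {
    diffs <- vapply(seq_len(200), function(k) {
      n <- sample(4:100, 1)
      scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)
      y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
      pos <- scores[y == 1]; neg <- scores[y == 0]
      conc <- 0
      for (p in pos) conc <- conc + sum(p > neg) + 0.5 * sum(p == neg)
      oracle <- conc / (length(pos) * length(neg))
      abs(roc_and_auc(scores, y)$auc - oracle)
    }, numeric(1))
    list(n_instances = 200, n_exact = sum(diffs == 0),
         max_abs_diff = max(diffs))
  })
}

#' Acceptance measurement: logistic-fit oracle equivalence
#'
#' 20-point, 2-channel toy set: the unpenalized fit must match an
#' independent BFGS minimizer of the mean negative log-likelihood within
#' 1e-4 per coefficient, and a beyond-the-grid lambda must return exactly
#' zero coefficients with the closed-form prevalence intercept.
#'
#' @param seed master seed.
#' @return list with `max_coef_diff`, `intercept_diff`,
#'   `n_nonzero_large_lambda`, `null_intercept_error`.
#' @export
acc_fit_oracle <- function(seed = 1) {
  with_seed(seed, {
    n <- 20
    X <- matrix(stats::rnorm(n * 2), n, 2)
    y <- as.numeric(stats::runif(n) <
                      stats::plogis(0.4 + X[, 1] - 0.6 * X[, 2]))
    y[1:3] <- 1 - y[1:3]  # guarantee class overlap
    m0 <- fit_lasso_logistic(X, y, 0)
    # independent route: BFGS on the handwritten NLL in the same
    # (population-sd standardized) coordinates
    ctr <- colMeans(X)
    psd <- sqrt(colMeans(X^2) - ctr^2)
    Xs <- sweep(sweep(X, 2, ctr), 2, psd, "/")
    nll <- function(par) {
      eta <- par[1] + drop(Xs %*% par[-1])
      mean(ifelse(eta > 35, eta, log1p(exp(eta))) - y * eta)
    }
    o <- stats::optim(rep(0, 3), nll, method = "BFGS",
                      control = list(maxit = 1000, reltol = 1e-15))
    big <- max(default_lambda_grid(X, y)) * 1.1
    m2 <- fit_lasso_logistic(X, y, big)
    list(
      max_coef_diff = max(abs(m0$coefficients - o$par[-1])),
      intercept_diff = abs(m0$intercept - o$par[1]),
      n_nonzero_large_lambda = sum(m2$coefficients != 0),
      null_intercept_error = abs(m2$intercept -
                                   log(mean(y) / (1 - mean(y))))
    )
  })
}

#' Acceptance measurement: preprocessing recovery
#'
#' Planted 50x-noise cosmic rays (hit rate and unreported alterations),
#' baseline-only residual fraction, planted +2 cm^-1 calibration-shift
#' recovery, and the post-excision channel count on the default axis.
#'
#' @param seed master seed.
#' @return list with `spike_hit_rate`, `n_unreported_changes`,
#'   `baseline_residual_fraction`, `calibration_shift_error_cm1`,
#'   `half_channel_cm1`, `n_channels_post_excision`, `n_spectra`.
#' @export
acc_preprocessing <- function(seed = 1) {
  ax <- make_axis()
  tpl <- default_template()
  noise_sd <- 0.01
  with_seed(seed, {
    n <- 150
    spiked <- matrix(0, n, length(ax))
    spike_ch <- sample(length(ax), n, replace = TRUE)
    clean <- spiked
    for (i in seq_len(n)) {
      clean[i, ] <- render_spectrum(tpl, "Tconv", ax,
                                    noise_sd = noise_sd)
      spiked[i, ] <- clean[i, ]
      spiked[i, spike_ch[i]] <- spiked[i, spike_ch[i]] + 50 * noise_sd
    }
    s <- spectrum_set(ax, spiked, data.frame(cell_id = paste0("c", 1:n)))
    ds <- remove_cosmic_rays(s)
    hits <- vapply(seq_len(n), function(i) {
      any(ds$spikes$cell_id == s$meta$cell_id[i] &
            ds$spikes$channel == spike_ch[i])
    }, logical(1))
    changed <- ds$set$intensities != spiked
    reported <- matrix(FALSE, n, length(ax))
    reported[cbind(match(ds$spikes$cell_id, s$meta$cell_id),
                   ds$spikes$channel)] <- TRUE
    n_unreported <- sum(changed & !reported)

    # baseline-only spectra (no peaks): residual < 1% of range
    x01 <- (ax - min(ax)) / diff(range(ax))
    curves <- rbind(2 + 1.2 * x01 - 0.5 * x01^2,
                    1.5 - 0.8 * x01 + 0.4 * x01^2 + 0.1 * x01^3,
                    3 - 2 * x01 + 0.7 * x01^2)
    bl <- correct_baseline(
      spectrum_set(ax, curves, data.frame(cell_id = paste0("b", 1:3))))
    resid_frac <- max(abs(bl$intensities)) /
      min(apply(curves, 1, function(r) diff(range(r))))

    # planted +2 cm^-1 shift
    y <- render_spectrum(tpl, "Tconv", ax, baseline = FALSE)
    cal <- calibrate_axis(
      spectrum_set(ax, rbind(y), data.frame(cell_id = "a")),
      ethanol_reference(ax, shift = 2, noise_sd = 0.005, seed = seed))
    list(
      n_spectra = n,
      spike_hit_rate = mean(hits),
      n_unreported_changes = n_unreported,
      baseline_residual_fraction = resid_frac,
      calibration_shift_error_cm1 = abs(cal$report$recovered_offset - 2),
      half_channel_cm1 = diff(ax)[1] / 2,
      n_channels_post_excision = length(remove_silent_region(
        spectrum_set(ax, rbind(y), data.frame(cell_id = "a")))$axis)
    )
  })
}

# shared small-cohort builder for the model-level criteria
.acc_cohort <- function(seed, n_donors, cells_per_donor, ...) {
  sim <- simulate_cohort(
    default_template(),
    cohort_config(n_donors = n_donors, cells_per_donor = cells_per_donor,
                  frIII_cells_per_donor = 0, cosmic_ray_rate = 0,
                  baseline = FALSE, seed = seed, ...)
  )
  sim$set <- remove_silent_region(sim$set)
  sim
}

#' Acceptance measurement: confident-learning noise-rate recovery
#'
#' Planted purities 0.92/0.82 at n = 5000 over `n_seeds` seeds: mean
#' class-wise removed fractions versus mean planted corruption rates.
#' Specificity: at planted impurity 0 (same n, 5 seeds) the removed
#' fraction must stay below 5%.
#'
#' @param seed master seed.
#' @param n_seeds replicate count (the criterion states 20).
#' @return list with per-class mean removed/planted rates, their
#'   deviations, `max_class_deviation`, and `clean_removed_fraction`.
#' @export
acc_noise_rate <- function(seed = 1, n_seeds = 20) {
  seeds <- fork_seeds(seed, n_seeds + 5, salt = 4L)
  removed <- planted <- matrix(NA_real_, n_seeds, 2)
  for (k in seq_len(n_seeds)) {
    sim <- .acc_cohort(seeds[k], n_donors = 3, cells_per_donor = 1667)
    set <- sim$set
    rep <- run_confident_learning(set, folds = 5, seed = seeds[k])
    removed[k, ] <- rep$removed_fraction_by_class[c("Tconv", "Treg")]
    planted[k, ] <- c(
      mean(set$meta$true_label[set$meta$sorted_label == "Tconv"] !=
             "Tconv"),
      mean(set$meta$true_label[set$meta$sorted_label == "Treg"] !=
             "Treg"))
  }
  clean <- vapply(seq_len(5), function(k) {
    s2 <- seeds[n_seeds + k]
    sim <- .acc_cohort(s2, n_donors = 3, cells_per_donor = 1667,
                       purity_tconv = 1, purity_treg = 1)
    run_confident_learning(sim$set, folds = 5,
                           seed = s2)$removed_fraction
  }, numeric(1))
  mr <- colMeans(removed); mp <- colMeans(planted)
  list(
    n_seeds = n_seeds, n_cells = 3 * 1667,
    mean_removed_tconv = mr[1], mean_removed_treg = mr[2],
    mean_planted_tconv = mp[1], mean_planted_treg = mp[2],
    deviation_tconv = mr[1] - mp[1], deviation_treg = mr[2] - mp[2],
    max_class_deviation = max(abs(mr - mp)),
    clean_removed_fraction = mean(clean)
  )
}

#' Acceptance measurement: pruning benefit
#'
#' Paired over `n_seeds` seeds at the default planted impurity
#' (purities 0.92/0.82, i.e. 18% Treg-sorted corruption): mean held-out
#' true-label accuracy of pruned-trained versus unpruned-trained models.
#' Labeled pool scaled to 2,499 cells/seed for the compute budget.
#'
#' @param seed master seed.
#' @param n_seeds replicate count (the criterion states 10).
#' @return list with the two mean accuracies and their difference.
#' @export
acc_pruning_benefit <- function(seed = 1, n_seeds = 10) {
  seeds <- fork_seeds(seed, n_seeds, salt = 5L)
  acc <- matrix(NA_real_, n_seeds, 2)
  for (k in seq_len(n_seeds)) {
    sim <- .acc_cohort(seeds[k], n_donors = 3, cells_per_donor = 833)
    ps <- run_pruned_study(sim$set, study_config(seed = seeds[k]))
    acc[k, ] <- c(ps$pruned$test_eval_true$accuracy,
                  ps$unpruned$test_eval_true$accuracy)
  }
  list(n_seeds = n_seeds, n_cells = 3 * 833,
       mean_accuracy_pruned = mean(acc[, 1]),
       mean_accuracy_unpruned = mean(acc[, 2]),
       benefit = mean(acc[, 1]) - mean(acc[, 2]))
}

#' Acceptance measurement: planted-band recovery
#'
#' Default-SNR cohort at n = 4000, fit on the planted (true) labels —
#' isolating separation-vector recovery from label noise, which the
#' noise-rate and pruning criteria cover: fraction of the 12 planted
#' discriminative bands matched with the correct sign by
#' [annotate_bands()] at a floor of 10% of the largest coefficient.
#'
#' @param seed master seed.
#' @return list with `n_bands`, `n_matched_correct_sign`, `fraction`,
#'   `n_nonzero`.
#' @export
acc_band_recovery <- function(seed = 1) {
  sim <- .acc_cohort(seed + 17L, n_donors = 3, cells_per_donor = 1334)
  set <- sim$set
  lam <- as.numeric(select_lambda_cv(set$intensities,
                                     set$meta$true_label, seed = seed))
  m <- fit_lasso_logistic(set$intensities, set$meta$true_label, lam,
                          axis = set$axis)
  ann <- annotate_bands(m, load_band_table(organism = "murine"))
  ok <- sum(ann$bands$matched & ann$bands$sign_agrees, na.rm = TRUE)
  list(n_bands = nrow(ann$bands), n_matched_correct_sign = ok,
       fraction = ok / nrow(ann$bands), n_nonzero = ann$n_nonzero)
}

#' Acceptance measurement: Fraction III mixture recovery
#'
#' Two donors with planted FrIII Treg fractions 0.70 and 0.40
#' (2,000 FrIII cells each), default sort purities; the scoring model is
#' trained with balanced class weights on confident-learning-pruned data
#' (see the methods vignette for why balance is required by the
#' tail-ratio estimator). The labeled pool uses the stated-world default
#' of 7,200 cells/donor.
#'
#' @param seed master seed.
#' @return list with per-donor estimates, planted fractions, errors and
#'   `max_abs_error`.
#' @export
acc_mixture <- function(seed = 1) {
  sim <- simulate_cohort(
    default_template(),
    cohort_config(n_donors = 2, cells_per_donor = 7200,
                  frIII_cells_per_donor = 2000,
                  frIII_fraction_treg = c(0.7, 0.4),
                  cosmic_ray_rate = 0, baseline = FALSE,
                  seed = seed + 23L))
  set <- remove_silent_region(sim$set)
  cfg <- study_config(seed = seed, weights = "balanced")
  ps <- run_pruned_study(set, cfg)
  mix <- score_mixture_fraction(ps$pruned$model, set, cfg)
  err <- mix$per_donor$treg_fraction_estimate -
    mix$per_donor$planted_treg_fraction
  list(
    n_frIII_per_donor = 2000,
    estimate_donor1 = mix$per_donor$treg_fraction_estimate[1],
    estimate_donor2 = mix$per_donor$treg_fraction_estimate[2],
    planted_donor1 = 0.7, planted_donor2 = 0.4,
    error_donor1 = err[1], error_donor2 = err[2],
    max_abs_error = max(abs(err)),
    scoring_model_test_auc = ps$pruned$test_eval$auc
  )
}

#' Acceptance measurement: donor-holdout behavior
#'
#' Paired over `n_seeds` seeds on 3-donor cohorts (600 cells/donor,
#' scaled for budget): with batch effects off, the donor-holdout test AUC
#' must sit within 0.03 of the random-split test AUC; and the mean
#' holdout AUC must be non-increasing as the batch wavenumber shift
#' sweeps 0, 1, 3 cm^-1 (common random numbers across the sweep).
#'
#' @param seed master seed.
#' @param n_seeds replicate count (the criterion states 10).
#' @return list with the paired AUC means, `auc_gap_zero_batch`, and the
#'   mean holdout AUC at each shift.
#' @export
acc_donor_holdout <- function(seed = 1, n_seeds = 10) {
  seeds <- fork_seeds(seed, n_seeds, salt = 6L)
  shifts <- c(0, 1, 3)
  rs_auc <- numeric(n_seeds)
  hold_auc <- matrix(NA_real_, n_seeds, length(shifts))
  for (k in seq_len(n_seeds)) {
    for (j in seq_along(shifts)) {
      sim <- .acc_cohort(seeds[k], n_donors = 3, cells_per_donor = 600,
                         batch_intensity_sd = 0,
                         batch_shift_sd = shifts[j])
      if (j == 1) {
        rs <- run_random_split_study(sim$set,
                                     study_config(seed = seeds[k]))
        rs_auc[k] <- rs$test_eval$auc
      }
      hd <- run_donor_holdout(
        sim$set, study_config(holdout_donor = "d3", seed = seeds[k]))
      hold_auc[k, j] <- hd$test_eval$auc
    }
  }
  m <- colMeans(hold_auc)
  list(
    n_seeds = n_seeds, n_cells = 3 * 600,
    mean_random_split_auc = mean(rs_auc),
    mean_holdout_auc_shift0 = m[1],
    mean_holdout_auc_shift1 = m[2],
    mean_holdout_auc_shift3 = m[3],
    auc_gap_zero_batch = abs(m[1] - mean(rs_auc)),
    monotone_nonincreasing = all(diff(m) <= 1e-12)
  )
}

#' Acceptance measurement: null control
#'
#' All discriminative class effects set to zero: over `n_seeds` seeds the
#' mean random-split test AUC must be 0.5 within 3 standard errors —
#' the generator and pipeline leak no labels.
#'
#' @param seed master seed.
#' @param n_seeds replicate count (the criterion states 20).
#' @return list with `mean_auc`, `se`, `z` (deviation from 0.5 in SEs).
#' @export
acc_null_control <- function(seed = 1, n_seeds = 20) {
  tpl <- default_template()
  tpl$discriminative_bands$class_effect <- 0
  seeds <- fork_seeds(seed, n_seeds, salt = 7L)
  aucs <- vapply(seq_len(n_seeds), function(k) {
    sim <- simulate_cohort(
      tpl,
      cohort_config(n_donors = 1, cells_per_donor = 400,
                    frIII_cells_per_donor = 0, cosmic_ray_rate = 0,
                    baseline = FALSE, purity_tconv = 1, purity_treg = 1,
                    seed = seeds[k]))
    set <- remove_silent_region(sim$set)
    run_random_split_study(set,
                           study_config(seed = seeds[k]))$test_eval$auc
  }, numeric(1))
  se <- stats::sd(aucs) / sqrt(n_seeds)
  list(n_seeds = n_seeds, n_cells = 400, mean_auc = mean(aucs), se = se,
       z = abs(mean(aucs) - 0.5) / se)
}
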