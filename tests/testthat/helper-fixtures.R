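# Shared fixtures and independent oracles.

# A small, fast template on a short axis for unit tests.
tiny_axis <- function(n = 240) make_axis(600, 1800, n)

tiny_template <- function() {
  tpl <- default_template()
  # widths stay >= 2 channels HWHM at the coarse tiny-axis spacing
  tpl$shared_bands <- rbind(
    band_spec(700, 11, 0.5), band_spec(1000, 11, 0.8),
    band_spec(1450, 12, 0.6), band_spec(1660, 14, 0.9)
  )
  tpl$discriminative_bands <- rbind(
    band_spec(820, 11, 0.6, -0.08, 0.10),
    band_spec(1130, 11, 0.7, +0.08, 0.10),
    band_spec(1560, 11, 0.5, +0.06, 0.10)
  )
  tpl$activation_bands <- band_spec(1260, 11, 0.3, 0, 0.15)
  tpl
}

# a small artifact-free cohort for classifier/workflow tests
quick_cohort <- function(cells_per_donor = 200, n_donors = 2, seed = 1,
                         frIII_cells_per_donor = 0, noise_sd = 0.01,
                         template = tiny_template(), ...) {
  simulate_cohort(
    template,
    cohort_config(n_donors = n_donors, cells_per_donor = cells_per_donor,
                  frIII_cells_per_donor = frIII_cells_per_donor,
                  batch_intensity_sd = 0, batch_shift_sd = 0,
                  cosmic_ray_rate = 0, baseline = FALSE,
                  noise_sd = noise_sd, seed = seed, ...),
    axis = tiny_axis()
  )
}

# very separable variant: 15% effects at 5% cell variability
easy_template <- function() {
  tpl <- tiny_template()
  tpl$discriminative_bands$class_effect <-
    0.15 * sign(tpl$discriminative_bands$class_effect)
  tpl$discriminative_bands$cell_cv <- 0.05
  tpl$shared_bands$cell_cv <- 0.05
  tpl$cell_intensity_cv <- 0.05
  tpl
}

# brute-force AUC: pairwise concordance probability, ties count 1/2
oracle_auc <- function(scores, y01) {
  pos <- scores[y01 == 1]
  neg <- scores[y01 == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# independent penalized-NLL minimizer on standardized X (matches the
# fit_lasso_logistic objective); BFGS for the smooth lambda = 0 case,
# Nelder-Mead polish from several starts otherwise
oracle_logistic <- function(X, y01, lambda = 0) {
  ctr <- colMeans(X)
  psd <- sqrt(colMeans(X^2) - ctr^2)  # population sd, as in the package
  Xs <- sweep(sweep(X, 2, ctr), 2, psd, "/")
  nll <- function(par) {
    eta <- par[1] + drop(Xs %*% par[-1])
    mean(ifelse(eta > 35, eta, log1p(exp(eta))) - y01 * eta) +
      lambda * sum(abs(par[-1]))
  }
  p <- ncol(X) + 1
  if (lambda == 0) {
    fit <- stats::optim(rep(0, p), nll, method = "BFGS",
                        control = list(maxit = 1000, reltol = 1e-15))
  } else {
    fit <- stats::optim(rep(0, p), nll, method = "Nelder-Mead",
                        control = list(maxit = 5000, reltol = 1e-14))
    for (k in 1:4) {
      fit <- stats::optim(fit$par, nll, method = "Nelder-Mead",
                          control = list(maxit = 5000, reltol = 1e-14))
    }
  }
  list(intercept = fit$par[1], beta = fit$par[-1], value = fit$value)
}

make_meta <- function(n, prefix = "c") {
  data.frame(cell_id = paste0(prefix, seq_len(n)))
}
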