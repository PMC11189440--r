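test_that("stratified_split keeps proportions, is seeded, rejects", {
  labels <- c(rep("Tconv", 100), rep("Treg", 50))
  sp <- stratified_split(test_fraction = 0.2, seed = 3, labels = labels)
  expect_length(sp$test_ids, 30)
  expect_equal(sum(labels[sp$test_ids] == "Tconv"), 20)
  expect_equal(sum(labels[sp$test_ids] == "Treg"), 10)
  expect_length(intersect(sp$train_ids, sp$test_ids), 0)
  expect_length(union(sp$train_ids, sp$test_ids), 150)
  sp2 <- stratified_split(test_fraction = 0.2, seed = 3, labels = labels)
  expect_identical(sp, sp2)
  expect_error(stratified_split(test_fraction = 0.2, seed = 1,
                                labels = rep("Treg", 10)), "2 classes")
})

test_that("fit matches closed forms and the brute-force NLL oracle", {
  set.seed(7)
  n <- 20
  X <- matrix(rnorm(n * 2), n, 2)
  eta <- 0.3 + X[, 1] - 0.5 * X[, 2]
  y <- as.numeric(runif(n) < plogis(eta))
  y[1:3] <- 1 - y[1:3]  # keep classes overlapping (finite optimum)

  # lambda = 0: agreement with an independent BFGS NLL minimizer
  m0 <- fit_lasso_logistic(X, y, 0)
  oracle <- oracle_logistic(X, y, 0)
  expect_lt(max(abs(m0$coefficients - oracle$beta)), 1e-4)
  expect_lt(abs(m0$intercept - oracle$intercept), 1e-4)

  # moderate lambda: objective within 1e-6 of the independent minimizer
  lam <- 0.05
  m1 <- fit_lasso_logistic(X, y, lam, thresh = 1e-12)
  obj <- function(int, beta) {
    psd <- sqrt(colMeans(X^2) - colMeans(X)^2)
    Xs <- sweep(sweep(X, 2, colMeans(X)), 2, psd, "/")
    eta <- int + drop(Xs %*% beta)
    mean(log1p(exp(eta)) - y * eta) + lam * sum(abs(beta))
  }
  o1 <- oracle_logistic(X, y, lam)
  expect_lt(obj(m1$intercept, m1$coefficients),
            o1$value + 1e-6)

  # large lambda: exactly-zero coefficients, prevalence intercept
  grid <- default_lambda_grid(X, y)
  m2 <- fit_lasso_logistic(X, y, max(grid) * 1.1)
  expect_true(all(m2$coefficients == 0))
  expect_equal(m2$intercept, log(mean(y) / (1 - mean(y))),
               tolerance = 1e-6)

  # duplicating every sample leaves the solution unchanged
  m3 <- fit_lasso_logistic(rbind(X, X), c(y, y), lam, thresh = 1e-12)
  expect_equal(m3$coefficients, m1$coefficients, tolerance = 1e-6)

  # degenerate constant X with lambda 0 errors
  expect_error(fit_lasso_logistic(matrix(1, n, 2), y, 0), "degenerate")
})

test_that("the regularization path is monotone in sparsity", {
  sim <- quick_cohort(cells_per_donor = 150, n_donors = 1, seed = 8)
  X <- sim$set$intensities
  y <- sim$set$meta$true_label
  grid <- default_lambda_grid(X, y, length_out = 8)
  nnz <- vapply(grid, function(l) {
    sum(fit_lasso_logistic(X, y, l)$coefficients != 0)
  }, numeric(1))
  expect_true(all(diff(nnz) >= 0))  # grid is decreasing in lambda
})

test_that("predict_proba follows the logistic closed forms", {
  m <- structure(list(intercept = 0, coefficients = c(0, 0),
                      center = c(0, 0), scale = c(1, 1), lambda = 1,
                      axis = NULL), class = "fitted_model")
  expect_equal(predict_proba(m, matrix(rnorm(10), 5, 2)), rep(0.5, 5))
  m$coefficients <- c(log(3), 0)
  expect_equal(predict_proba(m, matrix(c(1, 0), 1, 2)), 0.75)
  # monotone in a positively weighted channel
  expect_gt(predict_proba(m, matrix(c(2, 0), 1, 2)),
            predict_proba(m, matrix(c(1, 0), 1, 2)))
  expect_error(predict_proba(m, matrix(0, 1, 3)), "axis mismatch")
})

test_that("trapezoid AUC equals brute-force concordance", {
  expect_equal(roc_and_auc(c(3, 2, 1), c(1, 1, 0))$auc, 1)
  expect_equal(roc_and_auc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0))$auc, 0.5)
  expect_equal(roc_and_auc(c(0.9, 0.8, 0.3),
                           c("Treg", "Tconv", "Treg"))$auc, 0.5)
  set.seed(11)
  for (k in 1:60) {
    n <- sample(4:100, 1)
    scores <- sample(seq(0, 1, by = 0.05), n, replace = TRUE)  # force ties
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    r <- roc_and_auc(scores, y)
    expect_identical(r$auc, oracle_auc(scores, y))
    expect_true(all(diff(r$roc_points$fpr) >= 0))
    expect_true(all(diff(r$roc_points$tpr) >= 0))
    expect_equal(unlist(r$roc_points[1, ]), c(fpr = 0, tpr = 0))
    expect_equal(unlist(r$roc_points[nrow(r$roc_points), ]),
                 c(fpr = 1, tpr = 1))
  }
  expect_error(roc_and_auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("confusion_at_threshold counts and conventions", {
  r <- confusion_at_threshold(c(0.9, 0.1), c("Treg", "Tconv"), 0.5)
  expect_equal(r$accuracy, 1)
  expect_equal(unname(diag(r$confusion)), c(1, 1))
  # all predicted Treg on a balanced set
  r2 <- confusion_at_threshold(c(0.9, 0.8), c("Treg", "Tconv"), 0.5)
  expect_equal(r2$accuracy, 0.5)
  # ties at the threshold go to Treg
  r3 <- confusion_at_threshold(0.5, "Treg", 0.5)
  expect_equal(r3$confusion["Treg", "Treg"], 1)
  # raising the threshold trades sensitivity for specificity
  set.seed(2)
  sc <- runif(100)
  y <- rbinom(100, 1, sc)
  c5 <- confusion_at_threshold(sc, y, 0.5)$confusion
  c9 <- confusion_at_threshold(sc, y, 0.9)$confusion
  expect_lte(c9["Treg", "Treg"], c5["Treg", "Treg"])
  expect_gte(c9["Tconv", "Tconv"], c5["Tconv", "Tconv"])
  expect_error(confusion_at_threshold(numeric(0), character(0)), "empty")
})

test_that("select_lambda_cv honors its contract", {
  sim <- quick_cohort(cells_per_donor = 150, n_donors = 1, seed = 13)
  X <- sim$set$intensities
  y <- sim$set$meta$true_label
  expect_equal(as.numeric(select_lambda_cv(X, y, lambda_grid = 0.05,
                                           seed = 1)), 0.05)
  l1 <- select_lambda_cv(X, y, seed = 4)
  l2 <- select_lambda_cv(X, y, seed = 4)
  expect_identical(as.numeric(l1), as.numeric(l2))
  expect_error(select_lambda_cv(X, y, lambda_grid = c(-1, 0.1), seed = 1),
               "non-negative")
  # the selected lambda maximizes the recorded mean out-of-fold AUC,
  # with exact ties resolved to the larger (sparser) lambda
  mauc <- attr(l1, "mean_auc")
  grid <- attr(l1, "grid")
  expect_equal(as.numeric(l1), max(grid[mauc == max(mauc)]))
})

test_that("fitting permuted labels yields chance-level test AUC", {
  set.seed(19)
  aucs <- vapply(1:10, function(s) {
    sim <- quick_cohort(cells_per_donor = 120, n_donors = 1,
                        seed = 100 + s)
    y <- sample(sim$set$meta$true_label)  # break the label-feature link
    sp <- stratified_split(sim$set, 0.3, s, labels = y)
    tr <- match(sp$train_ids, sim$set$meta$cell_id)
    m <- fit_lasso_logistic(sim$set$intensities[tr, ], y[tr], 0.05)
    te <- match(sp$test_ids, sim$set$meta$cell_id)
    roc_and_auc(predict_proba(m, sim$set$intensities[te, ]), y[te])$auc
  }, numeric(1))
  se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * max(se, 0.01))
})

test_that("annotate_bands matches planted coefficients and signs", {
  ax <- seq(600, 1800, by = 2)
  beta <- numeric(length(ax))
  beta[which.min(abs(ax - 1602))] <- 0.8   # near the 1603 entry
  beta[which.min(abs(ax - 900))] <- -0.4   # matches no table entry
  m <- structure(list(intercept = 0, coefficients = beta,
                      center = numeric(length(ax)),
                      scale = rep(1, length(ax)), lambda = 0.1, axis = ax),
                 class = "fitted_model")
  tab <- load_band_table(organism = "murine")
  ann <- annotate_bands(m, tab, min_coefficient = 0.1)
  row1603 <- ann$bands[ann$bands$center_cm1 == 1603, ]
  expect_true(row1603$matched)
  expect_true(row1603$sign_agrees)
  expect_equal(row1603$matched_cm1, 1602)
  expect_equal(sum(ann$bands$matched), 1)
  expect_equal(ann$n_nonzero, 2)

  m$coefficients <- numeric(length(ax))
  ann0 <- annotate_bands(m, tab)
  expect_false(any(ann0$bands$matched))
  expect_equal(ann0$n_nonzero, 0)
})
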