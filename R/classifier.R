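#' Stratified train/test split
#'
#' Splits cells into disjoint, exhaustive train/test pools preserving
#' class proportions to within one cell per class. Seed-deterministic.
#'
#' @param set a [spectrum_set()], or NULL when `labels` is given directly.
#' @param test_fraction fraction in (0, 1).
#' @param seed integer seed.
#' @param labels character vector of class labels (default the set's
#'   `sorted_label`).
#' @return list with `train_ids` and `test_ids` (cell ids, or indices when
#'   called with bare labels).
#' @export
stratified_split <- function(set = NULL, test_fraction = 0.2, seed = 1L,
                             labels = NULL) {
  if (is.null(labels)) labels <- set$meta$sorted_label
  ids <- if (is.null(set)) seq_along(labels) else set$meta$cell_id
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  classes <- unique(labels)
  if (length(classes) < 2) stop("need at least 2 classes to split")
  if (any(table(labels) < 2)) stop("each class needs >= 2 cells")
  test_idx <- integer(0)
  with_seed(seed, {
    for (cl in sort(classes)) {
      members <- which(labels == cl)
      n_test <- round(length(members) * test_fraction)
      n_test <- max(1L, min(n_test, length(members) - 1L))
      test_idx <- c(test_idx, sample(members, n_test))
    }
  })
  test_idx <- sort(test_idx)
  list(train_ids = ids[-test_idx], test_ids = ids[test_idx])
}

.labels_to_binary <- function(y) {
  if (is.numeric(y)) {
    stopifnot(all(y %in% c(0, 1)))
    return(as.numeric(y))
  }
  stopifnot(all(y %in% c("Tconv", "Treg")))
  as.numeric(y == "Treg")
}

.pop_sd <- function(X) {
  sqrt(pmax(colMeans(X * X) - colMeans(X)^2, 0))
}

.balanced_weights <- function(y01) {
  n <- length(y01)
  n1 <- sum(y01)
  w <- ifelse(y01 == 1, n / (2 * n1), n / (2 * (n - n1)))
  w
}

#' Fit an L1-regularized logistic phenotype classifier
#'
#' Minimizes mean negative log-likelihood plus `lambda` times the L1 norm
#' of the coefficients (intercept unpenalized), on internally standardized
#' channels. Positive score means Treg. The coefficient vector on the
#' standardized scale is the model's separation vector. `lambda = 0` is
#' fit by IRLS ([stats::glm.fit()]); `lambda > 0` by
#' [glmnet::glmnet()], whose objective is exactly this one.
#'
#' @param X numeric matrix, cells x channels.
#' @param y labels: `"Tconv"`/`"Treg"` strings or 0/1 (1 = Treg).
#' @param lambda penalty weight >= 0.
#' @param weights `NULL` (unweighted, the default), `"balanced"`
#'   (inverse-prevalence class weights, mean 1), or a numeric vector.
#' @param axis optional wavenumber axis stored with the model (enables
#'   axis checks and band annotation).
#' @param manifest optional list recording training provenance (cell ids,
#'   seed, config); stored verbatim.
#' @param thresh glmnet convergence threshold.
#' @return object of class `fitted_model`: `intercept`, `coefficients`
#'   (standardized scale), `center`, `scale`, `lambda`, `axis`,
#'   `class_orientation`, `manifest`.
#' @export
fit_lasso_logistic <- function(X, y, lambda, weights = NULL, axis = NULL,
                               manifest = list(), thresh = 1e-8) {
  X <- as.matrix(X)
  y01 <- .labels_to_binary(y)
  if (lambda < 0) stop("lambda must be >= 0")
  if (sum(y01) < 2 || sum(1 - y01) < 2) stop("need >= 2 cells per class")
  if (!is.null(axis) && length(axis) != ncol(X)) {
    stop("axis length does not match X columns")
  }
  w <- if (is.null(weights)) rep(1, length(y01))
       else if (identical(weights, "balanced")) .balanced_weights(y01)
       else as.numeric(weights)

  center <- colMeans(X)
  scale_ <- .pop_sd(X)  # population sd: duplication-invariant
  live <- scale_ > 0
  if (!any(live)) {
    stop("degenerate X: all channels constant; model did not converge")
  }
  scale_safe <- ifelse(live, scale_, 1)
  Xs <- sweep(sweep(X, 2, center), 2, scale_safe, "/")

  beta <- numeric(ncol(X))
  if (lambda == 0) {
    fit <- suppressWarnings(
      stats::glm.fit(cbind(1, Xs[, live, drop = FALSE]), y01,
                     weights = w, family = stats::binomial())
    )
    if (!fit$converged || anyNA(fit$coefficients)) {
      stop("unpenalized fit did not converge (degenerate or separable X)")
    }
    intercept <- fit$coefficients[1]
    beta[live] <- fit$coefficients[-1]
  } else {
    # warm-started short path down to the requested lambda: much faster
    # than a cold single-lambda fit, identical solution at the end point
    wm <- w * length(w) / sum(w)
    lmax <- max(abs(crossprod(Xs[, live, drop = FALSE],
                              wm * (y01 - stats::weighted.mean(y01, wm))))) /
      length(y01)
    path <- if (lambda >= lmax) lambda
            else exp(seq(log(lmax), log(lambda), length.out = 10))
    fit <- glmnet::glmnet(
      Xs[, live, drop = FALSE], factor(y01, levels = c(0, 1)),
      family = "binomial", lambda = path, weights = w,
      standardize = FALSE, intercept = TRUE, thresh = thresh
    )
    k <- length(fit$lambda)
    if (abs(fit$lambda[k] - lambda) > 1e-12 * max(1, lambda)) {
      stop("internal: glmnet did not fit the requested lambda")
    }
    intercept <- as.numeric(fit$a0[k])
    beta[live] <- as.numeric(fit$beta[, k])
  }
  structure(
    list(
      intercept = unname(intercept), coefficients = unname(beta),
      center = unname(center), scale = unname(scale_safe),
      lambda = lambda, axis = axis,
      class_orientation = "positive score => Treg",
      weights = if (is.null(weights)) "none"
                else if (identical(weights, "balanced")) "balanced"
                else "custom",
      manifest = manifest
    ),
    class = "fitted_model"
  )
}

#' @export
print.fitted_model <- function(x, ...) {
  cat(sprintf(
    "fitted_model: %d channels, %d nonzero coefficients, lambda = %g\n",
    length(x$coefficients), sum(x$coefficients != 0), x$lambda))
  cat(" ", x$class_orientation, "\n")
  invisible(x)
}

#' Predicted probability of being a Treg
#'
#' Logistic transform of the standardized linear score.
#'
#' @param model a [fit_lasso_logistic()] model.
#' @param X matrix with columns aligned to the model's channels, or a
#'   [spectrum_set()] (its axis is checked against the model's).
#' @return numeric vector of probabilities in (0, 1).
#' @export
predict_proba <- function(model, X) {
  if (inherits(X, "spectrum_set")) {
    if (!is.null(model$axis) &&
        !isTRUE(all.equal(model$axis, X$axis, tolerance = 1e-8))) {
      stop("axis mismatch between model and spectra")
    }
    X <- X$intensities
  }
  X <- as.matrix(X)
  if (ncol(X) != length(model$coefficients)) {
    stop("axis mismatch: X has wrong number of channels")
  }
  Xs <- sweep(sweep(X, 2, model$center), 2, model$scale, "/")
  stats::plogis(drop(model$intercept + Xs %*% model$coefficients))
}

#' Default lambda grid for cross-validation
#'
#' Log-spaced from the smallest lambda that zeroes every coefficient
#' (the max absolute score-prevalence correlation bound) down by two
#' decades — the range where out-of-fold AUC peaks on spectra-shaped
#' problems; the denser tail below it only buys near-saturated models at
#' several times the compute.
#'
#' @param X,y data as in [fit_lasso_logistic()].
#' @param length_out grid size.
#' @return decreasing numeric vector.
#' @export
default_lambda_grid <- function(X, y, length_out = 25) {
  y01 <- .labels_to_binary(y)
  center <- colMeans(X)
  scale_ <- .pop_sd(X)
  scale_[scale_ == 0] <- 1
  Xs <- sweep(sweep(X, 2, center), 2, scale_, "/")
  lmax <- max(abs(crossprod(Xs, y01 - mean(y01)))) / length(y01)
  exp(seq(log(lmax), log(lmax * 1e-2), length.out = length_out))
}

#' Select the LASSO penalty by cross-validated AUC
#'
#' Stratified k-fold cross-validation over a decreasing lambda grid (one
#' warm-started path fit per fold). Returns the grid member maximizing the
#' mean out-of-fold AUC; exact ties resolve to the larger lambda (the
#' sparser model). Seed-deterministic.
#'
#' @param X,y data as in [fit_lasso_logistic()].
#' @param folds number of folds, >= 2.
#' @param lambda_grid decreasing positive grid; default
#'   [default_lambda_grid()].
#' @param seed integer seed for fold assignment.
#' @param weights as in [fit_lasso_logistic()].
#' @return the selected lambda (scalar), with attributes `mean_auc` and
#'   `grid`.
#' @export
select_lambda_cv <- function(X, y, folds = 5, lambda_grid = NULL,
                             seed = 1L, weights = NULL) {
  X <- as.matrix(X)
  y01 <- .labels_to_binary(y)
  if (folds < 2) stop("folds must be >= 2")
  if (is.null(lambda_grid)) lambda_grid <- default_lambda_grid(X, y01)
  if (any(lambda_grid < 0)) stop("lambda grid must be non-negative")
  lambda_grid <- sort(unique(lambda_grid), decreasing = TRUE)
  fold_id <- .stratified_folds(y01, folds, seed)
  auc_fold <- matrix(NA_real_, folds, length(lambda_grid))
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y01[tr])) < 2 || length(unique(y01[!tr])) < 2) {
      stop("a fold lost one of the classes; reduce folds")
    }
    w <- if (identical(weights, "balanced")) .balanced_weights(y01[tr])
         else if (is.null(weights)) rep(1, sum(tr)) else weights[tr]
    center <- colMeans(X[tr, , drop = FALSE])
    scale_ <- .pop_sd(X[tr, , drop = FALSE])
    live <- scale_ > 0
    scale_[!live] <- 1
    Xs_tr <- sweep(sweep(X[tr, live, drop = FALSE], 2, center[live]),
                   2, scale_[live], "/")
    fit <- glmnet::glmnet(Xs_tr, factor(y01[tr], levels = c(0, 1)),
                          family = "binomial", lambda = lambda_grid,
                          weights = w, standardize = FALSE,
                          thresh = 1e-6)
    Xs_te <- sweep(sweep(X[!tr, live, drop = FALSE], 2, center[live]),
                   2, scale_[live], "/")
    scores <- stats::predict(fit, Xs_te, s = lambda_grid,
                             type = "link", exact = FALSE)
    for (j in seq_len(ncol(scores))) {
      auc_fold[f, j] <- roc_and_auc(scores[, j], y01[!tr])$auc
    }
  }
  mean_auc <- colMeans(auc_fold)
  # which.max takes the first maximum; the grid is decreasing, so exact
  # ties already resolve to the larger (sparser) lambda
  out <- lambda_grid[which.max(mean_auc)]
  attr(out, "mean_auc") <- mean_auc
  attr(out, "grid") <- lambda_grid
  out
}

.stratified_folds <- function(y01, folds, seed) {
  fold_id <- integer(length(y01))
  with_seed(seed, {
    for (cl in c(0, 1)) {
      members <- which(y01 == cl)
      fold_id[members] <- sample(rep_len(seq_len(folds), length(members)))
    }
  })
  fold_id
}

#' ROC curve and AUC
#'
#' Sweeps every distinct score as a threshold to build the ROC polyline
#' and integrates it by the trapezoid rule. The result equals the pairwise
#' concordance probability P(score_Treg > score_Tconv) with ties counted
#' one half.
#'
#' @param scores numeric scores or probabilities (higher = more Treg).
#' @param labels `"Tconv"`/`"Treg"` or 0/1.
#' @return list with `roc_points` (data.frame `fpr`, `tpr`, from (0,0) to
#'   (1,1)) and `auc`.
#' @export
roc_and_auc <- function(scores, labels) {
  y01 <- .labels_to_binary(labels)
  n_pos <- sum(y01)
  n_neg <- length(y01) - n_pos
  if (n_pos == 0 || n_neg == 0) stop("both classes must be present")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- y01[ord]
  # indices of the last element of each tie group in descending order
  last <- which(!duplicated(s, fromLast = TRUE))
  tp <- c(0, cumsum(y)[last])
  fp <- c(0, cumsum(1 - y)[last])
  # integer-count trapezoid with one final division: bit-exact equal to
  # the pairwise concordance probability (ties counted one half)
  area2 <- sum(diff(fp) * (utils::head(tp, -1) + utils::tail(tp, -1)))
  auc <- area2 / (2 * n_pos * n_neg)
  list(roc_points = data.frame(fpr = fp / n_neg, tpr = tp / n_pos),
       auc = auc)
}

#' Confusion matrix and accuracy at a probability threshold
#'
#' Cells with score at or above the threshold are called Treg (ties go to
#' Treg by convention; this only matters for degenerate score sets).
#'
#' @param scores numeric scores/probabilities.
#' @param labels `"Tconv"`/`"Treg"` or 0/1.
#' @param threshold call threshold in (0, 1) (or any score cutoff).
#' @return list with `confusion` (2x2 matrix, rows = true, cols =
#'   predicted), `accuracy`, `threshold`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = 0.5) {
  if (!length(scores)) stop("empty input")
  y01 <- .labels_to_binary(labels)
  pred <- as.numeric(scores >= threshold)
  conf <- matrix(0, 2, 2,
                 dimnames = list(true = c("Tconv", "Treg"),
                                 predicted = c("Tconv", "Treg")))
  for (t in 0:1) for (p in 0:1) {
    conf[t + 1, p + 1] <- sum(y01 == t & pred == p)
  }
  list(confusion = conf,
       accuracy = mean(pred == y01),
       threshold = threshold)
}

#' Annotate separation-vector coefficients with known Raman bands
#'
#' Matches each band-table entry to the extremal (largest absolute)
#' coefficient within its tolerance window and reports whether its sign
#' agrees with the expected direction (negative = Tconv, positive = Treg).
#' Entries whose extremal coefficient falls below `min_coefficient` in
#' absolute value are reported unmatched.
#'
#' @param model a [fit_lasso_logistic()] model with a stored axis.
#' @param table a [load_band_table()] table.
#' @param min_coefficient absolute-coefficient floor for a match; default
#'   10% of the largest absolute coefficient.
#' @return list with `bands` (one row per table entry: match flag, matched
#'   wavenumber, coefficient, sign agreement), `n_nonzero` and
#'   `n_channels`.
#' @export
annotate_bands <- function(model, table, min_coefficient = NULL) {
  if (is.null(model$axis)) stop("model has no stored axis")
  beta <- model$coefficients
  if (is.null(min_coefficient)) {
    min_coefficient <- if (any(beta != 0)) 0.1 * max(abs(beta)) else Inf
  }
  rows <- lapply(seq_len(nrow(table)), function(i) {
    ctr <- table$center_cm1[i]
    tol <- table$tol_cm1[i]
    idx <- which(abs(model$axis - ctr) <= tol)
    if (!length(idx) || all(beta[idx] == 0)) {
      return(data.frame(center_cm1 = ctr, tol_cm1 = tol,
                        assignment = table$assignment[i],
                        expected_sign = table$sign[i], matched = FALSE,
                        matched_cm1 = NA_real_, coefficient = NA_real_,
                        sign_agrees = NA))
    }
    j <- idx[which.max(abs(beta[idx]))]
    matched <- abs(beta[j]) >= min_coefficient
    sign_ok <- if (!matched) NA else {
      (beta[j] > 0) == (table$sign[i] == "positive")
    }
    data.frame(center_cm1 = ctr, tol_cm1 = tol,
               assignment = table$assignment[i],
               expected_sign = table$sign[i], matched = matched,
               matched_cm1 = if (matched) model$axis[j] else NA_real_,
               coefficient = if (matched) beta[j] else NA_real_,
               sign_agrees = sign_ok)
  })
  list(bands = do.call(rbind, rows),
       n_nonzero = sum(beta != 0),
       n_channels = length(beta))
}
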