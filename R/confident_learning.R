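#' Out-of-fold class probabilities
#'
#' Estimates, for every labeled cell, the probability of each phenotype
#' from a model whose training fold excluded that cell. The penalty is
#' chosen once on the full pool by the same cross-validated rule as the
#' main fit ([select_lambda_cv()]) and reused in every fold, so one
#' consistent estimator runs throughout. Seed-deterministic.
#'
#' @param set a [spectrum_set()] (or a bare intensity matrix).
#' @param labels sorted labels, `"Tconv"`/`"Treg"`; default the set's
#'   `sorted_label`.
#' @param folds number of folds, >= 2 (up to n for leave-one-out).
#' @param lambda `"auto"` (CV on the full pool) or a numeric penalty.
#' @param seed integer seed.
#' @param weights as in [fit_lasso_logistic()].
#' @return n x 2 matrix with columns `Tconv`, `Treg`, rows summing to 1;
#'   attributes `fold_id` and `fold_train_ids` record the fold layout.
#' @export
out_of_fold_probs <- function(set, labels = NULL, folds = 5,
                              lambda = "auto", seed = 1L, weights = NULL) {
  if (inherits(set, "spectrum_set")) {
    if (is.null(labels)) labels <- set$meta$sorted_label
    X <- set$intensities
    ids <- set$meta$cell_id
  } else {
    X <- as.matrix(set)
    ids <- as.character(seq_len(nrow(X)))
  }
  if (folds < 2) stop("folds must be >= 2")
  y01 <- .labels_to_binary(labels)
  seeds <- fork_seeds(seed, 2)
  if (identical(lambda, "auto")) {
    lambda <- as.numeric(select_lambda_cv(X, y01, folds = folds,
                                          seed = seeds[1],
                                          weights = weights))
  }
  fold_id <- .stratified_folds(y01, folds, seeds[2])
  probs <- numeric(length(y01))
  train_ids <- vector("list", folds)
  for (f in seq_len(folds)) {
    tr <- fold_id != f
    if (length(unique(y01[tr])) < 2) stop("a training fold lost a class")
    m <- fit_lasso_logistic(X[tr, , drop = FALSE], y01[tr], lambda,
                            weights = weights)
    probs[!tr] <- predict_proba(m, X[!tr, , drop = FALSE])
    train_ids[[f]] <- ids[tr]
  }
  out <- cbind(Tconv = 1 - probs, Treg = probs)
  rownames(out) <- ids
  attr(out, "fold_id") <- fold_id
  attr(out, "fold_train_ids") <- train_ids
  attr(out, "lambda") <- lambda
  out
}

#' Per-class self-confidence thresholds
#'
#' The confident-learning threshold for class c is the mean predicted
#' probability of c among cells whose given (sorted) label is c.
#'
#' @param oof_probs n x 2 out-of-fold probability matrix
#'   ([out_of_fold_probs()]).
#' @param labels given labels, `"Tconv"`/`"Treg"`.
#' @return named numeric vector `c(Tconv = ..., Treg = ...)`.
#' @export
class_thresholds <- function(oof_probs, labels) {
  stopifnot(all(labels %in% c("Tconv", "Treg")))
  out <- vapply(c("Tconv", "Treg"), function(cl) {
    members <- labels == cl
    if (!any(members)) stop("empty class: ", cl)
    mean(oof_probs[members, cl])
  }, numeric(1))
  out
}

#' Confident joint counts
#'
#' A cell with given label s is counted in entry (s, t*), where t* is the
#' class with the highest out-of-fold probability among classes whose
#' probability reaches their threshold. Cells confident for no class are
#' left uncounted, so the total is at most n.
#'
#' @param oof_probs n x 2 out-of-fold probability matrix.
#' @param labels given labels.
#' @param thresholds per-class thresholds from [class_thresholds()].
#' @return 2 x 2 integer matrix, rows = given label, cols = inferred true
#'   label.
#' @export
confident_joint <- function(oof_probs, labels, thresholds) {
  classes <- c("Tconv", "Treg")
  joint <- matrix(0L, 2, 2, dimnames = list(given = classes,
                                            inferred = classes))
  confident <- sweep(oof_probs[, classes, drop = FALSE], 2,
                     thresholds[classes], ">=")
  for (i in seq_along(labels)) {
    cand <- which(confident[i, ])
    if (!length(cand)) next
    t_star <- cand[which.max(oof_probs[i, classes[cand]])]
    s <- match(labels[i], classes)
    joint[s, t_star] <- joint[s, t_star] + 1L
  }
  joint
}

#' Prune likely-mislabeled cells
#'
#' Default `by_noise_rate`: for every off-diagonal confident-joint entry
#' (s, t) with count k, the k cells carrying label s with the largest
#' probability margin p(t) - p(s) are removed. `by_class`: for each class
#' s the off-diagonal row mass of s is removed, lowest self-confidence
#' first. Removed cells are flagged `qc_flag = "pruned"`.
#'
#' @param oof_probs n x 2 out-of-fold probability matrix.
#' @param labels given labels.
#' @param joint confident joint from [confident_joint()]; recomputed when
#'   NULL.
#' @param method `"by_noise_rate"` or `"by_class"`.
#' @return a `pruning_report` list: `oof_probs`, `class_thresholds`,
#'   `confident_joint`, `estimated_noise_rates` (rows = given label, rows
#'   sum to 1), `removed_ids`, `removed_fraction`,
#'   `removed_fraction_by_class`, `keep` (logical vector).
#' @export
prune_mislabeled <- function(oof_probs, labels, joint = NULL,
                             method = c("by_noise_rate", "by_class")) {
  method <- match.arg(method)
  classes <- c("Tconv", "Treg")
  thresholds <- class_thresholds(oof_probs, labels)
  if (is.null(joint)) joint <- confident_joint(oof_probs, labels, thresholds)
  n <- length(labels)
  remove <- rep(FALSE, n)
  if (method == "by_noise_rate") {
    for (s in 1:2) for (t in 1:2) {
      if (s == t) next
      k <- joint[s, t]
      if (k == 0) next
      members <- which(labels == classes[s])
      margin <- oof_probs[members, classes[t]] -
        oof_probs[members, classes[s]]
      remove[members[order(margin, decreasing = TRUE)[seq_len(k)]]] <- TRUE
    }
  } else {
    for (s in 1:2) {
      k <- sum(joint[s, -s])
      if (k == 0) next
      members <- which(labels == classes[s])
      self_conf <- oof_probs[members, classes[s]]
      remove[members[order(self_conf)[seq_len(k)]]] <- TRUE
    }
  }
  row_tot <- rowSums(joint)
  noise_rates <- joint / ifelse(row_tot == 0, 1, row_tot)
  ids <- rownames(oof_probs)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  class_n <- table(factor(labels, levels = classes))
  removed_by_class <- vapply(classes, function(cl) {
    sum(remove & labels == cl) / max(1, class_n[[cl]])
  }, numeric(1))
  structure(
    list(
      oof_probs = oof_probs,
      class_thresholds = thresholds,
      confident_joint = joint,
      estimated_noise_rates = noise_rates,
      method = method,
      removed_ids = ids[remove],
      removed_fraction = mean(remove),
      removed_fraction_by_class = removed_by_class,
      keep = !remove
    ),
    class = "pruning_report"
  )
}

#' @export
print.pruning_report <- function(x, ...) {
  cat(sprintf("pruning_report (%s): removed %d / %d cells (%.1f%%)\n",
              x$method, length(x$removed_ids), length(x$keep),
              100 * x$removed_fraction))
  cat("  by class:",
      paste(names(x$removed_fraction_by_class),
            sprintf("%.1f%%", 100 * x$removed_fraction_by_class),
            sep = " ", collapse = ", "), "\n")
  invisible(x)
}

#' Run the full confident-learning pruning stage
#'
#' Out-of-fold probabilities, class thresholds, confident joint and
#' pruning in one call, restricted to Tconv/Treg-sorted cells: Fraction
#' III cells are never pruned (they are an unlabeled validation pool) and
#' their presence in `set` is an error here.
#'
#' @param set a [spectrum_set()] of sorted Tconv/Treg cells.
#' @param labels given labels; default the set's `sorted_label`.
#' @param folds,lambda,seed,weights as in [out_of_fold_probs()].
#' @param method as in [prune_mislabeled()].
#' @return a `pruning_report` (see [prune_mislabeled()]), plus element
#'   `lambda` (the penalty used for the fold models).
#' @export
run_confident_learning <- function(set, labels = NULL, folds = 5,
                                   lambda = "auto", seed = 1L,
                                   method = "by_noise_rate",
                                   weights = NULL) {
  if (is.null(labels)) labels <- set$meta$sorted_label
  if (any(labels == "FrIII")) {
    stop("FrIII cells must be excluded before pruning")
  }
  oof <- out_of_fold_probs(set, labels, folds = folds, lambda = lambda,
                           seed = seed, weights = weights)
  report <- prune_mislabeled(oof, labels, method = method)
  report$lambda <- attr(oof, "lambda")
  report
}
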