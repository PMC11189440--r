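#' Study configuration
#'
#' Defaults restate the evaluation conventions used throughout: 20% held
#' out for testing, probability call threshold 0.5, and mixture cutoffs at
#' p < 0.10 / p > 0.90.
#'
#' @param test_fraction held-out fraction in (0, 1).
#' @param threshold probability call threshold.
#' @param mixture_low,mixture_high mixture-scoring tail cutoffs,
#'   0 < low < high < 1.
#' @param holdout_donor donor id for [run_donor_holdout()], or NULL.
#' @param folds folds for penalty selection and confident learning.
#' @param prune_method confident-learning method, see
#'   [prune_mislabeled()].
#' @param weights classifier weighting, see [fit_lasso_logistic()].
#' @param seed master seed; every stage forks its own stream from it.
#' @return a list of class `study_config`.
#' @export
study_config <- function(test_fraction = 0.2, threshold = 0.5,
                         mixture_low = 0.10, mixture_high = 0.90,
                         holdout_donor = NULL, folds = 5,
                         prune_method = "by_noise_rate",
                         weights = NULL, seed = 1L) {
  stopifnot(test_fraction > 0, test_fraction < 1,
            mixture_low > 0, mixture_low < mixture_high,
            mixture_high < 1)
  structure(
    list(test_fraction = test_fraction, threshold = threshold,
         mixture_low = mixture_low, mixture_high = mixture_high,
         holdout_donor = holdout_donor, folds = folds,
         prune_method = prune_method, weights = weights,
         seed = as.integer(seed)),
    class = "study_config"
  )
}

# labeled (sorted Tconv/Treg, QC-passing) subset of a cohort
.labeled_subset <- function(set) {
  keep <- set$meta$sorted_label %in% c("Tconv", "Treg") &
    set$meta$qc_flag == "pass"
  if (!any(keep)) stop("no sorted Tconv/Treg cells present")
  subset_cells(set, which(keep))
}

.audit_disjoint <- function(train_ids, test_ids) {
  overlap <- intersect(train_ids, test_ids)
  if (length(overlap)) {
    stop("leakage: cell(s) in both train and test: ", overlap[1])
  }
  invisible(TRUE)
}

.evaluate_split <- function(model, set, labels, threshold) {
  scores <- predict_proba(model, set)
  roc <- roc_and_auc(scores, labels)
  conf <- confusion_at_threshold(scores, labels, threshold)
  list(n = length(scores), auc = roc$auc, roc_points = roc$roc_points,
       accuracy = conf$accuracy, confusion = conf$confusion,
       threshold = threshold)
}

# lambda selection + final fit on a training set, with manifest
.train_on <- function(set, labels, folds, seed, weights) {
  seeds <- fork_seeds(seed, 2)
  lambda <- as.numeric(select_lambda_cv(set$intensities, labels,
                                        folds = folds, seed = seeds[1],
                                        weights = weights))
  fit_lasso_logistic(
    set$intensities, labels, lambda, weights = weights, axis = set$axis,
    manifest = list(train_ids = set$meta$cell_id, seed = seed,
                    lambda = lambda, folds = folds)
  )
}

.true_labels_known <- function(set) all(set$meta$true_label != "unknown")

#' Random-split classification study
#'
#' Stratified 80/20 split of the sorted Tconv/Treg pool, penalty selection
#' by cross-validation on the training portion, one final fit, and
#' ROC/AUC/accuracy on both portions. When planted true labels are
#' available, test metrics against them are reported alongside the
#' sorted-label metrics.
#'
#' @param set a [spectrum_set()].
#' @param config a [study_config()].
#' @return a `study_report` list with elements `study_kind`, `model`,
#'   `train_eval`, `test_eval`, optional `test_eval_true`, `manifest`,
#'   `config`.
#' @export
run_random_split_study <- function(set, config = study_config()) {
  labeled <- .labeled_subset(set)
  seeds <- fork_seeds(config$seed, 2)
  split <- stratified_split(labeled, config$test_fraction, seeds[1])
  train <- subset_cells(labeled, split$train_ids)
  test <- subset_cells(labeled, split$test_ids)
  .audit_disjoint(split$train_ids, split$test_ids)
  model <- .train_on(train, train$meta$sorted_label, config$folds,
                     seeds[2], config$weights)
  report <- list(
    study_kind = "random_split",
    model = model,
    train_eval = .evaluate_split(model, train, train$meta$sorted_label,
                                 config$threshold),
    test_eval = .evaluate_split(model, test, test$meta$sorted_label,
                                config$threshold),
    manifest = list(train_ids = split$train_ids,
                    test_ids = split$test_ids, seed = config$seed),
    config = config
  )
  if (.true_labels_known(test)) {
    report$test_eval_true <- .evaluate_split(model, test,
                                             test$meta$true_label,
                                             config$threshold)
  }
  structure(report, class = "study_report")
}

#' Pruned-data classification study
#'
#' Confident-learning pruning on the full sorted pool, then a random-split
#' study on the pruned cells only; an unpruned study with the same split
#' seed is reported alongside for comparison. Fraction III cells are never
#' pruned or trained on.
#'
#' @param set a [spectrum_set()].
#' @param config a [study_config()].
#' @return a `study_report` with elements `pruning` (a `pruning_report`),
#'   `pruned` and `unpruned` (both `study_report`s), `manifest`, `config`.
#' @export
run_pruned_study <- function(set, config = study_config()) {
  labeled <- .labeled_subset(set)
  n_frIII <- sum(set$meta$sorted_label == "FrIII")
  seeds <- fork_seeds(config$seed, 2)
  pruning <- run_confident_learning(
    labeled, folds = config$folds, seed = seeds[1],
    method = config$prune_method, weights = config$weights
  )
  kept <- subset_cells(labeled, which(pruning$keep))
  sub_config <- config
  sub_config$seed <- seeds[2]
  structure(
    list(
      study_kind = "pruned",
      pruning = pruning,
      pruned = run_random_split_study(kept, sub_config),
      unpruned = run_random_split_study(labeled, sub_config),
      manifest = list(
        n_labeled = nrow(labeled$intensities),
        n_pruned_away = length(pruning$removed_ids),
        n_frIII_excluded = n_frIII,
        seed = config$seed
      ),
      config = config
    ),
    class = "study_report"
  )
}

#' Score a Fraction III mixture pool
#'
#' Applies a trained model (which must never have seen a Fraction III
#' cell) to all FrIII-sorted cells and reports, per donor, the fraction of
#' cells with p below the low cutoff and above the high cutoff, plus the
#' derived point estimate of the Treg fraction
#' `high / (high + low)` among confidently-called cells. Planted true
#' fractions are reported alongside when available.
#'
#' @param model a [fit_lasso_logistic()] model.
#' @param set a [spectrum_set()] containing FrIII-sorted cells.
#' @param config a [study_config()]; cutoffs default to 0.10 / 0.90.
#' @return a `study_report` with `per_donor` data.frame: `donor_id`, `n`,
#'   `frac_low`, `frac_high`, `treg_fraction_estimate`,
#'   `planted_treg_fraction` (NA when unknown).
#' @export
score_mixture_fraction <- function(model, set, config = study_config()) {
  frIII_idx <- which(set$meta$sorted_label == "FrIII")
  if (!length(frIII_idx)) stop("no FrIII cells present")
  frIII <- subset_cells(set, frIII_idx)
  train_ids <- model$manifest$train_ids
  if (!is.null(train_ids) && length(intersect(train_ids,
                                              frIII$meta$cell_id))) {
    stop("leakage: model was trained on FrIII cell(s)")
  }
  p <- predict_proba(model, frIII)
  donors <- sort(unique(frIII$meta$donor_id))
  rows <- lapply(donors, function(d) {
    sel <- frIII$meta$donor_id == d
    pd <- p[sel]
    lo <- mean(pd < config$mixture_low)
    hi <- mean(pd > config$mixture_high)
    est <- if (lo + hi > 0) hi / (hi + lo) else NA_real_
    planted <- if (all(frIII$meta$true_label[sel] != "unknown")) {
      mean(frIII$meta$true_label[sel] == "Treg")
    } else NA_real_
    data.frame(donor_id = d, n = sum(sel), frac_low = lo, frac_high = hi,
               treg_fraction_estimate = est,
               planted_treg_fraction = planted)
  })
  structure(
    list(study_kind = "mixture_scoring",
         cutoffs = c(low = config$mixture_low, high = config$mixture_high),
         per_donor = do.call(rbind, rows),
         manifest = list(n_scored = length(p)),
         config = config),
    class = "study_report"
  )
}

#' Donor-holdout study
#'
#' Confident-learning pruning and model training on all donors except the
#' holdout; every sorted cell of the holdout donor (unpruned — a deployed
#' model cannot prune unseen data) is scored as test data.
#'
#' @param set a [spectrum_set()] with >= 3 donors.
#' @param config a [study_config()] with `holdout_donor` set.
#' @return a `study_report` with `pruning`, `model`, `train_eval`,
#'   `test_eval`, optional `test_eval_true`, `manifest`, `config`.
#' @export
run_donor_holdout <- function(set, config) {
  if (is.null(config$holdout_donor)) stop("holdout_donor must be set")
  labeled <- .labeled_subset(set)
  donors <- unique(labeled$meta$donor_id)
  if (!config$holdout_donor %in% donors) {
    stop("unknown donor_id: ", config$holdout_donor)
  }
  if (length(donors) - 1 < 2) {
    stop("need >= 2 training donors besides the holdout")
  }
  is_hold <- labeled$meta$donor_id == config$holdout_donor
  train_pool <- subset_cells(labeled, which(!is_hold))
  test <- subset_cells(labeled, which(is_hold))
  seeds <- fork_seeds(config$seed, 2)
  pruning <- run_confident_learning(
    train_pool, folds = config$folds, seed = seeds[1],
    method = config$prune_method, weights = config$weights
  )
  train <- subset_cells(train_pool, which(pruning$keep))
  model <- .train_on(train, train$meta$sorted_label, config$folds,
                     seeds[2], config$weights)
  .audit_disjoint(model$manifest$train_ids, test$meta$cell_id)
  report <- list(
    study_kind = "donor_holdout",
    holdout_donor = config$holdout_donor,
    pruning = pruning,
    model = model,
    train_eval = .evaluate_split(model, train, train$meta$sorted_label,
                                 config$threshold),
    test_eval = .evaluate_split(model, test, test$meta$sorted_label,
                                config$threshold),
    manifest = list(train_ids = model$manifest$train_ids,
                    test_ids = test$meta$cell_id, seed = config$seed),
    config = config
  )
  if (.true_labels_known(test)) {
    report$test_eval_true <- .evaluate_split(model, test,
                                             test$meta$true_label,
                                             config$threshold)
  }
  structure(report, class = "study_report")
}

#' Naive-only versus full-population training comparison
#'
#' Holds out one common stratified test pool containing both naive and
#' effector cells, then trains two models on the remaining cells: one on
#' naive cells only, one on the full training pool. Both are evaluated on
#' the common test pool with confusion matrices at the configured
#' threshold.
#'
#' @param set a [spectrum_set()] with `subpop` tags `naive`/`effector`.
#' @param config a [study_config()].
#' @return a `study_report` with `naive_model`, `full_model`, their
#'   `naive_eval`/`full_eval` on the shared test pool, `manifest`,
#'   `config`.
#' @export
run_subpopulation_comparison <- function(set, config = study_config()) {
  labeled <- .labeled_subset(set)
  subpops <- unique(labeled$meta$subpop)
  if (!all(c("naive", "effector") %in% subpops)) {
    stop("subpop tags naive/effector required")
  }
  seeds <- fork_seeds(config$seed, 3)
  strata <- paste(labeled$meta$sorted_label, labeled$meta$subpop)
  split <- stratified_split(labeled, config$test_fraction, seeds[1],
                            labels = strata)
  train_pool <- subset_cells(labeled, split$train_ids)
  test <- subset_cells(labeled, split$test_ids)
  .audit_disjoint(split$train_ids, split$test_ids)
  naive_pool <- subset_cells(train_pool,
                             which(train_pool$meta$subpop == "naive"))
  naive_model <- .train_on(naive_pool, naive_pool$meta$sorted_label,
                           config$folds, seeds[2], config$weights)
  full_model <- .train_on(train_pool, train_pool$meta$sorted_label,
                          config$folds, seeds[3], config$weights)
  .audit_disjoint(naive_model$manifest$train_ids, test$meta$cell_id)
  .audit_disjoint(full_model$manifest$train_ids, test$meta$cell_id)
  structure(
    list(
      study_kind = "subpopulation",
      naive_model = naive_model, full_model = full_model,
      naive_eval = .evaluate_split(naive_model, test,
                                   test$meta$sorted_label,
                                   config$threshold),
      full_eval = .evaluate_split(full_model, test,
                                  test$meta$sorted_label,
                                  config$threshold),
      manifest = list(train_ids_full = full_model$manifest$train_ids,
                      train_ids_naive = naive_model$manifest$train_ids,
                      test_ids = split$test_ids, seed = config$seed),
      config = config
    ),
    class = "study_report"
  )
}

#' @export
print.study_report <- function(x, ...) {
  cat("study_report:", x$study_kind, "\n")
  show_eval <- function(name, ev) {
    if (!is.null(ev)) {
      cat(sprintf("  %s: n = %d, AUC = %.4f, accuracy = %.4f\n",
                  name, ev$n, ev$auc, ev$accuracy))
    }
  }
  show_eval("train", x$train_eval)
  show_eval("test", x$test_eval)
  show_eval("test (true labels)", x$test_eval_true)
  if (!is.null(x$per_donor)) print(x$per_donor)
  if (!is.null(x$pruning)) print(x$pruning)
  if (!is.null(x$pruned)) {
    cat("-- pruned --\n"); print(x$pruned)
    cat("-- unpruned --\n"); print(x$unpruned)
  }
  if (!is.null(x$naive_eval)) {
    show_eval("naive-trained test", x$naive_eval)
    show_eval("full-trained test", x$full_eval)
  }
  invisible(x)
}
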