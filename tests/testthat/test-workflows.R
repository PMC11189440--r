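# workflow tests run on small cohorts; the full-scale behavior checks
# live in test-acceptance.R

test_that("random-split study: contract, no leakage, reproducibility", {
  sim <- quick_cohort(cells_per_donor = 300, n_donors = 1, seed = 6,
                      purity_tconv = 1, purity_treg = 1,
                      template = easy_template())
  cfg <- study_config(seed = 42)
  rep <- run_random_split_study(sim$set, cfg)
  expect_equal(rep$config$test_fraction, 0.2)
  expect_length(intersect(rep$manifest$train_ids, rep$manifest$test_ids), 0)
  expect_gt(rep$test_eval$auc, 0.9)  # easy regime: strong effects, clean labels
  expect_equal(sum(rep$test_eval$confusion), rep$test_eval$n)
  # regeneration from the config echo is numerically identical
  rep2 <- run_random_split_study(sim$set, rep$config)
  expect_identical(rep$test_eval$auc, rep2$test_eval$auc)
  expect_identical(rep$model$coefficients, rep2$model$coefficients)
})

test_that("pruned study excludes FrIII and reports both models", {
  sim <- quick_cohort(cells_per_donor = 250, n_donors = 1, seed = 14,
                      frIII_cells_per_donor = 40)
  rep <- run_pruned_study(sim$set, study_config(seed = 2))
  expect_equal(rep$manifest$n_frIII_excluded, 40)
  fr_ids <- sim$set$meta$cell_id[sim$set$meta$sorted_label == "FrIII"]
  expect_length(intersect(rep$pruned$manifest$train_ids, fr_ids), 0)
  expect_length(intersect(rep$pruning$removed_ids, fr_ids), 0)
  expect_s3_class(rep$pruning, "pruning_report")
  expect_true(!is.null(rep$pruned$test_eval$auc))
  expect_true(!is.null(rep$unpruned$test_eval$auc))
})

test_that("mixture scoring: tails, leakage guard, degenerate model", {
  sim <- quick_cohort(cells_per_donor = 250, n_donors = 2, seed = 18,
                      frIII_cells_per_donor = 100,
                      frIII_fraction_treg = c(0.7, 0.3))
  cfg <- study_config(seed = 5)
  study <- run_random_split_study(sim$set, cfg)
  mix <- score_mixture_fraction(study$model, sim$set, cfg)
  expect_equal(unname(mix$cutoffs), c(0.10, 0.90))
  expect_equal(mix$per_donor$planted_treg_fraction, c(0.7, 0.3))
  expect_equal(mix$per_donor$n, c(100, 100))

  # a model trained on FrIII cells is refused
  bad_model <- study$model
  bad_model$manifest$train_ids <- sim$set$meta$cell_id[
    sim$set$meta$sorted_label == "FrIII"][1]
  expect_error(score_mixture_fraction(bad_model, sim$set, cfg), "leakage")

  # all-zero model: every probability 0.5, both tails empty
  null_model <- study$model
  null_model$coefficients[] <- 0
  null_model$intercept <- 0
  null_model$manifest$train_ids <- character(0)
  mix0 <- score_mixture_fraction(null_model, sim$set, cfg)
  expect_equal(mix0$per_donor$frac_low, c(0, 0))
  expect_equal(mix0$per_donor$frac_high, c(0, 0))
  expect_true(all(is.na(mix0$per_donor$treg_fraction_estimate)))
})

test_that("donor holdout: preconditions and no-leakage audit", {
  sim <- quick_cohort(cells_per_donor = 220, n_donors = 3, seed = 23)
  cfg <- study_config(holdout_donor = "d3", seed = 7)
  rep <- run_donor_holdout(sim$set, cfg)
  held <- sim$set$meta$cell_id[sim$set$meta$donor_id == "d3"]
  expect_length(intersect(rep$manifest$train_ids, held), 0)
  expect_setequal(rep$manifest$test_ids, held)
  # holdout cells are never pruned
  expect_length(intersect(rep$pruning$removed_ids, held), 0)

  expect_error(run_donor_holdout(sim$set,
                                 study_config(holdout_donor = "d9")),
               "unknown donor")
  sim2 <- quick_cohort(cells_per_donor = 220, n_donors = 2, seed = 23)
  expect_error(run_donor_holdout(sim2$set,
                                 study_config(holdout_donor = "d2")),
               ">= 2 training donors")
  expect_error(run_donor_holdout(sim$set, study_config()),
               "holdout_donor")
})

test_that("subpopulation comparison trains two models on one test pool", {
  sim <- quick_cohort(cells_per_donor = 300, n_donors = 1, seed = 29)
  cfg <- study_config(seed = 11)
  rep <- run_subpopulation_comparison(sim$set, cfg)
  expect_true(all(c("naive", "effector") %in%
                    sim$set$meta$subpop))
  # the naive model saw only naive cells
  naive_ids <- sim$set$meta$cell_id[sim$set$meta$subpop == "naive"]
  expect_true(all(rep$manifest$train_ids_naive %in% naive_ids))
  # both evaluated on the same disjoint pool
  expect_length(intersect(rep$manifest$train_ids_full,
                          rep$manifest$test_ids), 0)
  expect_length(intersect(rep$manifest$train_ids_naive,
                          rep$manifest$test_ids), 0)
  expect_equal(dim(rep$naive_eval$confusion), c(2, 2))
  # deterministic under a fixed seed
  rep2 <- run_subpopulation_comparison(sim$set, cfg)
  expect_identical(rep$full_eval$accuracy, rep2$full_eval$accuracy)

  no_tags <- sim$set
  no_tags$meta$subpop <- "mixed"
  expect_error(run_subpopulation_comparison(no_tags, cfg), "subpop tags")
})

test_that("models round-trip through the JSON schema", {
  sim <- quick_cohort(cells_per_donor = 80, n_donors = 1, seed = 3)
  m <- fit_lasso_logistic(sim$set$intensities, sim$set$meta$sorted_label,
                          0.05, axis = sim$set$axis,
                          manifest = list(train_ids = sim$set$meta$cell_id,
                                          seed = 3))
  path <- withr::local_tempfile(fileext = ".json")
  write_model_json(m, path)
  back <- read_model_json(path)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$axis, m$axis)
  expect_equal(predict_proba(back, sim$set), predict_proba(m, sim$set))
  expect_error(read_model_json(
    write_report_json(list(a = 1), withr::local_tempfile())),
    "not a ramanTreg model")
})

test_that("the CLI drives simulate/preprocess/train/prune end to end", {
  dir <- withr::local_tempdir()
  raw <- file.path(dir, "raw.csv")
  pre <- file.path(dir, "pre.csv")
  cli_main(c("simulate", "--out", raw, "--seed", "2", "--donors", "2",
             "--cells-per-donor", "60"))
  expect_true(file.exists(raw))
  cli_main(c("preprocess", "--in", raw, "--out", pre,
             "--qc-report", file.path(dir, "qc.json")))
  set <- read_spectra_table(pre)
  expect_length(set$axis, 643)
  qc <- jsonlite::read_json(file.path(dir, "qc.json"))
  expect_equal(qc$silent$n_channels, 643)
  suppressMessages(
    cli_main(c("train", "--in", pre, "--seed", "1",
               "--model-out", file.path(dir, "model.json"),
               "--report-out", file.path(dir, "train.json"))))
  m <- read_model_json(file.path(dir, "model.json"))
  expect_length(m$coefficients, 643)
  suppressMessages(
    cli_main(c("prune", "--in", pre, "--seed", "1",
               "--report-out", file.path(dir, "prune.json"),
               "--out", file.path(dir, "pruned.csv"))))
  pruned <- read_spectra_table(file.path(dir, "pruned.csv"))
  expect_lt(nrow(pruned$intensities), nrow(set$intensities))
  expect_error(cli_main(c("frobnicate")), "unknown subcommand")
})
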