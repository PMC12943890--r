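with_synth <- function(trials, n = 12L) {
  synth <- lapply(seq_len(n), function(i) {
    tr <- trials[[((i - 1L) %% length(trials)) + 1L]]
    tr$synthetic <- TRUE
    tr$subject_id <- "synthetic"
    tr
  })
  c(trials, synth)
}

test_that("stratified splits preserve class balance and exclude synthetic", {
  trials <- preprocess_trials(make_cohort(cohort_config(duration = 0.8,
                                                        sample_period = 0.05,
                                                        seed = 71L)))$trials
  expect_length(trials, 180L)
  ds <- with_synth(trials, 24L)
  sp <- make_split(ds, split_plan("stratified_sample", test_fraction = 0.25,
                                  seed = 3))
  expect_length(sp$test, 45L)
  cls <- vapply(ds[sp$test], `[[`, character(1), "movement")
  expect_true(all(table(cls) %in% c(7L, 8L)))  # 45/6 = 7.5, off-by-one balance
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_false(any(vapply(ds[sp$test], function(x) isTRUE(x$synthetic), logical(1))))
  expect_setequal(c(sp$train, sp$test), seq_along(ds))
})

test_that("LOSO yields one fold per subject with all its trials in test", {
  trials <- preprocess_trials(make_cohort(cohort_config(duration = 0.8,
                                                        sample_period = 0.05,
                                                        seed = 72L)))$trials
  folds <- make_split(with_synth(trials), split_plan("loso"))
  expect_length(folds, 10L)
  for (f in folds) {
    expect_length(f$test, 18L)
    subj <- unique(vapply(trials[f$test], `[[`, character(1), "subject_id"))
    expect_length(subj, 1L)
    expect_length(intersect(f$train, f$test), 0L)
  }
})

test_that("kfold stratifies and errors when folds exceed samples", {
  trials <- processed_small()
  folds <- make_split(trials, split_plan("kfold", folds = 4L, seed = 5))
  expect_length(folds, 4L)
  all_test <- sort(unlist(lapply(folds, `[[`, "test")))
  expect_equal(all_test, seq_along(trials))
  expect_error(make_split(trials[1:3], split_plan("kfold", folds = 5L)),
               class = "too_few_samples")
})

test_that("run_ablation produces the four-arm report with trial-level SDs", {
  trials <- preprocess_trials(make_cohort(clean_cohort_config(n_subjects = 3L,
                                                              seed = 73L)))$trials
  cfg <- classifier_config("gbt", gbt_rounds = 40L, seed = 2L)
  rep1 <- run_ablation(trials, cfg, gen_kind = "cvae",
                       gen_cfg = cvae_config(epochs = 30L),
                       translator_cfg = cvae_config(epochs = 30L),
                       n_trials = 1L, n_synth_per_class = 3L, seed = 4L)
  expect_s3_class(rep1, "eval_report")
  expect_identical(rep1$accuracy$arm,
                   c("base", "data_augment", "feature_augment", "mt_aim"))
  expect_equal(rep1$accuracy$sd, rep(0, 4))  # single trial -> SD 0
  expect_true(all(rep1$accuracy$mean >= 0 & rep1$accuracy$mean <= 1))

  bare <- lapply(trials, function(tr) { tr$kinematics <- NULL; tr })
  expect_error(run_ablation(bare, cfg, arms = c("base", "feature_augment")),
               class = "missing_kinematics")
})

test_that("subject-identifiability control sits near chance without signatures", {
  trials <- preprocess_trials(make_cohort(small_cohort_config(n_subjects = 4L,
                                                              seed = 74L)))$trials
  feats <- featurize_trials(trials, dtft = FALSE)
  ctl <- subject_identifiability_control(
    feats, classifier_config("gbt", gbt_rounds = 40L), folds = 3L, seed = 6L)
  expect_equal(ctl$chance, 0.25)
  expect_length(ctl$per_fold, 3L)
  expect_lt(abs(ctl$mean - ctl$chance), 0.35)
  expect_error(subject_identifiability_control(feats[1:18]),
               class = "single_subject")
})

test_that("pca projection returns ordered variance and labeled coordinates", {
  feats <- featurize_trials(processed_small()[1:30], dtft = FALSE)
  pj <- pca_projection(feats, 2L)
  expect_identical(ncol(pj$coordinates), 4L)  # PC1, PC2, subject, movement
  expect_length(pj$explained_variance_ratio, 2L)
  expect_true(all(diff(pj$explained_variance_ratio) <= 0))
  expect_true(all(pj$explained_variance_ratio <= 1))
  # duplicated dataset projects identically up to sign
  pj2 <- pca_projection(c(feats, feats), 2L)
  a <- abs(pj$coordinates$PC1[1:5])
  b <- abs(pj2$coordinates$PC1[1:5])
  expect_equal(a, b, tolerance = 1e-6)
})
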