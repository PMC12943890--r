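test_that("cohort CSV + manifest roundtrip preserves trials", {
  co <- make_cohort(small_cohort_config(n_subjects = 1L, seed = 81L))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_cohort(dir)
  expect_length(back, length(co))
  expect_equal(back[[4]]$mt$resistance, co[[4]]$mt$resistance, tolerance = 1e-9)
  expect_equal(back[[4]]$mt$baseline, co[[4]]$mt$baseline, tolerance = 1e-9)
  expect_equal(back[[4]]$kin$angles, co[[4]]$kin$angles,
               tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(back[[4]]$mt$movement, co[[4]]$mt$movement)
})

test_that("generator checkpoints roundtrip through JSON", {
  trials <- preprocess_trials(make_cohort(clean_cohort_config(n_subjects = 1L,
                                                              seed = 82L)))$trials
  gen <- train_class_conditional("cvae", trials, cvae_config(epochs = 15L, seed = 2L))
  path <- withr::local_tempfile(fileext = ".json")
  save_generator(gen, path)
  back <- load_generator(path)
  s1 <- sample_synthetic_mt(gen, "flexion", 2, seed = 3)
  s2 <- sample_synthetic_mt(back, "flexion", 2, seed = 3)
  expect_equal(s1[[1]]$strain, s2[[1]]$strain, tolerance = 1e-12)
})

test_that("pipeline config reader validates keys and merges defaults", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("cohort:", "  n_subjects: 2", "experiment:", "  n_trials: 1"), path)
  cfg <- read_pipeline_config(path, seed = 9)
  expect_identical(cfg$cohort$n_subjects, 2L)
  expect_identical(cfg$experiment$n_trials, 1L)
  expect_identical(cfg$preprocess$hampel_window, 11L)  # default survives
  writeLines(c("cohrt:", "  n_subjects: 2"), path)
  expect_error(read_pipeline_config(path), class = "unknown_config_key")
  writeLines(c("cohort:", "  n_subjcts: 2"), path)
  expect_error(read_pipeline_config(path), class = "unknown_config_key")
})

tiny_pipeline_config <- function(seed = 11L) {
  cfg <- default_pipeline_config(seed)
  cfg$cohort$n_subjects <- 2L
  cfg$cohort$duration <- 1.6
  cfg$cohort$sample_period <- 0.05
  cfg$generator$epochs <- 10L
  cfg$generator$n_synth_per_class <- 2L
  cfg$translator$epochs <- 10L
  cfg$classifier <- list(kind = "gbt", gbt_rounds = 20L)
  cfg$experiment$n_trials <- 1L
  cfg$experiment$arms <- c("base", "mt_aim")
  cfg
}

test_that("run_pipeline completes end to end and reruns identically", {
  out1 <- withr::local_tempdir()
  res <- run_pipeline(tiny_pipeline_config(), out_dir = out1)
  expect_s3_class(res$report, "eval_report")
  expect_true(file.exists(file.path(out1, "report.json")))
  expect_true(file.exists(file.path(out1, "accuracy.csv")))
  expect_identical(nrow(res$report$accuracy), 2L)

  res2 <- run_pipeline(tiny_pipeline_config())
  expect_equal(res$report$accuracy, res2$report$accuracy)
  expect_equal(res$report$per_trial, res2$report$per_trial)
})

test_that("ingest mode reproduces simulate mode downstream", {
  cfg <- tiny_pipeline_config()
  cc <- do.call(cohort_config,
                c(cfg$cohort, list(seed = mtaim:::derive_seed(cfg$seed, 1L))))
  dir <- withr::local_tempdir()
  write_cohort(make_cohort(cc), dir)
  res_sim <- run_pipeline(cfg)
  res_ing <- run_pipeline(cfg, cohort_dir = dir)
  expect_equal(res_sim$report$accuracy, res_ing$report$accuracy, tolerance = 1e-8)
})

test_that("feature tensors roundtrip through the CSV container", {
  feats <- featurize_trials(processed_small()[1:5], dtft = TRUE,
                            kinematics = "paired")
  dir <- withr::local_tempdir()
  write_feature_tensors(feats, dir)
  back <- read_feature_tensors(dir)
  expect_length(back, 5L)
  expect_identical(back[[2]]$channel_roles, feats[[2]]$channel_roles)
  expect_equal(back[[2]]$values, feats[[2]]$values, tolerance = 1e-9)
  expect_identical(back[[2]]$movement, feats[[2]]$movement)
})

test_that("the CLI runs simulate and preprocess as documented", {
  dir <- withr::local_tempdir()
  cohort_dir <- file.path(dir, "cohort")
  cfg_yaml <- file.path(dir, "cohort.yaml")
  writeLines(c("n_subjects: 1", "duration: 1.6", "sample_period: 0.05"), cfg_yaml)
  suppressMessages(
    mtaim_cli(c("simulate", "--config", cfg_yaml, "--out", cohort_dir,
                "--seed", "3")))
  expect_true(file.exists(file.path(cohort_dir, "manifest.json")))
  proc_dir <- file.path(dir, "processed")
  suppressMessages(
    mtaim_cli(c("preprocess", "--in", cohort_dir, "--out", proc_dir)))
  expect_true(file.exists(file.path(proc_dir, "drop_report.json")))
  trials <- mtaim:::read_processed_trials(proc_dir)
  expect_length(trials, 18L)
  expect_true(all(abs(trials[[1]]$strain) <= 1))
})
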