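# Generator contract tests use deliberately tiny training budgets: they
# check optimization sanity, determinism and shape/label contracts, not
# generative quality (that lives in test-acceptance.R).

tiny_cvae <- function(epochs = 40L, seed = 5L)
  cvae_config(epochs = epochs, seed = seed)

tiny_diff <- function(epochs = 15L, seed = 5L)
  diffusion_config(sampling_steps = 25L, epochs = epochs, seed = seed)

test_that("C-VAE training loss decreases and sampling honors contracts", {
  trials <- preprocess_trials(make_cohort(clean_cohort_config(n_subjects = 2L)))$trials
  gen <- train_class_conditional("cvae", trials, tiny_cvae())
  expect_s3_class(gen, "mt_generator")
  expect_lt(mean(tail(gen$loss_log, 5)), mean(head(gen$loss_log, 5)))

  syn <- sample_synthetic_mt(gen, "flexion", 4, seed = 9)
  expect_length(syn, 4L)
  expect_identical(dim(syn[[1]]$strain), c(6L, gen$T))
  expect_true(all(vapply(syn, `[[`, character(1), "movement") == "flexion"))
  expect_true(all(vapply(syn, `[[`, logical(1), "synthetic")))
  expect_true(all(abs(do.call(rbind, lapply(syn, `[[`, "strain"))) <= 1))
  expect_length(sample_synthetic_mt(gen, "flexion", 0), 0L)
  expect_error(sample_synthetic_mt(gen, "moonwalk", 2), class = "unknown_movement")
})

test_that("training and sampling are seed-deterministic end to end", {
  trials <- preprocess_trials(make_cohort(clean_cohort_config(n_subjects = 1L)))$trials
  g1 <- train_class_conditional("cvae", trials, tiny_cvae(epochs = 20L))
  g2 <- train_class_conditional("cvae", trials, tiny_cvae(epochs = 20L))
  s1 <- sample_synthetic_mt(g1, "extension", 3, seed = 2)
  s2 <- sample_synthetic_mt(g2, "extension", 3, seed = 2)
  expect_identical(lapply(s1, `[[`, "strain"), lapply(s2, `[[`, "strain"))
  s3 <- sample_synthetic_mt(g1, "extension", 3, seed = 3)
  expect_false(identical(s1[[1]]$strain, s3[[1]]$strain))
})

test_that("single-class datasets and TimeGAN are rejected", {
  trials <- preprocess_trials(make_cohort(clean_cohort_config(n_subjects = 1L)))$trials
  flex <- Filter(function(tr) tr$movement == "flexion", trials)
  expect_error(train_class_conditional("cvae", flex, tiny_cvae()),
               class = "single_class")
  expect_error(train_class_conditional("timegan", trials),
               class = "timegan_stub")
})

test_that("diffusion generator trains, samples in range and is deterministic", {
  trials <- preprocess_trials(make_cohort(clean_cohort_config(n_subjects = 1L)))$trials
  gen <- train_class_conditional("diffusion", trials, tiny_diff())
  expect_lt(tail(gen$loss_log, 1), gen$loss_log[1])
  s1 <- sample_synthetic_mt(gen, "rotation_left", 2, seed = 4)
  expect_identical(dim(s1[[1]]$strain), c(6L, gen$T))
  expect_true(all(abs(s1[[1]]$strain) <= 1))
  s2 <- sample_synthetic_mt(gen, "rotation_left", 2, seed = 4)
  expect_identical(s1[[1]]$strain, s2[[1]]$strain)
})

test_that("kinematics translator obeys pairing, shape and conditioning contracts", {
  trials <- preprocess_trials(make_cohort(clean_cohort_config(n_subjects = 2L)))$trials
  unpaired <- trials
  unpaired[[1]]$kinematics <- NULL
  expect_error(train_kinematics_translator("cvae", unpaired, tiny_cvae()),
               class = "unpaired_trial")

  tr <- train_kinematics_translator("cvae", trials, tiny_cvae(epochs = 60L))
  expect_identical(tr$condition_mode, "mt_series")
  out <- translate_kinematics(tr, trials[[1]]$strain, seed = 7)
  expect_identical(dim(out), c(6L, ncol(trials[[1]]$strain)))
  expect_identical(out, translate_kinematics(tr, trials[[1]]$strain, seed = 7))
  expect_error(translate_kinematics(tr, trials[[1]]$strain[, 1:10], seed = 1),
               class = "shape_mismatch")

  # distinct-class strains give distinct outputs (no mode collapse)
  i_flex <- which(vapply(trials, `[[`, character(1), "movement") == "flexion")[1]
  i_ext <- which(vapply(trials, `[[`, character(1), "movement") == "extension")[1]
  o1 <- translate_kinematics(tr, trials[[i_flex]]$strain, seed = 1)
  o2 <- translate_kinematics(tr, trials[[i_ext]]$strain, seed = 1)
  expect_gt(discrete_frechet(t(o1), t(o2)), 0.05)

  # zeroing the condition path makes generation independent of the strain
  tr0 <- tr
  tr0$params$cond$proj$W$val[] <- 0
  tr0$params$cond$proj$b$val[] <- 0
  z1 <- translate_kinematics(tr0, trials[[i_flex]]$strain, seed = 2)
  z2 <- translate_kinematics(tr0, trials[[i_ext]]$strain, seed = 2)
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("class-conditional and translator configs share hyperparameters", {
  cfg <- cvae_config(epochs = 10L, seed = 3L)
  expect_identical(cfg$hidden_dim, 12L)
  expect_identical(cfg$decoder_layers, 4L)
  dcfg <- diffusion_config()
  expect_identical(dcfg$sampling_steps, 500L)
  expect_identical(dcfg$hidden_dim, 64L)
  expect_identical(dcfg$decoder_layers, 12L)
})
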