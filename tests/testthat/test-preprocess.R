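test_that("baseline normalization is (R - R0)/R0", {
  expect_equal(baseline_normalize(c(10, 11, 9), 10), c(0, 0.1, -0.1))
  expect_equal(baseline_normalize(rep(7, 5), 7), rep(0, 5))
  expect_equal(baseline_normalize(12.5, 10), 0.25)
  expect_error(baseline_normalize(1:3, 0), class = "invalid_baseline")
  expect_error(baseline_normalize(1:3, -2), class = "invalid_baseline")
})

test_that("hampel filter replaces outliers and leaves smooth signals alone", {
  expect_equal(hampel_filter(rep(3, 20), 5, 3), rep(3, 20))
  expect_equal(hampel_filter(c(0, 0, 0, 100, 0, 0, 0), 5, 3),
               rep(0, 7))
  ramp <- seq(0, 10, length.out = 21)
  expect_equal(hampel_filter(ramp, 5, 3), ramp)
  expect_error(hampel_filter(1:10, window = 4), class = "invalid_config")
  # window longer than the series clamps instead of failing
  expect_length(hampel_filter(c(1, 1, 5, 1), window = 11L), 4L)
})

test_that("a single hampel pass matches a brute-force windowed median/MAD oracle", {
  oracle <- function(x, window, ns) {
    half <- window %/% 2
    vapply(seq_along(x), function(i) {
      w <- x[max(1, i - half):min(length(x), i + half)]
      med <- median(w)
      if (abs(x[i] - med) > ns * 1.4826 * median(abs(w - med))) med else x[i]
    }, numeric(1))
  }
  set.seed(42)
  for (rep_i in 1:20) {
    x <- rnorm(40) + ifelse(runif(40) < 0.1, rnorm(40, 0, 20), 0)
    expect_equal(hampel_filter(x, 7, 3, max_iter = 1L), oracle(x, 7, 3))
  }
})

test_that("hampel is idempotent on cohort-like signals", {
  co <- make_cohort(small_cohort_config(n_subjects = 2L, spike_rate = 2))
  for (pair in co[seq(1, 36, by = 7)]) {
    x <- baseline_normalize(pair$mt$resistance[1, ], pair$mt$baseline[1])
    once <- hampel_filter(x, 11, 3)
    expect_equal(hampel_filter(once, 11, 3), once)
  }
})

test_that("10-SD exclusion drops exactly the spike-injected trials", {
  clean <- preprocess_trials(make_cohort(small_cohort_config(n_subjects = 2L,
                                                             spike_rate = 0)))
  expect_length(clean$dropped, 0L)

  # T = 300 so a single injected spike cannot mask itself by inflating the
  # channel SD past the 10-SD threshold
  trials <- lapply(1:6, function(i) {
    list(subject_id = "S01", movement = "flexion", repetition = i,
         strain = matrix(rnorm(6 * 300), 6, 300))
  })
  # inject a spike 50 SDs above the channel mean into trials 2 and 5
  for (i in c(2L, 5L)) {
    ch <- trials[[i]]$strain[3, ]
    trials[[i]]$strain[3, 10] <- mean(ch) + 50 * sd(ch)
  }
  ex <- exclude_noisy_trials(trials, n_sd = 10)
  expect_length(ex$dropped, 2L)
  expect_setequal(vapply(ex$dropped, `[[`, integer(1), "repetition"), c(2L, 5L))
  # direct mean/SD verification of the rule on a kept trial
  kept1 <- ex$kept[[1]]$strain
  expect_true(all(apply(kept1, 1L, function(ch) max(ch) <= mean(ch) + 10 * sd(ch))))
  expect_length(exclude_noisy_trials(trials, n_sd = Inf)$dropped, 0L)
})

test_that("align_and_trim truncates to the shared length", {
  a <- matrix(1, 6, 300); b <- matrix(2, 6, 290)
  at <- align_and_trim(a, b)
  expect_identical(ncol(at$strain), 290L)
  expect_identical(ncol(at$angles), 290L)
  same <- align_and_trim(a, a)
  expect_identical(same$strain, a)
  pass <- align_and_trim(a, NULL)
  expect_identical(pass$strain, a)
  expect_null(pass$angles)
})

test_that("per-movement-trial min-max hits the [-1, 1] bounds exactly", {
  tr <- function(rep_i, vals) list(subject_id = "S1", movement = "flexion",
                                   repetition = rep_i,
                                   strain = matrix(vals, 1, length(vals)))
  # single-channel group spanning [2, 6]: 2 -> -1, 6 -> 1, 4 -> 0
  out <- minmax_normalize_per_movement_trial(list(tr(1, c(2, 4, 6))))
  expect_equal(out[[1]]$strain[1, ], c(-1, 0, 1))
  # constant channel maps to 0
  out2 <- minmax_normalize_per_movement_trial(list(tr(1, c(5, 5, 5))))
  expect_equal(out2[[1]]$strain[1, ], c(0, 0, 0))

  prep <- processed_small()
  key <- paste(vapply(prep, `[[`, character(1), "subject_id"),
               vapply(prep, `[[`, character(1), "movement"))
  for (k in unique(key)[1:5]) {
    grp <- prep[key == k]
    pooled <- do.call(cbind, lapply(grp, `[[`, "strain"))
    expect_equal(apply(pooled, 1L, min), rep(-1, 6))
    expect_equal(apply(pooled, 1L, max), rep(1, 6))
  }
})

test_that("the full chain is ordered, bounded and logged", {
  prep <- preprocess_trials(make_cohort(small_cohort_config(n_subjects = 1L)))
  tr <- prep$trials[[1]]
  expect_true(all(tr$strain >= -1 & tr$strain <= 1))
  expect_true(all(tr$kinematics >= -1 & tr$kinematics <= 1))
  expect_identical(tr$provenance,
                   c("baseline_normalize", "exclude_10sd", "hampel_w11_s3",
                     "align_trim", "minmax_per_movement_trial"))
  post <- preprocess_trials(make_cohort(small_cohort_config(n_subjects = 1L)),
                            exclude_after_hampel = TRUE)
  expect_match(post$trials[[1]]$provenance[3], "exclude")
})
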