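test_that("movement templates honor the documented channel orderings", {
  tpl <- movement_template("flexion", T = 300, class_overlap = 0.3)
  expect_identical(dim(tpl), c(6L, 300L))
  peaks <- apply(tpl, 1L, max)
  # tension largest for the lower sensor pair (5,6), then (3,4), then (1,2)
  expect_gt(peaks[5], peaks[1])
  expect_true(min(peaks[5:6]) > max(peaks[3:4]))
  expect_true(min(peaks[3:4]) > max(peaks[1:2]))

  ext <- movement_template("extension", T = 8, class_overlap = 0)
  expect_identical(dim(ext), c(6L, 8L))
  expect_true(all(is.finite(ext)))

  # lateral bends mirror between left {1,3,5} and right {2,4,6} columns
  lb <- movement_template("lateral_bend_left", T = 64, class_overlap = 0)
  rb <- movement_template("lateral_bend_right", T = 64, class_overlap = 0)
  expect_equal(lb[c(1, 3, 5), ], rb[c(2, 4, 6), ])
  expect_true(all(lb[1, ] * lb[2, ] <= 0))

  expect_error(movement_template("jumping_jacks", 64), class = "unknown_movement")
})

test_that("rotation templates converge as class_overlap goes to 1", {
  d <- vapply(c(0, 0.5, 1), function(ov) {
    sqrt(sum((movement_template("rotation_left", 64, ov) -
                movement_template("rotation_right", 64, ov))^2))
  }, numeric(1))
  expect_true(all(diff(d) < 0))
  expect_equal(d[3], 0)
  # at zero overlap all six templates are pairwise distinct
  tpls <- lapply(mt_movements(), movement_template, T = 64, class_overlap = 0)
  for (i in 1:5) for (j in (i + 1):6)
    expect_gt(sqrt(sum((tpls[[i]] - tpls[[j]])^2)), 0.1)
})

test_that("kinematics map is linear, length-preserving and axis-dominant", {
  tpl <- movement_template("flexion", T = 300, class_overlap = 0.3)
  ang <- kinematics_from_template("flexion", tpl)
  expect_identical(dim(ang), c(6L, 300L))
  rng <- apply(ang, 1L, function(r) diff(range(r)))
  # sagittal flexion dominates the x channels, not z
  expect_gt(rng[1], rng[3])
  expect_gt(rng[4], rng[6])

  expect_equal(kinematics_from_template("flexion", matrix(0, 6, 50)),
               matrix(0, 6, 50), ignore_attr = TRUE)
  # rotations drive z more than lateral bends do, relative to their y drive
  angr <- kinematics_from_template("rotation_left",
                                   movement_template("rotation_left", 64, 0))
  expect_gt(diff(range(angr[3, ])), diff(range(angr[2, ])))
})

test_that("make_cohort emits the full factorial of paired trials", {
  co <- make_cohort(small_cohort_config(n_subjects = 2L))
  expect_length(co, 2 * 6 * 3)
  expect_s3_class(co[[1]]$mt, "mt_trial")
  expect_s3_class(co[[1]]$kin, "kin_trial")
  expect_true(all(co[[1]]$mt$baseline > 0))
  expect_identical(ncol(co[[1]]$mt$resistance), ncol(co[[1]]$kin$angles))

  one <- make_cohort(small_cohort_config(n_subjects = 1L, reps_per_movement = 1L))
  expect_length(one, 6L)
})

test_that("cohorts are seed-deterministic and reps collapse in the clean world", {
  cfg <- small_cohort_config(n_subjects = 2L, seed = 77L)
  expect_identical(make_cohort(cfg), make_cohort(cfg))
  expect_false(identical(make_cohort(cfg),
                         make_cohort(small_cohort_config(n_subjects = 2L, seed = 78L))))

  clean <- make_cohort(clean_cohort_config(n_subjects = 1L))
  flex <- Filter(function(p) p$mt$movement == "flexion", clean)
  expect_equal(flex[[1]]$mt$resistance, flex[[2]]$mt$resistance)
  expect_equal(flex[[2]]$mt$resistance, flex[[3]]$mt$resistance)
})

test_that("config invariants are enforced", {
  expect_error(cohort_config(n_subjects = 0), class = "invalid_config")
  expect_error(cohort_config(class_overlap = 1.5), class = "invalid_config")
  expect_error(cohort_config(duration = 0.1, sample_period = 0.05),
               class = "invalid_config")
})
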