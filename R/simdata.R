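# Seeded cohort simulator: six-channel strain trials with paired lumbar
# Euler-angle kinematics, emulating the statistical structure of a small
# motion-capture-validated wearable study (10 subjects x 6 movements x 3 reps).
#
# Sensor layout: a 3x2 matrix lateral to the spine. Channels 1,2 = upper pair,
# 3,4 = middle pair, 5,6 = lower pair; odd channels on the left column, even
# on the right.

#' Cohort simulation configuration
#'
#' Collects every knob of the synthetic cohort generator. Defaults encode the
#' emulated study design: 10 subjects, 6 movements, 3 repetitions (180 trials),
#' ~6 s per trial sampled every 20 ms (T = 300).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param movements Ordered movement label set; defaults to [mt_movements()].
#' @param reps_per_movement Repetitions per subject and movement (>= 1).
#' @param sample_period Sampling period in seconds.
#' @param duration Trial duration in seconds; `T = round(duration/sample_period)`.
#' @param noise_sd Additive Gaussian noise SD in dimensionless strain units.
#' @param spike_rate Expected count of large sparse spikes per trial (Poisson).
#' @param drift_amplitude Amplitude of slow baseline drift (strain units).
#' @param class_overlap Scalar in `[0,1]`; 1 makes the two rotation-class
#'   templates identical, 0 makes them maximally distinct.
#' @param subject_amp_sd SD of the per-subject lognormal amplitude scale.
#' @param subject_warp_sd SD of the per-subject lognormal timing-warp exponent.
#' @param baseline_mean,baseline_sd Per-channel unstretched resistance draw
#'   (arbitrary units; the absolute scale cancels under baseline
#'   normalization `(R - R0)/R0`).
#' @param length_jitter If `TRUE`, trial lengths jitter uniformly by +/-10%
#'   ("around 6 s"); off by default so trials share `T`.
#' @param seed Integer master seed for the cohort.
#' @return An object of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 10L,
                          movements = mt_movements(),
                          reps_per_movement = 3L,
                          sample_period = 0.020,
                          duration = 6.0,
                          noise_sd = 0.05,
                          spike_rate = 0.3,
                          drift_amplitude = 0.05,
                          class_overlap = 0.5,
                          subject_amp_sd = 0.15,
                          subject_warp_sd = 0.10,
                          baseline_mean = 10,
                          baseline_sd = 0.5,
                          length_jitter = FALSE,
                          seed = 1L) {
  n_subjects <- check_count(n_subjects, "n_subjects")
  reps_per_movement <- check_count(reps_per_movement, "reps_per_movement")
  T_len <- as.integer(round(duration / sample_period))
  if (T_len < 8L)
    mt_stop("invalid_config", "duration/sample_period gives T=%d < 8", T_len)
  if (!is.numeric(class_overlap) || class_overlap < 0 || class_overlap > 1)
    mt_stop("invalid_config", "class_overlap must lie in [0,1]")
  stopifnot(is.character(movements), length(movements) >= 1)
  structure(list(
    n_subjects = n_subjects, movements = movements,
    reps_per_movement = reps_per_movement, sample_period = sample_period,
    duration = duration, T = T_len, noise_sd = noise_sd,
    spike_rate = spike_rate, drift_amplitude = drift_amplitude,
    class_overlap = class_overlap, subject_amp_sd = subject_amp_sd,
    subject_warp_sd = subject_warp_sd, baseline_mean = baseline_mean,
    baseline_sd = baseline_sd, length_jitter = isTRUE(length_jitter),
    seed = as.integer(seed)), class = "cohort_config")
}

# rise-hold-return window on phase u in [0,1]
bump_window <- function(u) {
  w <- numeric(length(u))
  rise <- u >= 0.15 & u < 0.35
  hold <- u >= 0.35 & u <= 0.65
  fall <- u > 0.65 & u <= 0.85
  w[rise] <- 0.5 * (1 - cos(pi * (u[rise] - 0.15) / 0.20))
  w[hold] <- 1
  w[fall] <- 0.5 * (1 + cos(pi * (u[fall] - 0.65) / 0.20))
  w
}

# Per-channel peak gains (signed strain) for each movement. Tension > 0.
movement_gains <- function(movement, class_overlap) {
  graded <- c(0.5, 0.5, 0.75, 0.75, 1.0, 1.0)      # lower sensors largest
  lat    <- c(0.9, 0.9, 0.8, 0.8, 0.7, 0.7)
  rot0   <- 0.25 * c(1.0, 1.0, 0.8, 0.8, 0.6, 0.6) # shared rotation part
  # rotation asymmetry strongest in the upper sensor pair
  rotd   <- 0.30 * c(1.0, -1.0, 0.5, -0.5, 0.15, -0.15) * (1 - class_overlap)
  switch(movement,
    flexion            = graded,
    extension          = -c(0.8, 0.8, 0.6, 0.6, 0.4, 0.4),
    # skin stretches on the convex (contralateral) side of the bend
    lateral_bend_left  = lat * c(-1, 1, -1, 1, -1, 1),
    lateral_bend_right = lat * c(1, -1, 1, -1, 1, -1),
    rotation_left      = rot0 + rotd,
    rotation_right     = rot0 - rotd,
    mt_stop("unknown_movement", "unknown movement label '%s'", movement))
}

#' Deterministic per-movement strain template
#'
#' Smooth rise-hold-return strain profile for all six sensor channels.
#' Flexion produces tension ordered lower pair > middle pair > upper pair;
#' lateral bends are mirror-asymmetric between the left (odd) and right
#' (even) sensor columns; rotations are smaller-amplitude asymmetric profiles
#' whose pairwise distance shrinks linearly to zero as `class_overlap` goes
#' to 1.
#'
#' @param movement One of [mt_movements()].
#' @param T Number of time steps (>= 8).
#' @param class_overlap Scalar in `[0,1]` controlling rotation-template
#'   similarity.
#' @return A `6 x T` numeric matrix of dimensionless strain.
#' @export
movement_template <- function(movement, T, class_overlap = 0.5) {
  T <- check_count(T, "T", min = 8L)
  if (!is.character(movement) || length(movement) != 1L)
    mt_stop("unknown_movement", "movement must be a single label")
  g <- movement_gains(movement, class_overlap)
  u <- seq(0, 1, length.out = T)
  outer(g, bump_window(u))
}

# Fixed linear readout from the six strain channels to the six Euler-angle
# channels; rows follow kin_channel_roles(). Sagittal motion (all channels in
# phase) drives the x channels, uniform left/right column differences drive y,
# row-graded column differences (rotation) drive z.
kin_map_matrix <- function() {
  x_row <- -rep(1 / 3, 6)                       # flexion -> angle decrease
  y_row <- c(1, -1, 1, -1, 1, -1) / 3
  z_row <- c(1, -1, -0.2, 0.2, -0.8, 0.8)      # cancels uniform column diffs
  M <- rbind(x_row, y_row, z_row,
             0.8 * x_row, 0.8 * y_row, 0.8 * z_row)
  rownames(M) <- kin_channel_roles()
  30 * M  # degrees at unit strain
}

#' Ground-truth kinematics from a strain template
#'
#' Deterministic linear map of the six strain channels onto the six
#' Euler-angle channels, followed by light moving-average smoothing. Flexion
#' dominantly drives the x (sagittal) channels, lateral bends a second axis,
#' rotations the third — a known map so that translator recovery is testable.
#'
#' @param movement Movement label (checked, but the map itself is shared).
#' @param template A `6 x T` strain matrix, e.g. from [movement_template()].
#' @return A `6 x T` matrix of Euler angles in degrees, rows ordered as
#'   [kin_channel_roles()].
#' @export
kinematics_from_template <- function(movement, template) {
  if (!movement %in% mt_movements())
    mt_stop("unknown_movement", "unknown movement label '%s'", movement)
  stopifnot(is.matrix(template), nrow(template) == 6L)
  ang <- kin_map_matrix() %*% template
  k <- 5L
  if (ncol(ang) >= k) {
    kern <- rep(1 / k, k)
    ang <- t(apply(ang, 1L, function(r) {
      pad <- c(rep(r[1], k %/% 2), r, rep(r[length(r)], k %/% 2))
      stats::filter(pad, kern, sides = 2)[(k %/% 2 + 1):(k %/% 2 + length(r))]
    }))
  }
  rownames(ang) <- kin_channel_roles()
  ang
}

new_mt_trial <- function(subject_id, movement, repetition, resistance,
                         baseline, sample_period) {
  structure(list(subject_id = subject_id, movement = movement,
                 repetition = repetition, resistance = resistance,
                 baseline = baseline, sample_period = sample_period),
            class = "mt_trial")
}

new_kin_trial <- function(subject_id, movement, repetition, angles,
                          sample_period) {
  structure(list(subject_id = subject_id, movement = movement,
                 repetition = repetition, angles = angles,
                 channel_roles = kin_channel_roles(),
                 sample_period = sample_period),
            class = "kin_trial")
}

#' Simulate a full cohort of paired strain and kinematics trials
#'
#' Emits `n_subjects x length(movements) x reps_per_movement` paired trials.
#' Each subject gets a lognormal amplitude scale, a lognormal timing-warp
#' exponent and per-channel baseline resistances; each trial adds Gaussian
#' noise, Poisson-count sparse spikes and a slow baseline drift to the
#' movement template. Fully reproducible from `config$seed`.
#'
#' @param config A [cohort_config()].
#' @return A list of class `mt_cohort`; each element is
#'   `list(mt = <mt_trial>, kin = <kin_trial>)`. The config is attached as
#'   attribute `config`.
#' @export
make_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  cohort <- list()
  for (s in seq_len(config$n_subjects)) {
    subj_seed <- derive_seed(config$seed, 1L, s)
    subj <- with_seed(subj_seed, list(
      amp  = rlnorm(1, 0, config$subject_amp_sd),
      warp = rlnorm(1, 0, config$subject_warp_sd),
      baseline = pmax(1, rnorm(6, config$baseline_mean, config$baseline_sd))))
    sid <- sprintf("S%02d", s)
    for (mi in seq_along(config$movements)) {
      mv <- config$movements[mi]
      for (r in seq_len(config$reps_per_movement)) {
        trial_seed <- derive_seed(config$seed, 2L, s, mi, r)
        tr <- with_seed(trial_seed,
                        simulate_trial(sid, mv, r, subj, config))
        cohort[[length(cohort) + 1L]] <- tr
      }
    }
  }
  structure(cohort, class = "mt_cohort", config = config)
}

simulate_trial <- function(sid, mv, rep_i, subj, config) {
  T_len <- config$T
  if (config$length_jitter)
    T_len <- max(8L, as.integer(round(T_len * runif(1, 0.9, 1.1))))
  # subject timing warp: evaluate the template on a warped phase grid
  u <- seq(0, 1, length.out = T_len)^subj$warp
  g <- movement_gains(mv, config$class_overlap)
  strain <- subj$amp * outer(g, bump_window(u))
  angles <- kinematics_from_template(mv, strain)

  noisy <- strain
  if (config$noise_sd > 0)
    noisy <- noisy + matrix(rnorm(6 * T_len, 0, config$noise_sd), 6, T_len)
  if (config$drift_amplitude > 0) {
    slope  <- runif(6, -1, 1) * config$drift_amplitude
    offset <- rnorm(6, 0, config$drift_amplitude / 2)
    noisy <- noisy + outer(slope, seq(0, 1, length.out = T_len)) + offset
  }
  n_spk <- if (config$spike_rate > 0) rpois(1, config$spike_rate) else 0L
  if (n_spk > 0) {
    for (k in seq_len(n_spk)) {
      ch <- sample.int(6, 1); t0 <- sample.int(T_len, 1)
      noisy[ch, t0] <- noisy[ch, t0] +
        sample(c(-1, 1), 1) * runif(1, 0.5, 1.5)
    }
  }
  resistance <- subj$baseline * (1 + noisy)  # so (R - R0)/R0 recovers strain
  list(mt  = new_mt_trial(sid, mv, rep_i, resistance, subj$baseline,
                          config$sample_period),
       kin = new_kin_trial(sid, mv, rep_i, angles, config$sample_period))
}

#' @export
print.mt_cohort <- function(x, ...) {
  cfg <- attr(x, "config")
  cat(sprintf("<mt_cohort> %d paired trials (%d subjects x %d movements x %d reps), T=%d\n",
              length(x), cfg$n_subjects, length(cfg$movements),
              cfg$reps_per_movement, cfg$T))
  invisible(x)
}
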