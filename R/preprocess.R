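# Raw-resistance processing chain: baseline normalization -> Hampel outlier
# filtering -> 10-SD noisy-trial exclusion -> alignment/trim against paired
# kinematics -> per-(subject, movement) min-max scaling to [-1, 1].

#' Baseline-normalize a resistance series
#'
#' `Rn = (R - R0) / R0`: relative resistance change with respect to the
#' unstretched baseline, i.e. strain in dimensionless units.
#'
#' @param R Numeric vector (or matrix, normalized element-wise).
#' @param R0 Positive scalar baseline resistance.
#' @return Same shape as `R`.
#' @export
baseline_normalize <- function(R, R0) {
  if (!is.numeric(R0) || length(R0) != 1L || is.na(R0) || R0 <= 0)
    mt_stop("invalid_baseline", "baseline R0 must be a positive scalar")
  (R - R0) / R0
}

#' Hampel outlier filter
#'
#' Sliding-window median/MAD detector: a point farther than
#' `n_sigmas * 1.4826 * MAD` from its local window median is replaced by that
#' median. Windows are local within the series (truncated at the edges).
#' With a zero-MAD window a point is replaced only when strictly different
#' from the local median. The pass is repeated until the series stops
#' changing (at most `max_iter` passes), which makes the filter a projection:
#' applying it twice equals applying it once.
#'
#' @param x Numeric vector.
#' @param window Odd window length >= 3 (clamped, with a warning in the
#'   provenance of callers, when longer than the series).
#' @param n_sigmas Threshold in estimated SD units.
#' @param max_iter Maximum number of passes (1 = classic single-pass filter).
#' @return Filtered vector.
#' @export
hampel_filter <- function(x, window = 11L, n_sigmas = 3, max_iter = 10L) {
  window <- check_count(window, "window", min = 3L)
  if (window %% 2L == 0L) mt_stop("invalid_config", "window must be odd")
  n <- length(x)
  if (window > n) {
    window <- if (n %% 2L == 1L) n else n - 1L
    if (window < 3L) return(x)
  }
  half <- window %/% 2L
  for (pass in seq_len(max_iter)) {
    y <- x
    for (i in seq_len(n)) {
      lo <- max(1L, i - half); hi <- min(n, i + half)
      w <- x[lo:hi]
      med <- median(w)
      thr <- n_sigmas * 1.4826 * median(abs(w - med))
      if (abs(x[i] - med) > thr) y[i] <- med
    }
    if (identical(y, x)) break
    x <- y
  }
  x
}

hampel_trial <- function(strain, window, n_sigmas) {
  t(apply(strain, 1L, hampel_filter, window = window, n_sigmas = n_sigmas))
}

#' Exclude excessively noisy trials
#'
#' A trial is dropped iff any channel contains a value greater than
#' `mean + n_sd * SD` of that channel's own series within the trial (the most
#' local reading of the exclusion rule). At `n_sd = Inf` nothing drops.
#'
#' @param trials List of trials, each carrying a `6 x T` `strain` matrix (or
#'   `mt_trial` resistance matrices).
#' @param n_sd Exclusion threshold in per-channel SD units (default 10).
#' @param field Name of the matrix field examined (default "strain").
#' @return `list(kept = , dropped = , reasons = )`, the two partitions plus a
#'   character reason per dropped trial.
#' @export
exclude_noisy_trials <- function(trials, n_sd = 10, field = "strain") {
  if (length(trials) < 1L) mt_stop("empty_input", "need at least one trial")
  keep <- logical(length(trials)); reasons <- character(0)
  for (i in seq_along(trials)) {
    m <- trials[[i]][[field]]
    bad <- NULL
    if (is.finite(n_sd)) {
      for (ch in seq_len(nrow(m))) {
        mu <- mean(m[ch, ]); s <- sd(m[ch, ])
        if (s > 0 && any(m[ch, ] > mu + n_sd * s)) { bad <- ch; break }
      }
    }
    keep[i] <- is.null(bad)
    if (!is.null(bad))
      reasons <- c(reasons, sprintf(
        "trial %d (%s/%s/rep%s): channel %d exceeds mean + %g SD",
        i, trials[[i]]$subject_id %||% "?", trials[[i]]$movement %||% "?",
        trials[[i]]$repetition %||% "?", bad, n_sd))
  }
  list(kept = trials[keep], dropped = trials[!keep], reasons = reasons)
}

#' Align a strain trial with its paired kinematics and trim to equal length
#'
#' Both series start at t = 0 of the trial clock; the longer one is truncated
#' to the shared length.
#'
#' @param strain `6 x T1` matrix.
#' @param angles `6 x T2` matrix or `NULL` (passthrough).
#' @return `list(strain = , angles = )` with equal column counts (or original
#'   strain and `NULL`).
#' @export
align_and_trim <- function(strain, angles = NULL) {
  if (is.null(angles)) return(list(strain = strain, angles = NULL))
  Tp <- min(ncol(strain), ncol(angles))
  if (Tp < 1L) mt_stop("empty_overlap", "series have no temporal overlap")
  list(strain = strain[, seq_len(Tp), drop = FALSE],
       angles = angles[, seq_len(Tp), drop = FALSE])
}

minmax_map <- function(m, lo, hi) {
  out <- m
  for (ch in seq_len(nrow(m))) {
    if (hi[ch] > lo[ch]) {
      out[ch, ] <- 2 * (m[ch, ] - lo[ch]) / (hi[ch] - lo[ch]) - 1
    } else {
      out[ch, ] <- 0  # degenerate constant channel
    }
  }
  out
}

#' Per-movement-trial min-max normalization
#'
#' Scales each channel to `[-1, 1]` using the min/max pooled over the group of
#' repetitions of one movement by one subject (a "movement trial"), so -1/+1
#' correspond to that subject's own peak compression/tension. A channel that
#' is constant within its group maps to 0. Kinematics channels, when present,
#' are scaled by the same rule.
#'
#' @param trials List of trials with fields `subject_id`, `movement`,
#'   `strain` and optionally `kinematics`.
#' @return The list with `strain` (and `kinematics`) rescaled.
#' @export
minmax_normalize_per_movement_trial <- function(trials) {
  if (length(trials) < 1L) mt_stop("empty_input", "need at least one trial")
  key <- vapply(trials, function(tr) paste(tr$subject_id, tr$movement, sep = "\r"),
                character(1))
  for (k in unique(key)) {
    idx <- which(key == k)
    smin <- apply(do.call(cbind, lapply(trials[idx], `[[`, "strain")), 1L, min)
    smax <- apply(do.call(cbind, lapply(trials[idx], `[[`, "strain")), 1L, max)
    has_kin <- !vapply(trials[idx], function(tr) is.null(tr$kinematics), logical(1))
    if (any(has_kin)) {
      kin_all <- do.call(cbind, lapply(trials[idx][has_kin], `[[`, "kinematics"))
      kmin <- apply(kin_all, 1L, min); kmax <- apply(kin_all, 1L, max)
    }
    for (i in idx) {
      trials[[i]]$strain <- minmax_map(trials[[i]]$strain, smin, smax)
      if (!is.null(trials[[i]]$kinematics))
        trials[[i]]$kinematics <- minmax_map(trials[[i]]$kinematics, kmin, kmax)
    }
  }
  trials
}

#' Run the full preprocessing chain on a simulated or ingested cohort
#'
#' Fixed stage order: baseline normalization, noisy-trial exclusion (before
#' Hampel by default; `exclude_after_hampel = TRUE` swaps), Hampel filtering,
#' alignment/trim against paired kinematics, per-(subject, movement) min-max
#' scaling. Every applied step is recorded in each trial's `provenance`.
#'
#' @param cohort An `mt_cohort` (paired `mt`/`kin` elements) or a list of such
#'   pairs; `kin` may be `NULL`.
#' @param hampel_window,hampel_sigmas Hampel parameters.
#' @param exclude_sd Noisy-trial exclusion threshold in SD units (`Inf`
#'   disables).
#' @param exclude_after_hampel Apply the exclusion after rather than before
#'   the Hampel stage.
#' @return `list(trials = <processed_trial list>, dropped = , reasons = )`.
#' @export
preprocess_trials <- function(cohort, hampel_window = 11L, hampel_sigmas = 3,
                              exclude_sd = 10, exclude_after_hampel = FALSE) {
  steps0 <- character(0)
  trials <- lapply(cohort, function(pair) {
    mt <- pair$mt
    strain <- mt$resistance
    for (ch in seq_len(6L))
      strain[ch, ] <- baseline_normalize(mt$resistance[ch, ], mt$baseline[ch])
    structure(list(subject_id = mt$subject_id, movement = mt$movement,
                   repetition = mt$repetition, strain = strain,
                   kinematics = if (!is.null(pair$kin)) pair$kin$angles,
                   provenance = c(steps0, "baseline_normalize")),
              class = "processed_trial")
  })
  run_exclude <- function(trs) {
    ex <- exclude_noisy_trials(trs, n_sd = exclude_sd)
    ex$kept <- lapply(ex$kept, function(tr) {
      tr$provenance <- c(tr$provenance, sprintf("exclude_%gsd", exclude_sd)); tr
    })
    ex
  }
  dropped <- list(); reasons <- character(0)
  if (!exclude_after_hampel) {
    ex <- run_exclude(trials); trials <- ex$kept
    dropped <- ex$dropped; reasons <- ex$reasons
  }
  trials <- lapply(trials, function(tr) {
    tr$strain <- hampel_trial(tr$strain, hampel_window, hampel_sigmas)
    tr$provenance <- c(tr$provenance,
                       sprintf("hampel_w%d_s%g", hampel_window, hampel_sigmas))
    tr
  })
  if (exclude_after_hampel) {
    ex <- run_exclude(trials); trials <- ex$kept
    dropped <- ex$dropped; reasons <- ex$reasons
  }
  trials <- lapply(trials, function(tr) {
    at <- align_and_trim(tr$strain, tr$kinematics)
    tr$strain <- at$strain; tr$kinematics <- at$angles
    tr$provenance <- c(tr$provenance, "align_trim")
    tr
  })
  trials <- minmax_normalize_per_movement_trial(trials)
  trials <- lapply(trials, function(tr) {
    tr$provenance <- c(tr$provenance, "minmax_per_movement_trial"); tr
  })
  list(trials = trials, dropped = dropped, reasons = reasons)
}
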