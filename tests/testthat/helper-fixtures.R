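# Shared fixtures: small, fast cohorts built in code. T = 48 (2.4 s at 50 ms)
# keeps neural training affordable; structural counts never depend on T.

small_cohort_config <- function(..., seed = 101L) {
  cohort_config(duration = 2.4, sample_period = 0.05, seed = seed, ...)
}

# noise-free, zero-overlap, identical-subject world: repetitions identical,
# classes maximally separable
clean_cohort_config <- function(n_subjects = 4L, seed = 102L, ...) {
  small_cohort_config(n_subjects = n_subjects, noise_sd = 0, spike_rate = 0,
                      drift_amplitude = 0, class_overlap = 0, seed = seed, ...)
}

processed_small <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- preprocess_trials(make_cohort(small_cohort_config(n_subjects = 4L)))$trials
    cache
  }
})

# brute-force discrete Frechet: enumerate all monotone couplings (oracle)
frechet_bruteforce <- function(P, Q) {
  if (!is.matrix(P)) P <- matrix(P, ncol = 1L)
  if (!is.matrix(Q)) Q <- matrix(Q, ncol = 1L)
  d <- function(i, j) sqrt(sum((P[i, ] - Q[j, ])^2))
  best <- Inf
  rec <- function(i, j, cur) {
    cur <- max(cur, d(i, j))
    if (cur >= best) return()
    if (i == nrow(P) && j == nrow(Q)) { best <<- cur; return() }
    if (i < nrow(P)) rec(i + 1L, j, cur)
    if (j < nrow(Q)) rec(i, j + 1L, cur)
    if (i < nrow(P) && j < nrow(Q)) rec(i + 1L, j + 1L, cur)
  }
  rec(1L, 1L, 0)
  best
}

# sorted-sample closed form for equal-size W1 (oracle)
w1_sorted_oracle <- function(a, b) mean(abs(sort(a) - sort(b)))

class_mean_templates <- function(trials) {
  out <- lapply(mt_movements(), function(m) {
    idx <- which(vapply(trials, `[[`, character(1), "movement") == m)
    Reduce(`+`, lapply(trials[idx], `[[`, "strain")) / length(idx)
  })
  names(out) <- mt_movements()
  out
}
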