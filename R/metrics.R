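# Generative-quality metrics: empirical 1-D Wasserstein distance (earth
# mover's distance) and the discrete Frechet time-series distance (FTSD).

#' Empirical 1-D Wasserstein-1 distance
#'
#' Exact W1 between the empirical distributions of two value samples, via the
#' quantile-function formula (the 1-D closed form of the optimal-coupling
#' definition). Sample sizes need not match.
#'
#' @param a,b Nonempty numeric vectors.
#' @return Nonnegative scalar.
#' @export
wasserstein_1d <- function(a, b) {
  if (length(a) < 1L || length(b) < 1L)
    mt_stop("empty_input", "both samples must be nonempty")
  if (length(a) == length(b)) return(mean(abs(sort(a) - sort(b))))
  # integral of |F_a - F_b| over the pooled support
  xs <- sort(c(a, b))
  dx <- diff(xs)
  Fa <- vapply(xs[-length(xs)], function(x) mean(a <= x), numeric(1))
  Fb <- vapply(xs[-length(xs)], function(x) mean(b <= x), numeric(1))
  sum(abs(Fa - Fb) * dx)
}

#' Set-level Wasserstein distance between two series collections
#'
#' Per channel, pools all values across samples and time steps, computes the
#' 1-D W1 between the pooled real and synthetic value distributions, and
#' averages over channels.
#'
#' @param A,B Lists of `C x T` matrices (or `feature_tensor`/trial lists via
#'   `field`).
#' @param field Optional field name extracting the matrix from list elements.
#' @return Nonnegative scalar.
#' @export
wasserstein_sets <- function(A, B, field = NULL) {
  A <- extract_series(A, field); B <- extract_series(B, field)
  C <- nrow(A[[1]])
  if (nrow(B[[1]]) != C)
    mt_stop("channel_mismatch", "channel counts differ (%d vs %d)", C, nrow(B[[1]]))
  w <- vapply(seq_len(C), function(ch) {
    wasserstein_1d(unlist(lapply(A, function(m) m[ch, ])),
                   unlist(lapply(B, function(m) m[ch, ])))
  }, numeric(1))
  mean(w)
}

extract_series <- function(x, field) {
  if (!is.null(field)) x <- lapply(x, `[[`, field)
  if (is.matrix(x)) x <- list(x)
  stopifnot(length(x) >= 1L, all(vapply(x, is.matrix, logical(1))))
  x
}

#' Discrete Frechet distance between two curves
#'
#' Minimum over monotone index couplings of the maximum pointwise Euclidean
#' distance — the computable realization of the continuous Frechet distance
#' for polyline vertices (Eiter-Mannila dynamic program, implemented in C++).
#'
#' @param P,Q `T x C` matrices (rows = time steps) or plain numeric vectors
#'   (treated as 1-channel curves).
#' @return Nonnegative scalar.
#' @export
discrete_frechet <- function(P, Q) {
  if (!is.matrix(P)) P <- matrix(P, ncol = 1L)
  if (!is.matrix(Q)) Q <- matrix(Q, ncol = 1L)
  if (nrow(P) < 1L || nrow(Q) < 1L)
    mt_stop("empty_input", "sequences must be nonempty")
  if (ncol(P) != ncol(Q))
    mt_stop("dimension_mismatch", "point dimensions differ (%d vs %d)",
            ncol(P), ncol(Q))
  .frechet_cpp(P, Q)
}

#' Set-level Frechet time-series distance (real vs synthetic)
#'
#' For each synthetic sample, the discrete Frechet distance to every real
#' sample of the same class is computed and the minimum taken; the score is
#' the mean of these minima over synthetic samples. Series are `C x T`
#' matrices; the point metric is Euclidean across the C channels at each time
#' index.
#'
#' @param real,synthetic Lists of `C x T` matrices.
#' @param real_labels,synthetic_labels Class labels per sample; `NULL` treats
#'   all samples as one class.
#' @param field Optional extraction field as in [wasserstein_sets()].
#' @return Nonnegative scalar.
#' @export
ftsd_sets <- function(real, synthetic, real_labels = NULL,
                      synthetic_labels = NULL, field = NULL) {
  real <- extract_series(real, field); synthetic <- extract_series(synthetic, field)
  if (is.null(real_labels)) real_labels <- rep("all", length(real))
  if (is.null(synthetic_labels)) synthetic_labels <- rep("all", length(synthetic))
  mins <- vapply(seq_along(synthetic), function(i) {
    idx <- which(real_labels == synthetic_labels[i])
    if (length(idx) == 0L)
      mt_stop("class_absent", "class '%s' absent in real set", synthetic_labels[i])
    min(vapply(idx, function(j)
      discrete_frechet(t(synthetic[[i]]), t(real[[j]])), numeric(1)))
  }, numeric(1))
  mean(mins)
}

#' Repeated generative-model evaluation
#'
#' Retrains/regenerates `n_runs` times via the caller-supplied closure and
#' reports mean and SD of the Wasserstein and FTSD scores against a fixed
#' real set, mirroring a repeated-trials evaluation protocol.
#'
#' @param real List of `C x T` matrices with `real_labels`.
#' @param sampler Function `f(run_seed) -> list(series = , labels = )`
#'   producing a synthetic set.
#' @param real_labels Labels for the real set.
#' @param n_runs Number of repeats (default 5).
#' @param seed Master seed; run seeds are derived from it.
#' @return List of class `metric_report`: per-run scores plus mean/SD.
#' @export
evaluate_generator <- function(real, sampler, real_labels = NULL, n_runs = 5L,
                               seed = 1L) {
  n_runs <- check_count(n_runs, "n_runs")
  wd <- numeric(n_runs); ft <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    syn <- sampler(derive_seed(seed, 7L, r))
    wd[r] <- wasserstein_sets(real, syn$series)
    ft[r] <- ftsd_sets(real, syn$series, real_labels, syn$labels)
  }
  structure(list(wasserstein = c(mean = mean(wd), sd = sd_or_zero(wd)),
                 ftsd = c(mean = mean(ft), sd = sd_or_zero(ft)),
                 runs = data.frame(run = seq_len(n_runs), wasserstein = wd,
                                   ftsd = ft),
                 n_runs = n_runs, seed = seed),
            class = "metric_report")
}

sd_or_zero <- function(x) if (length(x) > 1L) sd(x) else 0
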