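#' @useDynLib mtaim, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats fft mad median prcomp quantile rnorm rpois runif rlnorm sd var
#' @importFrom utils head read.csv write.csv
NULL

#' Canonical movement label set
#'
#' The six low-back movements, in fixed order: standing extension, forward
#' flexion, left/right lateral bend, seated left/right rotation.
#'
#' @return Character vector of length 6.
#' @export
mt_movements <- function() {
  c("extension", "flexion", "lateral_bend_left", "lateral_bend_right",
    "rotation_left", "rotation_right")
}

#' Fixed kinematic channel roles
#'
#' Euler-angle channels between upper and lower lumbar segments and between
#' the lower lumbar segment and the pelvis, x/y/z each.
#'
#' @return Character vector of length 6.
#' @export
kin_channel_roles <- function() {
  c("upper_lower_x", "upper_lower_y", "upper_lower_z",
    "lower_pelvis_x", "lower_pelvis_y", "lower_pelvis_z")
}

mt_stop <- function(code, fmt, ...) {
  stop(structure(class = c(code, "mtaim_error", "error", "condition"),
                 list(message = sprintf(fmt, ...), call = sys.call(-1))))
}

# All randomness flows from a master seed; derived seeds stay below 2^31.
derive_seed <- function(seed, ...) {
  offs <- c(...)
  s <- as.double(seed)
  for (o in offs) s <- (s * 69069 + as.double(o) + 1) %% 2147483647
  as.integer(s)
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
  }
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    mt_stop("invalid_config", "%s must be an integer >= %d (got %s)", name, min,
            paste(x, collapse = ","))
  as.integer(x)
}
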