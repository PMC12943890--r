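# Frequency-domain channel augmentation and assembly of the stacked feature
# tensor (6 strain channels, +6 DTFT magnitude channels, +6 kinematics).

#' DTFT magnitude channels
#'
#' Per channel, the magnitude of the length-T discrete Fourier transform
#' divided by T, returned as a length-T sequence (full two-sided spectrum) so
#' the frequency block stacks alongside the time-domain channels. Magnitude
#' (not phase) makes the block invariant to circular time shifts, i.e.
#' "time-independent".
#'
#' @param strain `C x T` matrix, `T >= 2`.
#' @return `C x T` matrix of spectral magnitudes.
#' @export
dtft_channels <- function(strain) {
  stopifnot(is.matrix(strain))
  if (ncol(strain) < 2L) mt_stop("invalid_input", "need T >= 2")
  t(apply(strain, 1L, function(x) Mod(fft(x)) / length(x)))
}

#' Assemble a stacked feature tensor
#'
#' Stacks the provided channel blocks in fixed role order (strain, then DTFT,
#' then kinematics), yielding 6, 12 or 18 channels. Slicing the named roles
#' recovers the input blocks exactly.
#'
#' @param strain `6 x T` strain block (required).
#' @param dtft Optional `6 x T` DTFT block.
#' @param kin Optional `6 x T` kinematics block.
#' @param movement,subject_id,repetition Label metadata carried along.
#' @param synthetic Flag marking generator-produced samples.
#' @return An object of class `feature_tensor` with fields `values`
#'   (`C x T`), `channel_roles`, and the metadata.
#' @export
assemble_features <- function(strain, dtft = NULL, kin = NULL,
                              movement = NA_character_,
                              subject_id = NA_character_,
                              repetition = NA_integer_,
                              synthetic = FALSE) {
  stopifnot(is.matrix(strain), nrow(strain) == 6L)
  blocks <- list(strain)
  roles <- paste0("strain", 1:6)
  for (nm in c("dtft", "kin")) {
    b <- get(nm)
    if (!is.null(b)) {
      stopifnot(is.matrix(b), nrow(b) == 6L)
      if (ncol(b) != ncol(strain))
        mt_stop("length_mismatch", "%s block length %d != strain length %d",
                nm, ncol(b), ncol(strain))
      blocks <- c(blocks, list(b))
      roles <- c(roles, paste0(nm, 1:6))
    }
  }
  values <- do.call(rbind, blocks)
  dimnames(values) <- NULL
  structure(list(values = values, channel_roles = roles,
                 movement = movement, subject_id = subject_id,
                 repetition = repetition, synthetic = isTRUE(synthetic)),
            class = "feature_tensor")
}

#' Featurize processed trials
#'
#' Maps [assemble_features()] over a list of processed trials, optionally
#' adding the DTFT block and a kinematics block (the trial's own paired
#' kinematics, or series produced by a translator).
#'
#' @param trials `processed_trial` list.
#' @param dtft Add DTFT magnitude channels.
#' @param kinematics One of `"none"`, `"paired"` (use `tr$kinematics`), or a
#'   function `f(strain) -> 6 x T` (e.g. a translator closure).
#' @param synthetic Flag forwarded to every tensor.
#' @return List of `feature_tensor`.
#' @export
featurize_trials <- function(trials, dtft = TRUE, kinematics = "none",
                             synthetic = FALSE) {
  lapply(trials, function(tr) {
    kin <- NULL
    if (is.function(kinematics)) kin <- kinematics(tr$strain)
    else if (identical(kinematics, "paired")) {
      if (is.null(tr$kinematics))
        mt_stop("missing_kinematics", "trial %s/%s has no paired kinematics",
                tr$subject_id, tr$movement)
      kin <- tr$kinematics
    }
    assemble_features(tr$strain,
                      dtft = if (dtft) dtft_channels(tr$strain),
                      kin = kin,
                      movement = tr$movement, subject_id = tr$subject_id,
                      repetition = tr$repetition,
                      synthetic = synthetic || isTRUE(tr$synthetic))
  })
}
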