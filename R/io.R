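# On-disk formats: one wide CSV per trial (time_s, mt1..mt6[, ang1..ang6])
# plus a cohort manifest JSON; generator / classifier checkpoints as JSON
# with a config + seed manifest.

#' Write a cohort to disk
#'
#' One wide CSV per trial with columns `time_s`, `mt1..mt6` and, when paired
#' kinematics exist, `ang1..ang6`; baselines are stored in the manifest.
#'
#' @param cohort An `mt_cohort` (or compatible list of `mt`/`kin` pairs).
#' @param dir Output directory (created if missing).
#' @return Invisibly, the manifest path.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- attr(cohort, "config")
  manifest <- list(seed = cfg$seed %||% NA, trials = list())
  for (i in seq_along(cohort)) {
    mt <- cohort[[i]]$mt; kin <- cohort[[i]]$kin
    fn <- sprintf("trial_%04d.csv", i)
    Tn <- ncol(mt$resistance)
    df <- data.frame(time_s = (seq_len(Tn) - 1L) * mt$sample_period)
    for (ch in 1:6) df[[paste0("mt", ch)]] <- mt$resistance[ch, ]
    if (!is.null(kin)) {
      Tk <- min(Tn, ncol(kin$angles))
      for (ch in 1:6) df[[paste0("ang", ch)]] <- c(kin$angles[ch, seq_len(Tk)],
                                                  rep(NA, Tn - Tk))
    }
    write.csv(df, file.path(dir, fn), row.names = FALSE)
    manifest$trials[[i]] <- list(subject = mt$subject_id,
                                 movement = mt$movement,
                                 repetition = mt$repetition, file = fn,
                                 baseline = mt$baseline,
                                 sample_period = mt$sample_period)
  }
  mp <- file.path(dir, "manifest.json")
  jsonlite::write_json(manifest, mp, auto_unbox = TRUE, digits = NA)
  invisible(mp)
}

#' Read a cohort written by [write_cohort()] (or any CSV in the same dialect)
#'
#' @param dir Directory containing `manifest.json` and the trial CSVs.
#' @return An `mt_cohort`-compatible list of `mt`/`kin` pairs.
#' @export
read_cohort <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  cohort <- lapply(manifest$trials, function(tr) {
    df <- read.csv(file.path(dir, tr$file))
    res <- t(as.matrix(df[paste0("mt", 1:6)]))
    dimnames(res) <- NULL
    mt <- new_mt_trial(tr$subject, tr$movement, tr$repetition, res,
                       unlist(tr$baseline), tr$sample_period)
    kin <- NULL
    if (all(paste0("ang", 1:6) %in% names(df))) {
      ang <- t(as.matrix(df[paste0("ang", 1:6)]))
      keep <- !apply(is.na(ang), 2L, any)
      ang <- ang[, keep, drop = FALSE]
      rownames(ang) <- kin_channel_roles()
      kin <- new_kin_trial(tr$subject, tr$movement, tr$repetition, ang,
                           tr$sample_period)
    }
    list(mt = mt, kin = kin)
  })
  structure(cohort, class = "mt_cohort",
            config = list(seed = manifest$seed))
}

#' Save / load a trained generator checkpoint (JSON + manifest)
#'
#' @param model An `mt_generator`.
#' @param path Output `.json` path.
#' @return Invisibly, `path`.
#' @export
save_generator <- function(model, path) {
  stopifnot(inherits(model, "mt_generator"))
  vals <- params_values(model$params)
  payload <- list(kind = model$kind, condition_mode = model$condition_mode,
                  config = unclass(model$config), D = model$D, T = model$T,
                  C = model$C, labels = model$labels, seed = model$seed,
                  shapes = lapply(vals, dim), values = lapply(vals, as.vector))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_generator
#' @export
load_generator <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- p$config
  class(cfg) <- c(paste0(p$kind, "_config"), "generator_config")
  cond <- if (p$condition_mode == "mt_series") list(T = p$T)
  params <- if (p$kind == "cvae") cvae_arch_init(p$D, length(p$labels), cfg,
                                                 cond_dim = if (!is.null(cond)) 1L)
            else diffusion_arch_init(p$D, length(p$labels), cfg,
                                     cond_dim = if (!is.null(cond)) 1L)
  if (!is.null(cond)) {
    proj <- if (p$kind == "cvae") cfg$latent_dim else cfg$hidden_dim
    params$cond <- cond_path_init(cfg$hidden_dim, proj)
  }
  vals <- lapply(seq_along(p$values), function(i)
    matrix(p$values[[i]], p$shapes[[i]][1], p$shapes[[i]][2]))
  params_restore(params, vals)
  new_generator(p$kind, p$condition_mode, cfg, params, p$D, p$T, p$C,
                p$labels, NULL)
}

#' Write / read feature tensors (wide CSV per tensor + JSON manifest)
#'
#' Columns are `t` plus one column per channel named by its role
#' (`strain1..6`, `dtft1..6`, `kin1..6`).
#'
#' @param tensors List of `feature_tensor`.
#' @param dir Output directory.
#' @return Invisibly, `dir`.
#' @export
write_feature_tensors <- function(tensors, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(tensors = list())
  for (i in seq_along(tensors)) {
    ft <- tensors[[i]]
    fn <- sprintf("features_%04d.csv", i)
    df <- data.frame(t = seq_len(ncol(ft$values)))
    for (ch in seq_along(ft$channel_roles))
      df[[ft$channel_roles[ch]]] <- ft$values[ch, ]
    write.csv(df, file.path(dir, fn), row.names = FALSE)
    manifest$tensors[[i]] <- list(subject = ft$subject_id,
                                  movement = ft$movement,
                                  repetition = ft$repetition, file = fn,
                                  synthetic = isTRUE(ft$synthetic),
                                  roles = ft$channel_roles)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_feature_tensors
#' @param dir Directory written by [write_feature_tensors()].
#' @export
read_feature_tensors <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest$tensors, function(ft) {
    df <- read.csv(file.path(dir, ft$file))
    roles <- unlist(ft$roles)
    vals <- t(as.matrix(df[roles])); dimnames(vals) <- NULL
    structure(list(values = vals, channel_roles = roles,
                   movement = ft$movement, subject_id = ft$subject,
                   repetition = ft$repetition,
                   synthetic = isTRUE(ft$synthetic)),
              class = "feature_tensor")
  })
}

write_processed_trials <- function(trials, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(trials = list())
  for (i in seq_along(trials)) {
    tr <- trials[[i]]
    fn <- sprintf("processed_%04d.csv", i)
    df <- data.frame(t = seq_len(ncol(tr$strain)))
    for (ch in 1:6) df[[paste0("mt", ch)]] <- tr$strain[ch, ]
    if (!is.null(tr$kinematics))
      for (ch in 1:6) df[[paste0("ang", ch)]] <- tr$kinematics[ch, ]
    write.csv(df, file.path(dir, fn), row.names = FALSE)
    manifest$trials[[i]] <- list(subject = tr$subject_id, movement = tr$movement,
                                 repetition = tr$repetition, file = fn,
                                 synthetic = isTRUE(tr$synthetic),
                                 provenance = tr$provenance)
  }
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

read_processed_trials <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"))
  lapply(manifest$trials, function(tr) {
    df <- read.csv(file.path(dir, tr$file))
    strain <- t(as.matrix(df[paste0("mt", 1:6)])); rownames(strain) <- NULL
    kin <- NULL
    if (all(paste0("ang", 1:6) %in% names(df))) {
      kin <- t(as.matrix(df[paste0("ang", 1:6)])); rownames(kin) <- NULL
    }
    structure(list(subject_id = tr$subject, movement = tr$movement,
                   repetition = tr$repetition, strain = strain,
                   kinematics = kin, synthetic = isTRUE(tr$synthetic),
                   provenance = unlist(tr$provenance)),
              class = "processed_trial")
  })
}
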