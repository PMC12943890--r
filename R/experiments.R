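# Evaluation protocol: stratified / LOSO / k-fold splits with a hard
# no-synthetic-in-test guarantee, the repeated four-arm ablation grid
# (base / data augment / feature augment / combined), the
# subject-identifiability control, and PCA projection of flattened features.

#' Split plan
#'
#' @param kind `"stratified_sample"`, `"loso"` or `"kfold"`.
#' @param test_fraction Test fraction for stratified sampling (default 0.25).
#' @param folds Fold count for k-fold (default 5).
#' @param seed Seed for stratification tie-breaking.
#' @return `split_plan` list.
#' @export
split_plan <- function(kind = c("stratified_sample", "loso", "kfold"),
                       test_fraction = 0.25, folds = 5L, seed = 1L) {
  kind <- match.arg(kind)
  if (test_fraction <= 0 || test_fraction >= 1)
    mt_stop("invalid_config", "test_fraction must lie in (0,1)")
  structure(list(kind = kind, test_fraction = test_fraction,
                 folds = check_count(folds, "folds", min = 2L),
                 seed = as.integer(seed)),
            class = "split_plan")
}

dataset_meta <- function(dataset) {
  data.frame(
    subject = vapply(dataset, function(x) as.character(x$subject_id %||% NA), character(1)),
    movement = vapply(dataset, function(x) as.character(x$movement), character(1)),
    synthetic = vapply(dataset, function(x) isTRUE(x$synthetic), logical(1)))
}

assert_no_synthetic_leak <- function(meta, test_idx) {
  if (any(meta$synthetic[test_idx]))
    mt_stop("synthetic_leak", "synthetic sample found in a test split")
  invisible(TRUE)
}

#' Build train/test splits
#'
#' Stratified splits preserve class proportions within the real samples;
#' LOSO yields one fold per subject with all that subject's real trials in
#' test; k-fold stratifies real samples over folds. Synthetic samples never
#' enter a test set (asserted), but always remain available for training.
#'
#' @param dataset List of labeled trials or feature tensors (fields
#'   `subject_id`, `movement`, optional `synthetic`).
#' @param plan A [split_plan()].
#' @return For `stratified_sample`: `list(train = , test = )` index vectors.
#'   Otherwise a list of such fold pairs.
#' @export
make_split <- function(dataset, plan) {
  stopifnot(inherits(plan, "split_plan"))
  meta <- dataset_meta(dataset)
  real <- which(!meta$synthetic)
  out <- with_seed(plan$seed, switch(plan$kind,
    stratified_sample = {
      # largest-remainder allocation: total test size is round(frac * n_real)
      # and per-class counts differ by at most one (ties broken by the
      # seeded shuffle below)
      classes <- unique(meta$movement[real])
      per <- vapply(classes, function(cls)
        plan$test_fraction * sum(meta$movement[real] == cls), numeric(1))
      n_take <- floor(per)
      short <- round(plan$test_fraction * length(real)) - sum(n_take)
      if (short > 0) {
        extra <- order(per - floor(per), runif(length(per)), decreasing = TRUE)
        n_take[extra[seq_len(short)]] <- n_take[extra[seq_len(short)]] + 1L
      }
      test <- integer(0)
      for (ci in seq_along(classes)) {
        idx <- real[meta$movement[real] == classes[ci]]
        test <- c(test, sample(idx, n_take[ci]))
      }
      test <- sort(test)
      list(train = setdiff(seq_along(dataset), test), test = test)
    },
    loso = {
      subjects <- unique(meta$subject[real])
      lapply(subjects, function(s) {
        test <- real[meta$subject[real] == s]
        list(train = setdiff(seq_along(dataset), test), test = test,
             subject = s)
      })
    },
    kfold = {
      if (length(real) < plan$folds)
        mt_stop("too_few_samples", "%d real samples < %d folds",
                length(real), plan$folds)
      fold_of <- integer(length(meta$movement))
      for (cls in unique(meta$movement[real])) {
        idx <- sample(real[meta$movement[real] == cls])
        fold_of[idx] <- rep_len(seq_len(plan$folds), length(idx))
      }
      lapply(seq_len(plan$folds), function(f) {
        test <- which(fold_of == f)
        list(train = setdiff(seq_along(dataset), test), test = test)
      })
    }))
  if (plan$kind == "stratified_sample") assert_no_synthetic_leak(meta, out$test)
  else for (fold in out) assert_no_synthetic_leak(meta, fold$test)
  out
}

ablation_arms <- c("base", "data_augment", "feature_augment", "mt_aim")

#' Run the four-arm ablation grid
#'
#' Arms: `base` (6 strain channels, real training data only);
#' `data_augment` (+ class-conditioned synthetic strain in the training set
#' only); `feature_augment` (+ DTFT and *real* paired kinematics channels, 18
#' channels, no synthetic data — the feature-augmentation upper bound);
#' `mt_aim` (synthetic strain + DTFT + *translated* kinematics for every
#' sample). Each arm is repeated `n_trials` times with fresh derived seeds on
#' fresh stratified splits; generators are trained per trial on that trial's
#' training split only, so no test information reaches the classifier.
#'
#' @param trials Processed real trials with paired kinematics.
#' @param classifier_cfg A [classifier_config()].
#' @param gen_kind Generator kind for both augmentations (`"cvae"` or
#'   `"diffusion"`).
#' @param gen_cfg,translator_cfg Generator configs (defaults per kind).
#' @param n_trials Number of repeated trials (default 5).
#' @param test_fraction Stratified test fraction (default 0.25).
#' @param train_fraction Fraction of the remaining real training pool to
#'   keep (default 1; lower it to emulate a deliberately small training set).
#' @param n_synth_per_class Synthetic samples per movement (default 20).
#' @param arms Subset of arms to run.
#' @param seed Master seed.
#' @return `eval_report`: per-arm accuracy mean/SD plus per-trial detail.
#' @export
run_ablation <- function(trials, classifier_cfg,
                         gen_kind = "cvae", gen_cfg = NULL,
                         translator_cfg = NULL, n_trials = 5L,
                         test_fraction = 0.25, train_fraction = 1.0,
                         n_synth_per_class = 20L, arms = ablation_arms,
                         seed = 1L) {
  arms <- match.arg(arms, ablation_arms, several.ok = TRUE)
  n_trials <- check_count(n_trials, "n_trials")
  needs_kin <- any(c("feature_augment", "mt_aim") %in% arms)
  if (needs_kin && any(vapply(trials, function(tr) is.null(tr$kinematics), logical(1))))
    mt_stop("missing_kinematics", "feature-augment arms need paired kinematics")
  acc <- matrix(NA_real_, n_trials, length(arms),
                dimnames = list(NULL, arms))
  for (tr_i in seq_len(n_trials)) {
    s <- derive_seed(seed, 11L, tr_i)
    sp <- make_split(trials, split_plan("stratified_sample",
                                        test_fraction = test_fraction,
                                        seed = s))
    train_idx <- sp$train
    if (train_fraction < 1) {
      meta <- dataset_meta(trials)
      keep <- integer(0)
      keep <- with_seed(derive_seed(s, 1L), {
        for (cls in unique(meta$movement[train_idx])) {
          idx <- train_idx[meta$movement[train_idx] == cls]
          keep <- c(keep, sample(idx, max(2L, round(train_fraction * length(idx)))))
        }
        keep
      })
      train_idx <- sort(keep)
    }
    train <- trials[train_idx]; test <- trials[sp$test]

    gen <- NULL; translator <- NULL
    if (any(c("data_augment", "mt_aim") %in% arms)) {
      gcfg <- gen_cfg %||% (if (gen_kind == "cvae") cvae_config() else diffusion_config())
      gcfg$seed <- derive_seed(s, 2L)
      gen <- train_class_conditional(gen_kind, train, gcfg)
    }
    if ("mt_aim" %in% arms) {
      tcfg <- translator_cfg %||% (if (gen_kind == "cvae") cvae_config() else diffusion_config())
      tcfg$seed <- derive_seed(s, 3L)
      translator <- train_kinematics_translator(gen_kind, train, tcfg)
    }
    synth <- if (!is.null(gen)) {
      do.call(c, lapply(gen$labels, function(mv)
        sample_synthetic_mt(gen, mv, n_synth_per_class,
                            seed = derive_seed(s, 4L, match(mv, gen$labels)))))
    }
    translate <- if (!is.null(translator)) {
      counter <- 0L
      function(strain) {
        counter <<- counter + 1L
        translate_kinematics(translator, strain, seed = derive_seed(s, 5L, counter))
      }
    }
    for (arm in arms) {
      feats <- switch(arm,
        base = list(train = featurize_trials(train, dtft = FALSE),
                    test = featurize_trials(test, dtft = FALSE)),
        data_augment = list(
          train = featurize_trials(c(train, synth), dtft = FALSE),
          test = featurize_trials(test, dtft = FALSE)),
        feature_augment = list(
          train = featurize_trials(train, dtft = TRUE, kinematics = "paired"),
          test = featurize_trials(test, dtft = TRUE, kinematics = "paired")),
        mt_aim = list(
          train = featurize_trials(c(train, synth), dtft = TRUE,
                                   kinematics = translate),
          test = featurize_trials(test, dtft = TRUE, kinematics = translate)))
      ccfg <- classifier_cfg
      ccfg$seed <- derive_seed(s, 6L, match(arm, ablation_arms))
      model <- train_classifier(feats$train, ccfg)
      acc[tr_i, arm] <- score_classifier(model, feats$test)$accuracy
    }
  }
  structure(list(
    accuracy = data.frame(arm = arms,
                          mean = colMeans(acc),
                          sd = apply(acc, 2L, sd_or_zero),
                          row.names = NULL),
    per_trial = acc, n_trials = n_trials, classifier = classifier_cfg$kind,
    gen_kind = gen_kind, seed = seed),
    class = "eval_report")
}

#' Subject-identifiability control
#'
#' Trains the CNN-LSTM head with subject identity as the label under
#' stratified k-fold cross-validation. On data without subject-specific
#' signatures the mean accuracy should sit near the `1/n_subjects` chance
#' line.
#'
#' @param tensors Real feature tensors (subject labels used as the class).
#' @param classifier_cfg Deep-head config (default small CNN-LSTM).
#' @param folds Number of CV folds (default 5).
#' @param seed Master seed.
#' @return `list(mean = , sd = , per_fold = , chance = )`.
#' @export
subject_identifiability_control <- function(tensors,
                                            classifier_cfg = classifier_config("cnn_lstm"),
                                            folds = 5L, seed = 1L) {
  subjects <- unique(vapply(tensors, function(x) as.character(x$subject_id),
                            character(1)))
  if (length(subjects) < 2L) mt_stop("single_subject", "need >= 2 subjects")
  relab <- lapply(tensors, function(x) { x$movement <- as.character(x$subject_id); x })
  fold_list <- make_split(relab, split_plan("kfold", folds = folds,
                                            seed = derive_seed(seed, 21L)))
  accs <- vapply(seq_along(fold_list), function(f) {
    cfg <- classifier_cfg
    cfg$seed <- derive_seed(seed, 22L, f)
    model <- train_classifier(relab[fold_list[[f]]$train], cfg)
    score_classifier(model, relab[fold_list[[f]]$test])$accuracy
  }, numeric(1))
  list(mean = mean(accs), sd = sd_or_zero(accs), per_fold = accs,
       chance = 1 / length(subjects))
}

#' PCA projection of flattened feature tensors
#'
#' @param tensors Feature tensors (>= 2 samples).
#' @param n_components Number of components to return (default 2).
#' @return `list(coordinates = , explained_variance_ratio = )`; coordinates
#'   carry subject and movement labels for plotting.
#' @export
pca_projection <- function(tensors, n_components = 2L) {
  if (length(tensors) < 2L) mt_stop("too_few_samples", "need >= 2 samples")
  X <- do.call(rbind, lapply(tensors, function(x) as.vector(x$values)))
  n_components <- min(check_count(n_components, "n_components"),
                      nrow(X) - 1L, ncol(X))
  pc <- prcomp(X, center = TRUE, scale. = FALSE)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  coords <- as.data.frame(pc$x[, seq_len(n_components), drop = FALSE])
  coords$subject <- vapply(tensors, function(x) as.character(x$subject_id), character(1))
  coords$movement <- vapply(tensors, function(x) as.character(x$movement), character(1))
  list(coordinates = coords,
       explained_variance_ratio = evr[seq_len(n_components)])
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> classifier=%s generator=%s, %d trials\n",
              x$classifier, x$gen_kind, x$n_trials))
  print(x$accuracy)
  invisible(x)
}
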