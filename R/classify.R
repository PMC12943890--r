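# The three classification heads: CNN-LSTM (1-D conv stack -> LSTM ->
# softmax), transformer encoder (per-step channel embeddings, mean pool,
# linear head) and gradient-boosted trees on per-channel summary statistics.

#' Classifier configuration
#'
#' Defaults encode the grid-searched working points: CNN-LSTM hidden state
#' 100 with 2 LSTM layers; transformer with 4 encoder layers and latent
#' dimension 12; boosted trees with learning rate 0.01 and maximum depth 3.
#'
#' @param kind `"cnn_lstm"`, `"transformer"` or `"gbt"`.
#' @param hidden LSTM hidden state size (cnn_lstm).
#' @param lstm_layers Number of stacked LSTM layers (cnn_lstm).
#' @param conv_channels,conv_kernel,conv_stride CNN front-end (cnn_lstm).
#' @param encoder_layers,latent_dim Transformer depth and width.
#' @param gbt_learning_rate,gbt_max_depth,gbt_rounds Boosted-tree knobs.
#' @param gbt_features `"summary"` (8 stats per channel) or `"flatten"`.
#' @param epochs,batch_size,learning_rate,patience Deep-head training budget
#'   (early stop when the training loss plateaus for `patience` epochs).
#' @param seed Training seed.
#' @return `classifier_config` list.
#' @export
classifier_config <- function(kind = c("cnn_lstm", "transformer", "gbt"),
                              hidden = 100L, lstm_layers = 2L,
                              conv_channels = c(32L, 64L), conv_kernel = 5L,
                              conv_stride = 2L,
                              encoder_layers = 4L, latent_dim = 12L,
                              gbt_learning_rate = 0.01, gbt_max_depth = 3L,
                              gbt_rounds = 200L, gbt_features = "summary",
                              epochs = 200L, batch_size = 16L,
                              learning_rate = 1e-3, patience = 20L,
                              seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(gbt_learning_rate > 0, learning_rate > 0)
  structure(list(kind = kind, hidden = check_count(hidden, "hidden"),
                 lstm_layers = check_count(lstm_layers, "lstm_layers"),
                 conv_channels = as.integer(conv_channels),
                 conv_kernel = check_count(conv_kernel, "conv_kernel"),
                 conv_stride = check_count(conv_stride, "conv_stride"),
                 encoder_layers = check_count(encoder_layers, "encoder_layers"),
                 latent_dim = check_count(latent_dim, "latent_dim"),
                 gbt_learning_rate = gbt_learning_rate,
                 gbt_max_depth = check_count(gbt_max_depth, "gbt_max_depth"),
                 gbt_rounds = check_count(gbt_rounds, "gbt_rounds"),
                 gbt_features = match.arg(gbt_features, c("summary", "flatten")),
                 epochs = check_count(epochs, "epochs"),
                 batch_size = check_count(batch_size, "batch_size"),
                 learning_rate = learning_rate,
                 patience = check_count(patience, "patience"),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

tensor_meta <- function(dataset) {
  Cs <- vapply(dataset, function(x) nrow(x$values), integer(1))
  Ts <- vapply(dataset, function(x) ncol(x$values), integer(1))
  if (length(unique(Cs)) != 1L || length(unique(Ts)) != 1L)
    mt_stop("heterogeneous_shapes", "feature tensors differ in C or T")
  list(C = Cs[1], T = Ts[1],
       labels = vapply(dataset, `[[`, character(1), "movement"))
}

# stack tensors sample-major: rows = time steps, columns = channels
stack_tensors <- function(dataset) {
  do.call(rbind, lapply(dataset, function(x) t(x$values)))
}

cnn_lstm_init <- function(C, cfg) {
  convs <- list(); c_in <- C
  for (c_out in cfg$conv_channels) {
    convs[[length(convs) + 1L]] <- conv1d_init(c_in, c_out, cfg$conv_kernel)
    c_in <- c_out
  }
  lstms <- list(); l_in <- c_in
  for (l in seq_len(cfg$lstm_layers)) {
    lstms[[l]] <- lstm_init(l_in, cfg$hidden); l_in <- cfg$hidden
  }
  list(convs = convs, lstms = lstms, head = NULL, c_last = c_in)
}

cnn_lstm_forward <- function(p, X, n, Tn, cfg) {
  h <- X
  for (cv in p$convs) {
    r <- nn_conv1d(cv, h, n, Tn, cfg$conv_stride)
    h <- ad_relu(r$out); Tn <- r$T
  }
  for (ls in p$lstms) {
    r <- nn_lstm(ls, h, n, Tn)
    h <- r$stacked
  }
  nn_dense(p$head, r$last)
}

transformer_init <- function(C, cfg, K) {
  list(emb = nn_dense_init(C, cfg$latent_dim),
       blocks = lapply(seq_len(cfg$encoder_layers),
                       function(i) attn_block_init(cfg$latent_dim)),
       head = nn_dense_init(cfg$latent_dim, K))
}

transformer_forward <- function(p, tensor_mats, cfg) {
  d <- cfg$latent_dim
  Tn <- nrow(tensor_mats[[1]])
  pos <- sinusoidal_encoding(seq_len(Tn), d)
  chunks <- split(seq_along(tensor_mats),
                  ceiling(seq_along(tensor_mats) / attn_chunk_size(Tn)))
  pooled <- lapply(chunks, function(idx) {
    b <- length(idx)
    x <- ad_add(nn_dense(p$emb, ad_const(do.call(rbind, tensor_mats[idx]))),
                ad_const(pos[rep(seq_len(Tn), b), , drop = FALSE]))
    mask <- if (b > 1L) ad_const(attn_block_mask(b, Tn))
    for (blk in p$blocks) x <- nn_attn_block(blk, x, mask)
    ad_matmul(ad_const(pool_matrix(b, Tn)), x)
  })
  nn_dense(p$head, ad_rbind(pooled))
}

#' Train a movement classifier
#'
#' @param dataset List of [assemble_features()] tensors with homogeneous
#'   channel count and length and at least two classes.
#' @param config A [classifier_config()].
#' @return An `mt_classifier`.
#' @export
train_classifier <- function(dataset, config = classifier_config()) {
  meta <- tensor_meta(dataset)
  levels <- intersect(c(mt_movements(), unique(meta$labels)), unique(meta$labels))
  if (length(levels) < 2L)
    mt_stop("single_class", "need >= 2 classes, got %d", length(levels))
  K <- length(levels)
  model <- with_seed(config$seed, switch(config$kind,
    gbt = {
      Xf <- gbt_design_matrix(dataset, config)
      gbt_fit(Xf, meta$labels, levels, config$gbt_learning_rate,
              config$gbt_max_depth, config$gbt_rounds)
    },
    cnn_lstm = train_deep(dataset, meta, levels, config),
    transformer = train_deep(dataset, meta, levels, config)))
  structure(list(kind = config$kind, config = config, model = model,
                 levels = levels, C = meta$C, T = meta$T),
            class = "mt_classifier")
}

gbt_design_matrix <- function(dataset, config) {
  if (config$gbt_features == "summary")
    do.call(rbind, lapply(dataset, function(x) summary_features(x$values)))
  else do.call(rbind, lapply(dataset, function(x) as.vector(x$values)))
}

train_deep <- function(dataset, meta, levels, cfg) {
  K <- length(levels)
  n <- length(dataset)
  Y <- one_hot(meta$labels, levels)
  if (cfg$kind == "cnn_lstm") {
    params <- cnn_lstm_init(meta$C, cfg)
    params$head <- nn_dense_init(cfg$hidden, K)
    Xall <- stack_tensors(dataset)
    fwd <- function(idx) {
      Xb <- ad_const(Xall[rep((idx - 1L) * meta$T, each = meta$T) +
                            seq_len(meta$T), , drop = FALSE])
      cnn_lstm_forward(params, Xb, length(idx), meta$T, cfg)
    }
  } else {
    params <- transformer_init(meta$C, cfg, K)
    mats <- lapply(dataset, function(x) t(x$values))
    fwd <- function(idx) transformer_forward(params, mats[idx], cfg)
  }
  plist <- collect_params(params)
  opt <- adam_init(plist, lr = cfg$learning_rate)
  best <- Inf; stall <- 0L
  loss_log <- numeric(0)
  for (ep in seq_len(cfg$epochs)) {
    tot <- 0
    for (bidx in minibatches(n, cfg$batch_size)) {
      ad_zero_grad(plist)
      loss <- ad_ce_softmax(fwd(bidx), Y[bidx, , drop = FALSE])
      ad_backward(loss)
      opt <- adam_step(opt, plist)
      tot <- tot + loss$val[1] * length(bidx)
    }
    ep_loss <- tot / n
    loss_log <- c(loss_log, ep_loss)
    if (ep_loss < best - 1e-4) { best <- ep_loss; stall <- 0L }
    else stall <- stall + 1L
    if (stall >= cfg$patience) break
  }
  list(params = params, forward = NULL, loss_log = loss_log)
}

classifier_probs <- function(object, dataset) {
  cfg <- object$config
  meta <- tensor_meta(dataset)
  if (meta$C != object$C || meta$T != object$T)
    mt_stop("shape_mismatch", "tensors are %dx%d, model expects %dx%d",
            meta$C, meta$T, object$C, object$T)
  if (object$kind == "gbt") {
    Fm <- gbt_margins(object$model, gbt_design_matrix(dataset, cfg))
    P <- exp(Fm - apply(Fm, 1L, max)); P <- P / rowSums(P)
  } else {
    n <- length(dataset)
    P <- matrix(0, n, length(object$levels))
    for (chunk in split(seq_len(n), ceiling(seq_len(n) / 32))) {
      logits <- if (cfg$kind == "cnn_lstm") {
        Xb <- ad_const(stack_tensors(dataset[chunk]))
        cnn_lstm_forward(object$model$params, Xb, length(chunk), meta$T, cfg)
      } else {
        transformer_forward(object$model$params,
                            lapply(dataset[chunk], function(x) t(x$values)), cfg)
      }
      v <- logits$val - apply(logits$val, 1L, max)
      e <- exp(v)
      P[chunk, ] <- e / rowSums(e)
    }
  }
  colnames(P) <- object$levels
  P
}

#' Predict movement labels
#'
#' @param object An `mt_classifier`.
#' @param newdata A single `feature_tensor` or a list of them.
#' @param ... Unused.
#' @return `list(label = , probs = )`; probabilities sum to 1 per sample and
#'   the label is the argmax of its row.
#' @export
predict.mt_classifier <- function(object, newdata, ...) {
  if (inherits(newdata, "feature_tensor")) newdata <- list(newdata)
  P <- classifier_probs(object, newdata)
  list(label = object$levels[max.col(P, ties.method = "first")], probs = P)
}

#' Score a classifier on a labeled test set
#'
#' @param model An `mt_classifier`.
#' @param testset Nonempty list of labeled feature tensors.
#' @return `list(accuracy = , table = , confusion = )` where `table` has
#'   one-vs-rest precision and recall per class plus a macro-average row.
#' @export
score_classifier <- function(model, testset) {
  if (length(testset) < 1L) mt_stop("empty_input", "empty test set")
  truth <- vapply(testset, `[[`, character(1), "movement")
  pred <- predict(model, testset)$label
  levels <- model$levels
  conf <- table(factor(truth, levels), factor(pred, levels))
  prec <- vapply(levels, function(l) {
    tp <- conf[l, l]; pp <- sum(conf[, l])
    if (pp == 0) NA_real_ else tp / pp
  }, numeric(1))
  rec <- vapply(levels, function(l) {
    tp <- conf[l, l]; ap <- sum(conf[l, ])
    if (ap == 0) NA_real_ else tp / ap
  }, numeric(1))
  tab <- data.frame(class = c(levels, "macro_average"),
                    precision = c(prec, mean(prec, na.rm = TRUE)),
                    recall = c(rec, mean(rec, na.rm = TRUE)),
                    row.names = NULL)
  list(accuracy = mean(pred == truth), table = tab, confusion = conf)
}

#' @export
print.mt_classifier <- function(x, ...) {
  cat(sprintf("<mt_classifier> kind=%s C=%d T=%d classes=%d\n",
              x$kind, x$C, x$T, length(x$levels)))
  invisible(x)
}
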