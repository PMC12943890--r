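# Conditional generative models in two condition modes:
#   * class_label — movement-conditioned synthesis of strain trials
#     (data augmentation);
#   * mt_series   — strain-series-conditioned synthesis of kinematics via a
#     transformer-encoder condition path (feature augmentation).
# Two model kinds share both modes: a conditional VAE and a DDPM-style
# diffusion model. A TimeGAN interface stub exists but is excluded from the
# pipeline.

#' C-VAE configuration
#'
#' @param decoder_layers Decoder depth (default 4; encoder mirrors it).
#' @param hidden_dim Hidden state width (default 12).
#' @param latent_dim Latent width (default = `hidden_dim`).
#' @param epochs,learning_rate,kl_weight,batch_size Training knobs.
#' @param seed Training seed.
#' @return `cvae_config` list.
#' @export
cvae_config <- function(decoder_layers = 4L, hidden_dim = 12L,
                        latent_dim = hidden_dim, epochs = 500L,
                        learning_rate = 1e-3, kl_weight = 1.0,
                        batch_size = 32L, seed = 1L) {
  structure(list(kind = "cvae",
                 decoder_layers = check_count(decoder_layers, "decoder_layers"),
                 hidden_dim = check_count(hidden_dim, "hidden_dim"),
                 latent_dim = check_count(latent_dim, "latent_dim"),
                 epochs = check_count(epochs, "epochs"),
                 learning_rate = learning_rate, kl_weight = kl_weight,
                 batch_size = check_count(batch_size, "batch_size"),
                 seed = as.integer(seed)),
            class = c("cvae_config", "generator_config"))
}

#' Diffusion model configuration
#'
#' @param sampling_steps Diffusion discretization / sampling steps
#'   (default 500).
#' @param hidden_dim Denoiser width (default 64).
#' @param decoder_layers Residual denoiser depth (default 12).
#' @param noise_schedule `"cosine"` or `"linear"`.
#' @param epochs,learning_rate,batch_size Training knobs.
#' @param seed Training seed.
#' @return `diffusion_config` list.
#' @export
diffusion_config <- function(sampling_steps = 500L, hidden_dim = 64L,
                             decoder_layers = 12L, noise_schedule = "cosine",
                             epochs = 200L, learning_rate = 1e-3,
                             batch_size = 32L, seed = 1L) {
  structure(list(kind = "diffusion",
                 sampling_steps = check_count(sampling_steps, "sampling_steps"),
                 hidden_dim = check_count(hidden_dim, "hidden_dim"),
                 decoder_layers = check_count(decoder_layers, "decoder_layers"),
                 noise_schedule = match.arg(noise_schedule, c("cosine", "linear")),
                 epochs = check_count(epochs, "epochs"),
                 learning_rate = learning_rate,
                 batch_size = check_count(batch_size, "batch_size"),
                 seed = as.integer(seed)),
            class = c("diffusion_config", "generator_config"))
}

flatten_series <- function(m) as.vector(m)
unflatten_series <- function(v, C = 6L) matrix(v, C, length(v) / C)

series_matrix <- function(trials, field = "strain") {
  Ts <- vapply(trials, function(tr) ncol(tr[[field]]), integer(1))
  if (length(unique(Ts)) != 1L)
    mt_stop("inconsistent_length", "trials have inconsistent T: %s",
            paste(unique(Ts), collapse = ","))
  do.call(rbind, lapply(trials, function(tr) flatten_series(tr[[field]])))
}

noise_schedule_alphas <- function(steps, kind = "cosine") {
  if (kind == "cosine") {
    s <- 0.008
    f <- function(t) cos((t / steps + s) / (1 + s) * pi / 2)^2
    ab <- f(0:steps) / f(0)
    beta <- pmin(1 - ab[-1] / ab[-(steps + 1)], 0.999)
  } else {
    beta <- seq(1e-4, 0.02, length.out = steps)
  }
  alpha <- 1 - beta
  list(beta = beta, alpha = alpha, alpha_bar = cumprod(alpha))
}

# ---- architectures ----

cvae_arch_init <- function(D, K, cfg, cond_dim = NULL) {
  # cond_dim non-NULL => series-conditioned (translator); else class labels
  H <- cfg$hidden_dim; L <- cfg$latent_dim
  depth <- cfg$decoder_layers
  list(enc = nn_mlp_init(D, H, depth),
       Eenc = if (is.null(cond_dim)) ad_param(matrix(rnorm(K * H, 0, 0.1), K, H)),
       mu = nn_dense_init(H, L), lv = nn_dense_init(H, L),
       Edec = if (is.null(cond_dim)) ad_param(matrix(rnorm(K * L, 0, 0.1), K, L)),
       # class embedding re-injected at every decoder layer: summing into the
       # latent alone lets the decoder ignore the condition
       Edech = if (is.null(cond_dim))
         lapply(seq_len(depth), function(i)
           ad_param(matrix(rnorm(K * H, 0, 0.1), K, H))),
       dec = nn_mlp_init(L, H, depth),
       out = nn_dense_init(H, D))
}

cvae_encode <- function(p, Xn, Yn) {
  h <- ad_tanh(nn_dense(p$enc[[1]], Xn))
  if (!is.null(p$Eenc) && !is.null(Yn)) h <- ad_add(h, ad_matmul(Yn, p$Eenc))
  for (l in p$enc[-1]) h <- ad_tanh(nn_dense(l, h))
  list(mu = nn_dense(p$mu, h), lv = nn_dense(p$lv, h))
}

cvae_decode <- function(p, Zn, Yn = NULL) {
  h <- Zn
  for (i in seq_along(p$dec)) {
    pre <- nn_dense(p$dec[[i]], h)
    if (!is.null(p$Edech) && !is.null(Yn))
      pre <- ad_add(pre, ad_matmul(Yn, p$Edech[[i]]))
    h <- ad_tanh(pre)
  }
  ad_tanh(nn_dense(p$out, h))
}

diffusion_arch_init <- function(D, K, cfg, cond_dim = NULL) {
  H <- cfg$hidden_dim
  list(inp = nn_dense_init(D, H),
       tden = nn_dense_init(H, H),
       Ecls = if (is.null(cond_dim)) ad_param(matrix(rnorm(K * H, 0, 0.1), K, H)),
       res = nn_mlp_init(H, H, cfg$decoder_layers),
       out = nn_dense_init(H, D))
}

diffusion_eps <- function(p, Xt, temb, cond_emb) {
  h <- ad_tanh(nn_dense(p$inp, Xt))
  h <- ad_add(h, ad_tanh(nn_dense(p$tden, temb)))
  if (!is.null(cond_emb)) h <- ad_add(h, cond_emb)
  nn_dense(p$out, nn_resmlp(p$res, h))
}

# transformer-encoder condition path: one self-attention encoder layer over
# the 6 x T strain series, mean-pooled and linearly projected into the
# generator's embedding width
cond_path_init <- function(d_model, proj_dim) {
  list(emb = nn_dense_init(6L, d_model),
       blk = attn_block_init(d_model),
       proj = nn_dense_init(d_model, proj_dim),
       d_model = d_model)
}

# token_list: per-sample T x 6 matrices (pre-transposed strain)
cond_path_embed <- function(cp, token_list, Tn) {
  pos_enc <- sinusoidal_encoding(seq_len(Tn), cp$d_model)
  chunk <- attn_chunk_size(Tn)
  chunks <- split(seq_along(token_list),
                  ceiling(seq_along(token_list) / chunk))
  ad_rbind(lapply(chunks, function(idx) {
    b <- length(idx)
    x <- ad_add(nn_dense(cp$emb, ad_const(do.call(rbind, token_list[idx]))),
                ad_const(pos_enc[rep(seq_len(Tn), b), , drop = FALSE]))
    x <- nn_attn_block(cp$blk, x,
                       mask = if (b > 1L) ad_const(attn_block_mask(b, Tn)))
    nn_dense(cp$proj, ad_matmul(ad_const(pool_matrix(b, Tn)), x))
  }))
}

new_generator <- function(kind, condition_mode, config, params, D, Tn, C,
                          labels, loss_log, extra = list()) {
  structure(c(list(kind = kind, condition_mode = condition_mode,
                   config = config, params = params, D = D, T = Tn, C = C,
                   labels = labels, seed = config$seed, loss_log = loss_log),
              extra),
            class = "mt_generator")
}

#' Train a movement-class-conditioned strain generator
#'
#' C-VAE: reconstruction + KL loss, with a learned label embedding summed
#' into both the encoder hidden state and the decoder latent. Diffusion:
#' DDPM-style epsilon-prediction MSE with the class embedding summed into the
#' denoiser's internal embedding. Training is seeded and loss-logged.
#'
#' @param kind `"cvae"`, `"diffusion"` or `"timegan"` (stub; excluded from
#'   the pipeline).
#' @param dataset List of processed trials (equal T, >= 2 movement classes).
#' @param config A [cvae_config()] or [diffusion_config()] matching `kind`.
#' @return An `mt_generator` with `condition_mode = "class_label"`.
#' @export
train_class_conditional <- function(kind = c("cvae", "diffusion", "timegan"),
                                    dataset, config = NULL) {
  kind <- match.arg(kind)
  if (kind == "timegan")
    mt_stop("timegan_stub",
            "TimeGAN is an interface stub: excluded from the pipeline for poor generative quality")
  labels <- intersect(mt_movements(),
                      unique(vapply(dataset, `[[`, character(1), "movement")))
  if (length(labels) < 2L)
    mt_stop("single_class", "need >= 2 movement classes, got %d", length(labels))
  X <- series_matrix(dataset)
  Y <- one_hot(vapply(dataset, `[[`, character(1), "movement"), labels)
  if (is.null(config)) config <- if (kind == "cvae") cvae_config() else diffusion_config()
  stopifnot(config$kind == kind)
  Tn <- ncol(dataset[[1]]$strain)
  fit <- with_seed(config$seed, {
    if (kind == "cvae") fit_cvae(X, Y, config, cond = NULL)
    else fit_diffusion(X, Y, config, cond = NULL)
  })
  new_generator(kind, "class_label", config, fit$params, ncol(X), Tn, 6L,
                labels, fit$loss_log)
}

fit_cvae <- function(X, Y, cfg, cond = NULL) {
  D <- ncol(X); K <- if (is.null(Y)) 0L else ncol(Y)
  params <- cvae_arch_init(D, K, cfg, cond_dim = if (!is.null(cond)) 1L)
  if (!is.null(cond)) params$cond <- cond_path_init(cfg$hidden_dim, cfg$latent_dim)
  plist <- collect_params(params)
  opt <- adam_init(plist, lr = cfg$learning_rate)
  n <- nrow(X)
  loss_log <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    tot <- 0
    for (bidx in minibatches(n, cfg$batch_size)) {
      ad_zero_grad(plist)
      Xb <- ad_const(X[bidx, , drop = FALSE])
      Yb <- if (!is.null(Y)) ad_const(Y[bidx, , drop = FALSE])
      enc <- cvae_encode(params, Xb, Yb)
      eps <- ad_const(matrix(rnorm(length(bidx) * cfg$latent_dim),
                             length(bidx), cfg$latent_dim))
      z <- ad_add(enc$mu, ad_mul(ad_exp(ad_scale(enc$lv, 0.5)), eps))
      # condition summed into the latent, after reparameterization
      if (!is.null(cond)) {
        z <- ad_add(z, cond_path_embed(params$cond, cond$tokens[bidx], cond$T))
      } else if (!is.null(Yb)) {
        z <- ad_add(z, ad_matmul(Yb, params$Edec))
      }
      xhat <- cvae_decode(params, z, Yb)
      target <- if (is.null(cond)) Xb$val else cond$target[bidx, , drop = FALSE]
      recon <- ad_scale(ad_sum(ad_powc(ad_sub(xhat, ad_const(target)), 2)),
                        1 / length(bidx))
      kl <- ad_scale(ad_sum(ad_scale(ad_sub(ad_add(ad_mul(enc$mu, enc$mu),
                                                   ad_exp(enc$lv)),
                                            ad_add(enc$lv, ad_const(matrix(1, 1, 1)))),
                                     0.5)),
                     cfg$kl_weight / length(bidx))
      loss <- ad_add(recon, kl)
      ad_backward(loss)
      opt <- adam_step(opt, plist)
      tot <- tot + loss$val[1] * length(bidx)
    }
    loss_log[ep] <- tot / n
  }
  list(params = params, loss_log = loss_log)
}

fit_diffusion <- function(X, Y, cfg, cond = NULL) {
  D <- ncol(X); K <- if (is.null(Y)) 0L else ncol(Y)
  params <- diffusion_arch_init(D, K, cfg, cond_dim = if (!is.null(cond)) 1L)
  if (!is.null(cond)) params$cond <- cond_path_init(cfg$hidden_dim, cfg$hidden_dim)
  plist <- collect_params(params)
  opt <- adam_init(plist, lr = cfg$learning_rate)
  sched <- noise_schedule_alphas(cfg$sampling_steps, cfg$noise_schedule)
  n <- nrow(X); H <- cfg$hidden_dim
  loss_log <- numeric(cfg$epochs)
  for (ep in seq_len(cfg$epochs)) {
    tot <- 0
    for (bidx in minibatches(n, cfg$batch_size)) {
      ad_zero_grad(plist)
      nb <- length(bidx)
      tt <- sample.int(cfg$sampling_steps, nb, replace = TRUE)
      ab <- sched$alpha_bar[tt]
      eps <- matrix(rnorm(nb * D), nb, D)
      Xt <- sqrt(ab) * X[bidx, , drop = FALSE] + sqrt(1 - ab) * eps
      temb <- ad_const(sinusoidal_encoding(tt / cfg$sampling_steps, H))
      cemb <- if (!is.null(cond)) cond_path_embed(params$cond, cond$tokens[bidx], cond$T)
              else if (!is.null(Y)) ad_matmul(ad_const(Y[bidx, , drop = FALSE]), params$Ecls)
      loss <- ad_mse(diffusion_eps(params, ad_const(Xt), temb, cemb), eps)
      ad_backward(loss)
      opt <- adam_step(opt, plist)
      tot <- tot + loss$val[1] * nb
    }
    loss_log[ep] <- tot / n
  }
  list(params = params, loss_log = loss_log)
}

diffusion_sample <- function(model, n, cemb_val) {
  cfg <- model$config
  sched <- noise_schedule_alphas(cfg$sampling_steps, cfg$noise_schedule)
  D <- model$D; H <- cfg$hidden_dim
  x <- matrix(rnorm(n * D), n, D)
  cemb <- if (is.null(cemb_val)) NULL else ad_const(cemb_val)
  for (t in rev(seq_len(cfg$sampling_steps))) {
    temb <- ad_const(sinusoidal_encoding(rep(t / cfg$sampling_steps, n), H))
    eh <- diffusion_eps(model$params, ad_const(x), temb, cemb)$val
    ab <- sched$alpha_bar[t]
    ab_prev <- if (t > 1L) sched$alpha_bar[t - 1L] else 1
    x0 <- pmin(pmax((x - sqrt(1 - ab) * eh) / sqrt(ab), -1), 1)
    mu <- (sqrt(ab_prev) * sched$beta[t] / (1 - ab)) * x0 +
      (sqrt(sched$alpha[t]) * (1 - ab_prev) / (1 - ab)) * x
    if (t > 1L) {
      sigma <- sqrt((1 - ab_prev) / (1 - ab) * sched$beta[t])
      x <- mu + sigma * matrix(rnorm(n * D), n, D)
    } else x <- mu
  }
  pmin(pmax(x, -1), 1)
}

#' Sample synthetic strain trials from a class-conditional generator
#'
#' @param model `mt_generator` with `condition_mode = "class_label"`.
#' @param movement Conditioning movement label.
#' @param n Number of samples (0 gives an empty list).
#' @param seed Sampling seed.
#' @return List of processed-trial-like objects (`strain`, `movement`,
#'   `synthetic = TRUE`), values in `[-1, 1]`.
#' @export
sample_synthetic_mt <- function(model, movement, n, seed = 1L) {
  stopifnot(inherits(model, "mt_generator"))
  if (model$condition_mode != "class_label")
    mt_stop("wrong_condition_mode", "model is not class-conditional")
  if (!movement %in% model$labels)
    mt_stop("unknown_movement", "movement '%s' not in training label set", movement)
  n <- check_count(n, "n", min = 0L)
  if (n == 0L) return(list())
  Y <- one_hot(rep(movement, n), model$labels)
  Xs <- with_seed(seed, {
    if (model$kind == "cvae") {
      z <- ad_const(matrix(rnorm(n * model$config$latent_dim),
                           n, model$config$latent_dim))
      z <- ad_add(z, ad_matmul(ad_const(Y), model$params$Edec))
      cvae_decode(model$params, z, ad_const(Y))$val
    } else {
      diffusion_sample(model, n,
                       (Y %*% model$params$Ecls$val))
    }
  })
  lapply(seq_len(n), function(i) {
    structure(list(subject_id = "synthetic", movement = movement,
                   repetition = i,
                   strain = unflatten_series(Xs[i, ], model$C),
                   kinematics = NULL, synthetic = TRUE,
                   provenance = sprintf("sampled:%s", model$kind)),
              class = "processed_trial")
  })
}

#' Train a strain-conditioned kinematics translator
#'
#' The condition path is a single self-attention encoder layer over the
#' `6 x T` strain series followed by a linear projection; the pooled strain
#' embedding is summed (not concatenated) with the kinematics latent (C-VAE)
#' or with the per-step denoising embedding (diffusion). The supervised loss
#' is computed against the ground-truth angle trajectories. Hyperparameters
#' are shared with the class-conditional generator of the same kind.
#'
#' @param kind `"cvae"` or `"diffusion"`.
#' @param paired List of processed trials with both `strain` and `kinematics`
#'   present and aligned.
#' @param config Generator config of matching kind.
#' @return An `mt_generator` with `condition_mode = "mt_series"`.
#' @export
train_kinematics_translator <- function(kind = c("cvae", "diffusion"), paired,
                                        config = NULL) {
  kind <- match.arg(kind)
  bad <- vapply(paired, function(tr)
    is.null(tr$kinematics) || ncol(tr$kinematics) != ncol(tr$strain), logical(1))
  if (any(bad))
    mt_stop("unpaired_trial", "%d trial(s) lack aligned kinematics", sum(bad))
  if (is.null(config)) config <- if (kind == "cvae") cvae_config() else diffusion_config()
  stopifnot(config$kind == kind)
  Xkin <- series_matrix(paired, "kinematics")
  Tn <- ncol(paired[[1]]$strain)
  cond <- list(tokens = lapply(paired, function(tr) t(tr$strain)), T = Tn,
               target = Xkin)
  fit <- with_seed(config$seed, {
    if (kind == "cvae") fit_cvae(Xkin, NULL, config, cond = cond)
    else fit_diffusion(Xkin, NULL, config, cond = cond)
  })
  new_generator(kind, "mt_series", config, fit$params, ncol(Xkin), Tn, 6L,
                NULL, fit$loss_log)
}

#' Generate kinematics conditioned on a strain series
#'
#' Draws a standard-Gaussian latent, sums it with the strain embedding from
#' the transformer condition path, and decodes to a `6 x T` angle series
#' (C-VAE), or runs ancestral diffusion sampling with the strain embedding
#' summed into the denoiser (diffusion).
#'
#' @param model `mt_generator` with `condition_mode = "mt_series"`.
#' @param strain `6 x T` matrix matching the training T.
#' @param seed Sampling seed.
#' @return `6 x T` matrix of generated (normalized) kinematics.
#' @export
translate_kinematics <- function(model, strain, seed = 1L) {
  stopifnot(inherits(model, "mt_generator"))
  if (model$condition_mode != "mt_series")
    mt_stop("wrong_condition_mode", "model is not strain-conditioned")
  if (!is.matrix(strain) || nrow(strain) != 6L || ncol(strain) != model$T)
    mt_stop("shape_mismatch", "strain must be 6 x %d", model$T)
  emb <- cond_path_embed(model$params$cond, list(t(strain)), model$T)$val
  v <- with_seed(seed, {
    if (model$kind == "cvae") {
      z <- matrix(rnorm(model$config$latent_dim), 1L)
      cvae_decode(model$params, ad_const(z + emb))$val
    } else {
      diffusion_sample(model, 1L, emb)
    }
  })
  unflatten_series(v[1, ], model$C)
}

#' @export
print.mt_generator <- function(x, ...) {
  cat(sprintf("<mt_generator> kind=%s condition=%s D=%d T=%d (seed %d)\n",
              x$kind, x$condition_mode, x$D, x$T, x$seed))
  invisible(x)
}
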