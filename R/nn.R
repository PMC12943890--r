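# Layer library on top of the autodiff engine: dense stacks, 1-D convolution
# (im2col), LSTM, single-head transformer encoder blocks, sinusoidal
# positional/time encodings. Initialization is Glorot; callers seed the RNG.

nn_dense_init <- function(n_in, n_out) {
  s <- sqrt(2 / (n_in + n_out))
  list(W = ad_param(matrix(rnorm(n_in * n_out, 0, s), n_in, n_out)),
       b = ad_param(matrix(0, 1L, n_out)))
}

nn_dense <- function(p, x) ad_add(ad_matmul(x, p$W), p$b)

# stack of `depth` hidden layers of width `hidden` with tanh activations
nn_mlp_init <- function(n_in, hidden, depth) {
  dims <- c(n_in, rep(hidden, depth))
  lapply(seq_len(depth), function(i) nn_dense_init(dims[i], dims[i + 1L]))
}

nn_mlp <- function(layers, x, act = ad_tanh) {
  for (p in layers) x <- act(nn_dense(p, x))
  x
}

# residual stack of equal-width layers: h <- h + act(dense(h))
nn_resmlp <- function(layers, x, act = ad_tanh) {
  for (p in layers) x <- ad_add(x, act(nn_dense(p, x)))
  x
}

# ---- 1-D convolution over stacked sample-major sequences ----
# X is an (n*T) x C node, rows time-major within each sample. Valid padding.

conv1d_init <- function(c_in, c_out, kernel) {
  s <- sqrt(2 / (kernel * c_in + c_out))
  list(W = ad_param(matrix(rnorm(kernel * c_in * c_out, 0, s),
                           kernel * c_in, c_out)),
       b = ad_param(matrix(0, 1L, c_out)), kernel = kernel)
}

conv1d_out_len <- function(T, kernel, stride) (T - kernel) %/% stride + 1L

nn_conv1d <- function(p, x, n, T, stride = 2L) {
  k <- p$kernel
  T_out <- conv1d_out_len(T, k, stride)
  if (T_out < 1L) mt_stop("too_short", "sequence length %d < kernel %d", T, k)
  base <- as.vector(outer((seq_len(T_out) - 1L) * stride,
                          (seq_len(n) - 1L) * T, `+`))  # 0-based patch starts
  patches <- ad_cbind(lapply(seq_len(k) - 1L,
                             function(o) ad_rows(x, base + o + 1L)))
  list(out = ad_add(ad_matmul(patches, p$W), p$b), T = T_out)
}

# ---- LSTM over stacked sequences ----

lstm_init <- function(n_in, hidden) {
  s <- sqrt(1 / hidden)
  b0 <- matrix(0, 1L, 4L * hidden)
  b0[1, (hidden + 1L):(2L * hidden)] <- 1  # forget-gate bias
  list(W = ad_param(matrix(rnorm((n_in + hidden) * 4L * hidden, 0, s),
                           n_in + hidden, 4L * hidden)),
       b = ad_param(b0), hidden = hidden)
}

# x: (n*T) x C node; returns final hidden state (n x hidden) and the stacked
# per-step hidden states for layer chaining
nn_lstm <- function(p, x, n, T) {
  H <- p$hidden
  h <- ad_const(matrix(0, n, H)); cc <- ad_const(matrix(0, n, H))
  hs <- vector("list", T)
  for (t in seq_len(T)) {
    xt <- ad_rows(x, (seq_len(n) - 1L) * T + t)
    z <- ad_add(ad_matmul(ad_cbind(list(xt, h)), p$W), p$b)
    i <- ad_sigmoid(ad_cols(z, 1:H))
    f <- ad_sigmoid(ad_cols(z, (H + 1L):(2L * H)))
    o <- ad_sigmoid(ad_cols(z, (2L * H + 1L):(3L * H)))
    g <- ad_tanh(ad_cols(z, (3L * H + 1L):(4L * H)))
    cc <- ad_add(ad_mul(f, cc), ad_mul(i, g))
    h <- ad_mul(o, ad_tanh(cc))
    hs[[t]] <- h
  }
  # restack time-major within sample for the next layer
  stacked <- ad_rbind(hs)                       # (T*n) x H, step-major
  perm <- as.vector(t(matrix(seq_len(n * T), n, T)))  # -> sample-major
  list(last = h, stacked = ad_rows(stacked, perm))
}

# ---- single-head transformer encoder block (post-layernorm) ----

attn_block_init <- function(d_model, d_ff = 4L * d_model) {
  s <- sqrt(1 / d_model)
  pm <- function(nr, nc) ad_param(matrix(rnorm(nr * nc, 0, s), nr, nc))
  list(Wq = pm(d_model, d_model), Wk = pm(d_model, d_model),
       Wv = pm(d_model, d_model), Wo = pm(d_model, d_model),
       ff1 = nn_dense_init(d_model, d_ff), ff2 = nn_dense_init(d_ff, d_model),
       g1 = ad_param(matrix(1, 1L, d_model)), b1 = ad_param(matrix(0, 1L, d_model)),
       g2 = ad_param(matrix(1, 1L, d_model)), b2 = ad_param(matrix(0, 1L, d_model)),
       d_model = d_model)
}

# x: T x d_model node for ONE sample, or a stacked (n*T) x d_model batch with
# a block-diagonal additive mask keeping attention within each sample
nn_attn_block <- function(p, x, mask = NULL) {
  q <- ad_matmul(x, p$Wq); k <- ad_matmul(x, p$Wk); v <- ad_matmul(x, p$Wv)
  sc <- ad_scale(ad_matmul(q, ad_t(k)), 1 / sqrt(p$d_model))
  if (!is.null(mask)) sc <- ad_add(sc, mask)
  a <- ad_softmax_rows(sc)
  x1 <- ad_layernorm(ad_add(x, ad_matmul(ad_matmul(a, v), p$Wo)), p$g1, p$b1)
  ff <- nn_dense(p$ff2, ad_relu(nn_dense(p$ff1, x1)))
  ad_layernorm(ad_add(x1, ff), p$g2, p$b2)
}

# additive block-diagonal attention mask for n stacked sequences of length T
attn_block_mask <- function(n, T) {
  m <- matrix(-1e9, n * T, n * T)
  for (s in seq_len(n)) {
    idx <- ((s - 1L) * T + 1L):(s * T)
    m[idx, idx] <- 0
  }
  m
}

# per-sample mean pooling matrix over stacked sequences: (n x n*T)
pool_matrix <- function(n, T) {
  m <- matrix(0, n, n * T)
  for (s in seq_len(n)) m[s, ((s - 1L) * T + 1L):(s * T)] <- 1 / T
  m
}

# samples per attention chunk: batching divides the per-node bookkeeping
# overhead by the chunk size but wastes compute on the off-diagonal score
# blocks, so keep chunks modest and cap the (chunk*T)^2 score matrix
attn_chunk_size <- function(T, budget = 1024L) max(1L, min(6L, budget %/% T))

# fixed sinusoidal encoding (positions x d) — also used for diffusion time
sinusoidal_encoding <- function(positions, d) {
  i <- seq_len(d)
  ang <- outer(positions, 1 / 10000^((2 * (ceiling(i / 2) - 1)) / d))
  enc <- ang
  enc[, i %% 2L == 1L] <- sin(ang[, i %% 2L == 1L, drop = FALSE])
  enc[, i %% 2L == 0L] <- cos(ang[, i %% 2L == 0L, drop = FALSE])
  enc
}

one_hot <- function(labels, levels) {
  m <- matrix(0, length(labels), length(levels),
              dimnames = list(NULL, levels))
  m[cbind(seq_along(labels), match(labels, levels))] <- 1
  m
}

# seeded minibatch index generator
minibatches <- function(n, batch_size) {
  idx <- sample.int(n)
  split(idx, ceiling(seq_along(idx) / batch_size))
}
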