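# Minimal reverse-mode automatic differentiation on matrices.
#
# Every neural component in the package (C-VAE, diffusion denoiser,
# transformer-encoder condition path, CNN-LSTM and transformer classifiers)
# is written as a forward composition of the node operations below; gradients
# come from one reverse sweep over the recorded graph. Nodes are environments
# holding a value, an accumulated gradient, parent references and a backward
# closure; a monotone creation index gives a valid topological order because
# parameters are created before any node that consumes them.

ad_state <- new.env(parent = emptyenv())
ad_state$counter <- 0

ad_node <- function(val, parents = list(), backward = NULL, requires = NULL) {
  if (is.null(dim(val))) val <- matrix(val, nrow = 1L)
  if (is.null(requires))
    requires <- any(vapply(parents, function(p) p$requires, logical(1)))
  e <- new.env(parent = emptyenv())
  e$val <- val; e$grad <- NULL
  e$parents <- parents; e$backward <- backward
  e$requires <- requires
  ad_state$counter <- ad_state$counter + 1
  e$idx <- ad_state$counter
  class(e) <- "ad_node"
  e
}

ad_const <- function(x) ad_node(x, requires = FALSE)
ad_param <- function(x) ad_node(x, requires = TRUE)

is_ad <- function(x) inherits(x, "ad_node")
as_ad <- function(x) if (is_ad(x)) x else ad_const(x)

# reduce a full-size gradient back to a broadcast operand's shape
unbroadcast <- function(g, d) {
  if (identical(dim(g), d)) return(g)
  if (d[1] == 1L && d[2] == ncol(g)) return(matrix(colSums(g), 1L))
  if (d[2] == 1L && d[1] == nrow(g)) return(matrix(rowSums(g), ncol = 1L))
  if (d[1] == 1L && d[2] == 1L) return(matrix(sum(g), 1L, 1L))
  stop("unbroadcastable gradient shape")
}

# expand an operand to the target shape (row vector, column vector or scalar)
bc_expand <- function(v, dr, dc) {
  if (nrow(v) == dr && ncol(v) == dc) return(v)
  if (nrow(v) == 1L && ncol(v) == dc) return(matrix(v, dr, dc, byrow = TRUE))
  if (ncol(v) == 1L && nrow(v) == dr) return(matrix(v, dr, dc))
  if (length(v) == 1L) return(matrix(v[1], dr, dc))
  stop("non-conformable broadcast")
}

bc_dims <- function(a, b) {
  c(max(nrow(a$val), nrow(b$val)), max(ncol(a$val), ncol(b$val)))
}

ad_add <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  d <- bc_dims(a, b)
  ad_node(bc_expand(a$val, d[1], d[2]) + bc_expand(b$val, d[1], d[2]),
          list(a, b),
          function(g) list(unbroadcast(g, dim(a$val)), unbroadcast(g, dim(b$val))))
}

ad_sub <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  d <- bc_dims(a, b)
  ad_node(bc_expand(a$val, d[1], d[2]) - bc_expand(b$val, d[1], d[2]),
          list(a, b),
          function(g) list(unbroadcast(g, dim(a$val)), unbroadcast(-g, dim(b$val))))
}

ad_mul <- function(a, b) {
  a <- as_ad(a); b <- as_ad(b)
  d <- bc_dims(a, b)
  av <- bc_expand(a$val, d[1], d[2]); bv <- bc_expand(b$val, d[1], d[2])
  ad_node(av * bv, list(a, b),
          function(g) list(unbroadcast(g * bv, dim(a$val)),
                           unbroadcast(g * av, dim(b$val))))
}

ad_scale <- function(a, k) {
  ad_node(a$val * k, list(a), function(g) list(g * k))
}

ad_matmul <- function(a, b) {
  ad_node(a$val %*% b$val, list(a, b),
          function(g) list(g %*% t(b$val), t(a$val) %*% g))
}

ad_t <- function(a) ad_node(t(a$val), list(a), function(g) list(t(g)))

ad_tanh <- function(a) {
  v <- tanh(a$val)
  ad_node(v, list(a), function(g) list(g * (1 - v * v)))
}

ad_sigmoid <- function(a) {
  v <- 1 / (1 + exp(-a$val))
  ad_node(v, list(a), function(g) list(g * v * (1 - v)))
}

ad_relu <- function(a) {
  v <- a$val; m <- v > 0; v[!m] <- 0
  ad_node(v, list(a), function(g) list(g * m))
}

ad_exp <- function(a) {
  v <- exp(a$val)
  ad_node(v, list(a), function(g) list(g * v))
}

ad_powc <- function(a, p) {
  v <- a$val^p
  ad_node(v, list(a), function(g) list(g * p * a$val^(p - 1)))
}

ad_sum <- function(a) {
  dm <- dim(a$val)
  ad_node(matrix(sum(a$val), 1L, 1L), list(a),
          function(g) list(matrix(g[1], dm[1], dm[2])))
}

ad_mean <- function(a) ad_scale(ad_sum(a), 1 / length(a$val))

ad_rowmeans <- function(a) {
  nc <- ncol(a$val)
  ad_node(matrix(rowMeans(a$val), ncol = 1L), list(a),
          function(g) list(matrix(g, nrow(a$val), nc) / nc))
}

# gather rows (duplicates allowed); backward scatter-adds
ad_rows <- function(a, idx) {
  dm <- dim(a$val)
  ad_node(a$val[idx, , drop = FALSE], list(a), function(g) {
    z <- matrix(0, dm[1], dm[2])
    agg <- rowsum(g, group = idx)
    z[as.integer(rownames(agg)), ] <- agg
    list(z)
  })
}

ad_cols <- function(a, idx) {
  dm <- dim(a$val)
  ad_node(a$val[, idx, drop = FALSE], list(a), function(g) {
    z <- matrix(0, dm[1], dm[2])
    agg <- t(rowsum(t(g), group = idx))
    z[, as.integer(colnames(agg))] <- agg
    list(z)
  })
}

ad_rbind <- function(nodes) {
  ns <- vapply(nodes, function(x) nrow(x$val), integer(1))
  ad_node(do.call(rbind, lapply(nodes, `[[`, "val")), nodes, function(g) {
    ends <- cumsum(ns); starts <- c(1L, head(ends, -1L) + 1L)
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

ad_cbind <- function(nodes) {
  ns <- vapply(nodes, function(x) ncol(x$val), integer(1))
  ad_node(do.call(cbind, lapply(nodes, `[[`, "val")), nodes, function(g) {
    ends <- cumsum(ns); starts <- c(1L, head(ends, -1L) + 1L)
    lapply(seq_along(nodes), function(i) g[, starts[i]:ends[i], drop = FALSE])
  })
}

rowmax <- function(v) v[cbind(seq_len(nrow(v)), max.col(v, ties.method = "first"))]

ad_softmax_rows <- function(a) {
  e <- exp(a$val - rowmax(a$val))  # length-n vector recycles down columns
  s <- e / rowSums(e)
  ad_node(s, list(a),
          function(g) list(s * (g - rowSums(g * s))))
}

# mean squared error against a constant target
ad_mse <- function(pred, target) {
  tv <- if (is_ad(target)) target$val else target
  d <- pred$val - tv; n <- length(d)
  ad_node(matrix(mean(d * d), 1L, 1L), list(pred),
          function(g) list(g[1] * 2 * d / n))
}

# softmax cross-entropy against constant one-hot rows; mean over rows
ad_ce_softmax <- function(logits, onehot) {
  e <- exp(logits$val - rowmax(logits$val))
  p <- e / rowSums(e)
  n <- nrow(p)
  nll <- -mean(rowSums(onehot * log(pmax(p, 1e-12))))
  ad_node(matrix(nll, 1L, 1L), list(logits),
          function(g) list(g[1] * (p - onehot) / n))
}

ad_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  mu <- ad_rowmeans(x)
  xc <- ad_sub(x, mu)
  vr <- ad_rowmeans(ad_mul(xc, xc))
  inv <- ad_powc(ad_add(vr, ad_const(matrix(eps, 1, 1))), -0.5)
  ad_add(ad_mul(ad_mul(xc, inv), gamma), beta)
}

# reverse sweep from a scalar loss node
ad_backward <- function(loss) {
  stopifnot(length(loss$val) == 1L)
  # collect reachable grad-requiring nodes
  seen <- new.env(parent = emptyenv())
  stack <- list(loss); nodes <- list()
  while (length(stack) > 0L) {
    nd <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
    key <- as.character(nd$idx)
    if (!is.null(seen[[key]]) || !nd$requires) next
    seen[[key]] <- TRUE
    nodes[[length(nodes) + 1L]] <- nd
    for (p in nd$parents) if (p$requires) stack[[length(stack) + 1L]] <- p
  }
  ord <- order(vapply(nodes, `[[`, numeric(1), "idx"), decreasing = TRUE)
  loss$grad <- matrix(1, 1L, 1L)
  for (nd in nodes[ord]) {
    if (is.null(nd$grad) || is.null(nd$backward)) next
    gs <- nd$backward(nd$grad)
    for (k in seq_along(nd$parents)) {
      p <- nd$parents[[k]]
      if (!p$requires) next
      if (is.null(p$grad)) p$grad <- gs[[k]] else p$grad <- p$grad + gs[[k]]
    }
  }
  invisible(loss)
}

ad_zero_grad <- function(params) {
  for (p in params) p$grad <- NULL
  invisible(params)
}

# ---- Adam optimizer over a flat list of parameter nodes ----

adam_init <- function(params, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
       m = lapply(params, function(p) p$val * 0),
       v = lapply(params, function(p) p$val * 0))
}

adam_step <- function(opt, params) {
  opt$t <- opt$t + 1L
  b1 <- opt$beta1; b2 <- opt$beta2
  for (i in seq_along(params)) {
    g <- params[[i]]$grad
    if (is.null(g)) next
    opt$m[[i]] <- b1 * opt$m[[i]] + (1 - b1) * g
    opt$v[[i]] <- b2 * opt$v[[i]] + (1 - b2) * g * g
    mhat <- opt$m[[i]] / (1 - b1^opt$t)
    vhat <- opt$v[[i]] / (1 - b2^opt$t)
    params[[i]]$val <- params[[i]]$val - opt$lr * mhat / (sqrt(vhat) + opt$eps)
  }
  opt
}

# collect every ad_param node nested anywhere in a parameter structure
collect_params <- function(x) {
  if (is_ad(x)) return(if (x$requires) list(x) else list())
  if (is.list(x)) return(do.call(c, lapply(x, collect_params)))
  list()
}

# snapshot / restore parameter values (for checkpointing and serialization)
params_values <- function(x) lapply(collect_params(x), `[[`, "val")
params_restore <- function(x, vals) {
  ps <- collect_params(x)
  stopifnot(length(ps) == length(vals))
  for (i in seq_along(ps)) ps[[i]]$val <- matrix(as.numeric(vals[[i]]),
                                                nrow(ps[[i]]$val),
                                                ncol(ps[[i]]$val))
  invisible(x)
}
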