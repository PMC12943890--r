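# Multinomial gradient boosting with depth-limited regression trees,
# standing in for an XGBoost-style head. One tree per class per round fits
# the softmax residual y - p; leaf values use the classic multinomial
# gamma step ((K-1)/K) * sum(r) / sum(|r| (1 - |r|)).

gbt_best_split <- function(x, r, min_leaf) {
  o <- order(x)
  xs <- x[o]; rs <- r[o]
  n <- length(x)
  cs <- cumsum(rs); tot <- cs[n]
  i <- seq_len(n - 1L)
  valid <- xs[i] < xs[i + 1L] & i >= min_leaf & (n - i) >= min_leaf
  if (!any(valid)) return(NULL)
  gain <- cs[i]^2 / i + (tot - cs[i])^2 / (n - i)
  gain[!valid] <- -Inf
  j <- which.max(gain)
  list(threshold = (xs[j] + xs[j + 1L]) / 2, gain = gain[j] - tot^2 / n)
}

gbt_leaf_value <- function(r, K) {
  den <- sum(abs(r) * (1 - abs(r)))
  if (den < 1e-10) return(0)
  ((K - 1) / K) * sum(r) / den
}

gbt_grow_tree <- function(X, r, K, depth, min_leaf = 2L) {
  if (depth == 0L || nrow(X) < 2L * min_leaf || var(r) < 1e-12)
    return(list(leaf = TRUE, value = gbt_leaf_value(r, K)))
  best <- NULL; best_f <- NA_integer_
  for (f in seq_len(ncol(X))) {
    sp <- gbt_best_split(X[, f], r, min_leaf)
    if (!is.null(sp) && (is.null(best) || sp$gain > best$gain)) {
      best <- sp; best_f <- f
    }
  }
  if (is.null(best) || best$gain <= 1e-12)
    return(list(leaf = TRUE, value = gbt_leaf_value(r, K)))
  l <- X[, best_f] <= best$threshold
  list(leaf = FALSE, feature = best_f, threshold = best$threshold,
       left = gbt_grow_tree(X[l, , drop = FALSE], r[l], K, depth - 1L, min_leaf),
       right = gbt_grow_tree(X[!l, , drop = FALSE], r[!l], K, depth - 1L, min_leaf))
}

gbt_tree_predict <- function(tree, X) {
  out <- numeric(nrow(X))
  rec <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) { out[idx] <<- node$value; return() }
    l <- X[idx, node$feature] <= node$threshold
    rec(node$left, idx[l]); rec(node$right, idx[!l])
  }
  rec(tree, seq_len(nrow(X)))
  out
}

gbt_fit <- function(X, y, levels, learning_rate = 0.01, max_depth = 3L,
                    n_rounds = 200L) {
  K <- length(levels)
  Y <- one_hot(y, levels)
  Fm <- matrix(0, nrow(X), K)
  trees <- vector("list", n_rounds)
  for (m in seq_len(n_rounds)) {
    P <- exp(Fm - apply(Fm, 1L, max)); P <- P / rowSums(P)
    round_trees <- vector("list", K)
    for (k in seq_len(K)) {
      r <- Y[, k] - P[, k]
      tr <- gbt_grow_tree(X, r, K, max_depth)
      Fm[, k] <- Fm[, k] + learning_rate * gbt_tree_predict(tr, X)
      round_trees[[k]] <- tr
    }
    trees[[m]] <- round_trees
  }
  list(trees = trees, levels = levels, learning_rate = learning_rate)
}

gbt_margins <- function(fit, X) {
  K <- length(fit$levels)
  Fm <- matrix(0, nrow(X), K)
  for (round_trees in fit$trees)
    for (k in seq_len(K))
      Fm[, k] <- Fm[, k] + fit$learning_rate * gbt_tree_predict(round_trees[[k]], X)
  Fm
}

# 8 summary statistics per channel: mean, SD, min, max, median, IQR,
# normalized argmax time, dominant non-DC frequency bin (normalized)
summary_features <- function(values) {
  Tn <- ncol(values)
  as.vector(t(apply(values, 1L, function(x) {
    sp <- Mod(fft(x))[2:max(2L, floor(Tn / 2))]
    c(mean(x), sd(x), min(x), max(x), median(x),
      quantile(x, 0.75, names = FALSE) - quantile(x, 0.25, names = FALSE),
      which.max(x) / Tn, which.max(sp) / Tn)
  })))
}
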