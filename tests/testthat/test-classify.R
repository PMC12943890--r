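small_heads <- function(kind, seed = 6L, epochs = 30L)
  classifier_config(kind, hidden = 24L, lstm_layers = 1L, encoder_layers = 2L,
                    epochs = epochs, gbt_rounds = 60L, seed = seed)

clean_feats <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      trials <- preprocess_trials(make_cohort(clean_cohort_config(n_subjects = 3L,
                                                                  seed = 61L)))$trials
      cache <<- featurize_trials(trials, dtft = FALSE)
    }
    cache
  }
})

test_that("every head separates the clean zero-overlap cohort in-sample", {
  feats <- clean_feats()
  for (kind in c("gbt", "cnn_lstm")) {
    m <- train_classifier(feats, small_heads(kind))
    expect_equal(score_classifier(m, feats)$accuracy, 1.0)
  }
})

test_that("training is deterministic and rejects degenerate inputs", {
  feats <- clean_feats()
  m1 <- train_classifier(feats, small_heads("cnn_lstm", epochs = 8L))
  m2 <- train_classifier(feats, small_heads("cnn_lstm", epochs = 8L))
  expect_identical(predict(m1, feats)$label, predict(m2, feats)$label)
  expect_error(train_classifier(Filter(function(f) f$movement == "flexion", feats),
                                small_heads("gbt")),
               class = "single_class")
  mixed <- feats
  mixed[[1]]$values <- mixed[[1]]$values[, 1:10]
  expect_error(train_classifier(mixed, small_heads("gbt")),
               class = "heterogeneous_shapes")
})

test_that("prediction contracts hold: simplex, argmax, batch consistency", {
  feats <- clean_feats()
  m <- train_classifier(feats, small_heads("gbt"))
  p <- predict(m, feats[1:8])
  expect_equal(rowSums(p$probs), rep(1, 8), tolerance = 1e-6)
  expect_identical(p$label,
                   m$levels[apply(p$probs, 1L, which.max)])
  singles <- vapply(feats[1:8], function(f) predict(m, f)$label, character(1))
  expect_identical(p$label, singles)
  bad <- feats[[1]]; bad$values <- bad$values[1:3, , drop = FALSE]
  expect_error(predict(m, bad), class = "shape_mismatch")

  mt <- train_classifier(feats, small_heads("transformer", epochs = 4L))
  pt <- predict(mt, feats[1:4])
  expect_equal(rowSums(pt$probs), rep(1, 4), tolerance = 1e-6)
})

test_that("score_classifier computes accuracy, PR table and confusion marginals", {
  feats <- clean_feats()
  m <- train_classifier(feats, small_heads("gbt"))
  sc <- score_classifier(m, feats)
  expect_equal(sc$accuracy, 1.0)
  expect_true(all(sc$table$precision == 1, na.rm = TRUE))
  truth <- vapply(feats, `[[`, character(1), "movement")
  expect_equal(as.vector(rowSums(sc$confusion)),
               as.vector(table(factor(truth, m$levels))))
  macro <- sc$table[sc$table$class == "macro_average", ]
  percls <- sc$table[sc$table$class != "macro_average", ]
  expect_equal(macro$precision, mean(percls$precision, na.rm = TRUE))
  expect_error(score_classifier(m, list()), class = "empty_input")
})

test_that("label-destroying shuffle drives held-out accuracy to chance", {
  trials <- preprocess_trials(make_cohort(small_cohort_config(n_subjects = 4L,
                                                              seed = 63L)))$trials
  feats <- featurize_trials(trials, dtft = FALSE)
  set.seed(64)
  shuffled <- feats
  perm <- sample(seq_along(feats))
  for (i in seq_along(feats)) shuffled[[i]]$values <- feats[[perm[i]]]$values
  sp <- make_split(shuffled, split_plan("stratified_sample", seed = 65))
  m <- train_classifier(shuffled[sp$train], small_heads("gbt"))
  acc <- score_classifier(m, shuffled[sp$test])$accuracy
  expect_lt(acc, 1 / 6 + 0.35)  # chance 1/6 plus generous sampling slack
})
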