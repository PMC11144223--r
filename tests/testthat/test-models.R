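# Separable toy windows: class 1 carries a mid-window amplitude collapse
# of a 0.25 Hz carrier, the signature the event detector must learn.
toy_windows <- function(n, samples = 480, rate = 16, seed = 1) {
  set.seed(seed)
  X <- matrix(0, n, samples)
  y <- rep(0:1, length.out = n)
  tt <- (seq_len(samples) - 1) / rate
  for (i in seq_len(n)) {
    amp <- rep(1, samples)
    if (y[i] == 1) amp[round(samples * 0.4):round(samples * 0.6)] <- 0.1
    X[i, ] <- amp * sin(2 * pi * 0.25 * tt) + rnorm(samples, 0, 0.05)
  }
  list(X = X, y = y)
}

test_that("the full profile exposes the 1280-wide feature contract", {
  m <- build_extractor(extractor_config("full", input_samples = 1920))
  expect_equal(m$feature_width, 1280)
  expect_gt(n_params(m), 1e7)
  lg <- extractor_logits(m, matrix(0, 2, 1920))
  expect_equal(dim(lg), c(2, 2))
  expect_true(all(is.finite(lg)))
  f <- extract_features(m, matrix(rnorm(2 * 1920), 2, 1920))
  expect_equal(dim(f), c(2, 1280))
})

test_that("profiles document their feature widths and input limits", {
  tiny <- build_extractor(extractor_config("tiny", input_samples = 480))
  expect_equal(tiny$feature_width, 64)
  expect_equal(tiny$third_last_width, 32)
  f3 <- extract_features(tiny, matrix(rnorm(3 * 480), 3, 480),
                         feature_layer = "third_last")
  expect_equal(dim(f3), c(3, 32))
  small <- build_extractor(extractor_config("small", input_samples = 480))
  expect_equal(small$feature_width, 256)
  expect_error(build_extractor(extractor_config("tiny", input_samples = 4)),
               "minimum supported length")
})

test_that("backpropagation matches numerical gradients", {
  set.seed(2)
  m <- build_extractor(extractor_config("tiny", input_samples = 64, seed = 9))
  X <- array(rnorm(3 * 64), c(3, 64, 1))
  y <- c(0L, 1L, 1L)
  fw <- driven:::forward_nodes(m$nodes, m$params, X, keep_cache = TRUE)
  ce <- driven:::softmax_ce(fw$out, y)
  gr <- driven:::backward_nodes(m$nodes, m$params, fw$caches, ce$grad,
                                driven:::zero_grads(m$params))$grads
  loss_at <- function(params) {
    out <- driven:::forward_nodes(m$nodes, params, X, keep_cache = FALSE)$out
    driven:::softmax_ce(out, y)$loss
  }
  eps <- 1e-5
  worst <- 0
  for (id in names(m$params)) {
    for (f in c("W", "b")) {
      v <- m$params[[id]][[f]]
      for (k in sample(length(v), min(2, length(v)))) {
        p2 <- m$params
        p2[[id]][[f]][k] <- p2[[id]][[f]][k] + eps
        num <- (loss_at(p2) - ce$loss) / eps
        an <- gr[[id]][[f]][k]
        worst <- max(worst, abs(num - an) / max(1e-6, abs(num) + abs(an)))
      }
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("early stopping fires after the configured patience", {
  tw <- toy_windows(32, samples = 64)
  vw <- toy_windows(16, samples = 64, seed = 2)
  # zero learning rate: the validation loss never improves after epoch 1,
  # so training must stop at exactly 1 + patience epochs
  cfg <- extractor_config("tiny", input_samples = 64, learning_rate = 0,
                          epochs_patience = 3, max_epochs = 20, seed = 3)
  m <- train_extractor(build_extractor(cfg), tw$X, tw$y, vw$X, vw$y)
  expect_equal(nrow(m$history), 4)
  expect_equal(m$best_epoch, 1)
  expect_true(m$trained)
  expect_error(train_extractor(build_extractor(cfg), tw$X, tw$y,
                               tw$X[0, , drop = FALSE], integer(0)),
               "validation set is empty")
})

test_that("a tiny profile learns separable windows quickly", {
  tw <- toy_windows(128)
  vw <- toy_windows(64, seed = 5)
  cfg <- extractor_config("tiny", input_samples = 480, learning_rate = 3e-3,
                          max_epochs = 10, seed = 4)
  m <- train_extractor(build_extractor(cfg), tw$X, tw$y, vw$X, vw$y)
  lg <- extractor_logits(m, tw$X)
  acc <- mean((lg[, 2] > lg[, 1]) == (tw$y == 1))
  expect_gt(acc, 0.95)

  # inference is deterministic: identical windows, identical features
  f1 <- extract_features(m, vw$X[1:4, ])
  f2 <- extract_features(m, vw$X[1:4, ])
  expect_identical(f1, f2)
  expect_identical(f1[1, ], extract_features(m, vw$X[c(1, 1), ])[2, ])
  expect_error(extract_features(m, vw$X[, 1:100]), "does not match")
})

test_that("unbalanced training labels raise a warning", {
  tw <- toy_windows(30, samples = 64)
  y_skew <- c(rep(1L, 25), rep(0L, 5))
  cfg <- extractor_config("tiny", input_samples = 64, max_epochs = 1, seed = 1)
  expect_warning(train_extractor(build_extractor(cfg), tw$X, y_skew,
                                 tw$X, y_skew),
                 "not balanced")
})

test_that("stacker separates toy features and is reproducible", {
  set.seed(6)
  n <- 400
  y <- rep(0:1, each = n / 2)
  f <- cbind(rnorm(n, sd = 0.5) + 3 * y, rnorm(n))
  st <- fit_stacker(f, y, search_budget = 4, seed = 2)
  p <- predict_proba(st, f)
  expect_true(all(p >= 0 & p <= 1))
  expect_gt(roc_auc(p, y), 0.99)

  st2 <- fit_stacker(f, y, search_budget = 4, seed = 2)
  expect_identical(st$hyperparams, st2$hyperparams)
  expect_identical(predict_proba(st2, f), p)

  one <- fit_stacker(f, y, search_budget = 1, seed = 3)
  expect_s3_class(one, "stacker_model")
  expect_error(fit_stacker(f, rep(1, n)), "both classes")
  expect_error(predict_proba(st, f[, 1, drop = FALSE]), "feature width")
})

test_that("stacker probability is monotone in a single informative feature", {
  set.seed(7)
  x <- seq(-2, 2, length.out = 200)
  y <- as.integer(x > 0)
  st <- fit_stacker(matrix(x, ncol = 1), y, search_budget = 2, seed = 1)
  p <- predict_proba(st, matrix(sort(x), ncol = 1))
  # every tree splits the one feature with ordered leaf values, so the
  # ensemble probability is a non-decreasing staircase in x
  expect_true(all(diff(p) >= -1e-9))
  expect_gt(p[200], p[1])
})
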