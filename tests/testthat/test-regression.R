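test_that("constant targets are predicted exactly", {
  set.seed(1)
  coords <- matrix(runif(40), 20, 2)
  coefs <- cbind(rep(2.5, 20), rep(-1, 20))
  ch <- fit_coefficient_chain(coords, coefs, chain_config(trees = 10L))
  pred <- predict_chain(ch, matrix(runif(10), 5, 2))
  expect_equal(pred, cbind(rep(2.5, 5), rep(-1, 5)), tolerance = 1e-12)
})

test_that("a one-mode chain degenerates to a plain forest", {
  set.seed(2)
  coords <- matrix(runif(100), 50, 2)
  y <- sin(2 * pi * coords[, 1]) + coords[, 2]
  cfg <- chain_config(trees = 25L, depth = 10L, seed = 99L)
  ch <- fit_coefficient_chain(coords, cbind(y), cfg)
  q <- matrix(runif(20), 10, 2)
  got <- predict_chain(ch, q)
  feats <- data.frame(tsne_x = coords[, 1], tsne_y = coords[, 2])
  plain <- ranger::ranger(x = feats, y = y, num.trees = 25L, max.depth = 10L,
                          seed = 100L, num.threads = 1L)  # chain uses seed + j
  want <- predict(plain, data.frame(tsne_x = q[, 1], tsne_y = q[, 2]))$predictions
  expect_equal(as.vector(got), want, tolerance = 1e-12)
})

test_that("a smooth coefficient surface is learned accurately", {
  set.seed(3)
  n <- 500L
  coords <- matrix(runif(2 * n), n, 2)
  coefs <- cbind(sin(2 * pi * coords[, 1]) + coords[, 2],
                 coords[, 1] * coords[, 2],
                 cos(pi * coords[, 2]) - 0.5 * coords[, 1])
  tr <- 1:400; te <- 401:500
  ch <- fit_coefficient_chain(coords[tr, ], coefs[tr, ], chain_config(seed = 4L))
  pred <- predict_chain(ch, coords[te, ])
  for (j in 1:3) {
    r2 <- 1 - sum((pred[, j] - coefs[te, j])^2) /
      sum((coefs[te, j] - mean(coefs[te, j]))^2)
    expect_gt(r2, 0.9)
  }
})

test_that("chain prediction equals manually threading the forests", {
  set.seed(4)
  coords <- matrix(runif(60), 30, 2)
  coefs <- matrix(rnorm(90), 30, 3)
  ch <- fit_coefficient_chain(coords, coefs, chain_config(trees = 15L, seed = 7L))
  q <- matrix(runif(8), 4, 2)
  got <- predict_chain(ch, q)
  # brute-force: evaluate each stored forest in chain order by hand
  feats <- data.frame(tsne_x = q[, 1], tsne_y = q[, 2])
  manual <- matrix(0, 4, 3)
  for (j in 1:3) {
    p <- predict(ch$forests[[j]], feats)$predictions
    manual[, ch$order[j]] <- p
    feats[[sprintf("chat_m%d", ch$order[j])]] <- p
  }
  expect_equal(got, manual, tolerance = 1e-12)
})

test_that("degenerate training sets fall back to constants", {
  ch <- fit_coefficient_chain(matrix(c(0.3, 0.7), 1, 2),
                              matrix(c(1.5, -2), 1, 2), chain_config())
  pred <- predict_chain(ch, matrix(runif(20), 10, 2))
  expect_equal(pred, cbind(rep(1.5, 10), rep(-2, 10)), tolerance = 1e-12)
})

test_that("fit and predict are deterministic under a fixed seed", {
  set.seed(5)
  coords <- matrix(runif(80), 40, 2)
  coefs <- matrix(rnorm(80), 40, 2)
  q <- matrix(runif(12), 6, 2)
  p1 <- predict_chain(fit_coefficient_chain(coords, coefs,
                                            chain_config(seed = 3L)), q)
  p2 <- predict_chain(fit_coefficient_chain(coords, coefs,
                                            chain_config(seed = 3L)), q)
  expect_identical(p1, p2)
  p3 <- predict_chain(fit_coefficient_chain(coords, coefs,
                                            chain_config(seed = 8L)), q)
  expect_false(identical(p1, p3))
})

test_that("chain order and shapes are validated", {
  coords <- matrix(runif(20), 10, 2)
  coefs <- matrix(rnorm(20), 10, 2)
  expect_error(fit_coefficient_chain(coords[1:5, ], coefs), "mismatch")
  expect_error(fit_coefficient_chain(coords, coefs,
                                     chain_config(order = c(1L, 3L))),
               "permute")
  ch <- fit_coefficient_chain(coords, coefs,
                              chain_config(order = c(2L, 1L), trees = 5L))
  expect_equal(ch$order, c(2L, 1L))
  expect_equal(dim(predict_chain(ch, coords)), c(10L, 2L))
})

test_that("coefficient RMSE normalises by the supplied range", {
  truth <- matrix(c(0, 1, 2, 3), 4, 1)
  expect_equal(coefficient_rmse_percent(truth, truth, 1L), 0)
  # constant error e on a coefficient with range R -> 100 e / R
  expect_equal(coefficient_rmse_percent(truth + 0.3, truth, 1L), 10,
               tolerance = 1e-12)
  expect_equal(coefficient_rmse_percent(truth + 0.3, truth, 1L,
                                        norm_range = 6), 5, tolerance = 1e-12)
  # hand-computed random case
  pred <- matrix(c(0.1, 1.2, 1.9, 3.3), 4, 1)
  hand <- 100 * sqrt(mean(c(0.1, 0.2, -0.1, 0.3)^2)) / 3
  expect_equal(coefficient_rmse_percent(pred, truth, 1L), hand,
               tolerance = 1e-12)
  expect_warning(out <- coefficient_rmse_percent(truth, truth, 1L,
                                                 norm_range = 0), "zero")
  expect_true(is.na(out))
  expect_error(coefficient_rmse_percent(truth, truth[1:2, , drop = FALSE]),
               "shape mismatch")
  expect_error(coefficient_rmse_percent(truth, truth, 5L), "out of range")
})
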