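test_that("SELU matches its closed form", {
  expect_equal(selu(0), 0)
  expect_equal(selu(1), 1.05070098)
  # limit as x -> -Inf is -lambda * alpha
  expect_equal(selu(-40), -1.05070098 * 1.67326324, tolerance = 1e-12)
  expect_equal(selu(c(2, -1)),
               c(2 * 1.05070098, 1.05070098 * 1.67326324 * (exp(-1) - 1)))
})

test_that("scaler uses train statistics with the divisor-n convention", {
  sc <- fit_scaler(matrix(c(1, 3), ncol = 1))
  expect_equal(sc$mean, 2)
  expect_equal(sc$scale, 1)  # population SD of {1, 3}
  expect_equal(drop(apply_scaler(sc, matrix(5, ncol = 1))), 3)
  # constant training column: scale 1, transformed to zeros, no error
  sc2 <- fit_scaler(cbind(rep(4, 6), 1:6))
  expect_equal(sc2$scale[1], 1)
  expect_equal(apply_scaler(sc2, cbind(rep(4, 3), 1:3))[, 1], rep(0, 3))
})

test_that("standardize fits on train only and leaves the DV untouched", {
  sp <- make_split(50, 3, seed = 21)
  std <- standardize(sp)
  expect_equal(unname(colMeans(std$train_x)), rep(0, 3), tolerance = 1e-10)
  n <- nrow(std$train_x)
  expect_equal(unname(sqrt(colMeans(std$train_x^2))), rep(1, 3),
               tolerance = 1e-10)
  expect_identical(std$train_y, sp$train$dv_vector)
  expect_identical(std$test_y, sp$test$dv_vector)
  # test transform must use the train statistics
  expect_equal(std$test_x, apply_scaler(std$scaler, sp$test$iv_matrix))
})

test_that("forward propagation composes affine maps and activations", {
  cfg <- network_config(2, "regression", init_scheme = "zero")
  net <- init_network(3, cfg)
  expect_equal(forward(net, matrix(rnorm(12), 4)), rep(0, 4))
  cfgc <- network_config(2, "classification", init_scheme = "zero")
  netc <- init_network(3, cfgc)
  expect_equal(forward(netc, matrix(rnorm(12), 4)), rep(0.5, 4))
  # one hidden unit, hand-set identity weights: output = selu(x)
  net1 <- manual_network(list(matrix(1), matrix(1)), list(0, 0))
  expect_equal(forward(net1, matrix(1)), 1.05070098)
  expect_error(forward(net1, matrix(1, 1, 2)), "expects")
})

test_that("losses match hand-computed values", {
  y <- rnorm(5)
  expect_equal(compute_loss("regression", y, y), 0)
  expect_equal(compute_loss("regression", c(0, 2), c(0, 0)), 2)
  expect_equal(compute_loss("classification", 1, 0.5), log(2))
  # clipping keeps the cross-entropy finite at hard 0/1 predictions
  expect_true(is.finite(compute_loss("classification", c(1, 0), c(0, 1))))
})

test_that("a single Adam step matches the closed form", {
  st <- list(m = 0, v = 0)
  up <- adam_step(1, 0.5, st, t = 1, learning_rate = 0.001,
                  beta1 = 0.9, beta2 = 0.999, epsilon = 0)
  expect_equal(up$param, 0.999)
  expect_equal(up$state$m, 0.05)
  expect_equal(up$state$v, 0.00025)
  # zero gradient from zero state leaves the parameter unchanged
  up0 <- adam_step(2, 0, list(m = 0, v = 0), t = 1)
  expect_equal(up0$param, 2)
  # with repeated identical gradients the step magnitude approaches lr
  w <- 0; st <- list(m = 0, v = 0)
  for (t in 1:300) {
    up <- adam_step(w, 1, st, t, learning_rate = 0.001, epsilon = 0)
    step <- up$param - w
    w <- up$param; st <- up$state
  }
  expect_equal(abs(step), 0.001, tolerance = 1e-6)
  expect_lt(step, 0)  # sign follows -gradient
})

test_that("backpropagation agrees with central finite differences", {
  shapes <- list(2L, 7L, 30L, c(10L, 10L), c(50L, 50L))
  for (task in c("regression", "classification")) {
    for (shape in shapes) {
      set.seed(sum(shape) + nchar(task))
      cfg <- network_config(shape, task)
      net <- init_network(3, cfg)
      X <- matrix(rnorm(15), 5, 3)
      y <- if (task == "regression") rnorm(5) else rbinom(5, 1, 0.5)
      got <- backprop_gradients(net, X, y)
      want <- numeric_gradients(net, X, y)
      for (l in seq_along(net$weights)) {
        denom <- pmax(abs(want$weights[[l]]), 1e-4)
        expect_lt(max(abs(got$weights[[l]] - want$weights[[l]]) / denom), 1e-4)
        denomb <- pmax(abs(want$biases[[l]]), 1e-4)
        expect_lt(max(abs(got$biases[[l]] - want$biases[[l]]) / denomb), 1e-4)
      }
    }
  }
})

test_that("gradients vanish at a perfect regression fit", {
  set.seed(33)
  cfg <- network_config(c(4L, 3L), "regression")
  net <- init_network(2, cfg)
  X <- matrix(rnorm(10), 5, 2)
  y <- forward(net, X)
  g <- backprop_gradients(net, X, y)
  expect_equal(max(abs(unlist(g$weights))), 0, tolerance = 1e-12)
  expect_equal(max(abs(unlist(g$biases))), 0, tolerance = 1e-12)
})

test_that("output-layer gradient under MSE is 2 * mean(pred - y)", {
  # bias-only single-layer effect: zero weights, so only the output bias moves
  cfg <- network_config(2, "regression", init_scheme = "zero")
  net <- init_network(3, cfg)
  X <- matrix(rnorm(12), 4, 3)
  y <- c(1, 2, 3, 4)
  g <- backprop_gradients(net, X, y)
  expect_equal(g$biases[[2]], 2 * mean(0 - y))
})

test_that("training honours the early-stopping contract", {
  for (dv in c("continuous", "binary")) {
    sp <- make_split(100, 3, dv_kind = dv, seed = 44)
    task <- if (dv == "continuous") "regression" else "classification"
    set.seed(7)
    fit <- train_network(sp, network_config(7, task))
    tr <- fit$trace
    expect_lte(tr$stopped_epoch, 100)
    expect_equal(tr$val_loss[tr$best_epoch], min(tr$val_loss))
    expect_lte(tr$stopped_epoch - tr$best_epoch, 10)
    expect_true(all(is.finite(tr$train_loss)))
    expect_true(all(is.finite(unlist(fit$network$weights))))
  }
})

test_that("training is deterministic given the seed", {
  sp <- make_split(50, 3, dv_kind = "binary", seed = 55)
  cfg <- network_config(2, "classification")
  set.seed(99); f1 <- train_network(sp, cfg)
  set.seed(99); f2 <- train_network(sp, cfg)
  expect_identical(f1$network$weights, f2$network$weights)
  expect_identical(f1$trace$val_loss, f2$trace$val_loss)
  x <- sp$test$iv_matrix
  expect_identical(predict_scores(f1, x), predict_scores(f2, x))
})

test_that("prediction composes scaling and forward propagation", {
  sp <- make_split(50, 3, dv_kind = "binary", seed = 66)
  set.seed(8)
  fit <- train_network(sp, network_config(2, "classification"))
  s <- predict_scores(fit, sp$test$iv_matrix)
  manual <- forward(fit$network, apply_scaler(fit$scaler, sp$test$iv_matrix))
  expect_identical(s, manual)
  expect_true(all(s > 0 & s < 1))
  expect_error(predict_scores(fit$network, sp$test$iv_matrix), "scaler")
})

test_that("a strong injected signal is recovered end to end", {
  spec <- spec_cont(500, 3)
  set.seed(123)
  iv <- sample_iv_matrix(500, 3)
  dv <- sample_signal_dv(iv, 5, "continuous")
  data <- structure(list(iv_matrix = iv, dv_vector = dv, spec = spec),
                    class = "nn_dataset")
  colnames(data$iv_matrix) <- paste0("iv_", 1:3)
  sp <- split_dataset(data, 0.8)
  fit <- train_network(sp, network_config(7, "regression"))
  r2 <- r_squared(sp$test$dv_vector, predict_scores(fit, sp$test$iv_matrix))
  expect_gt(r2, 0.5)

  dvb <- sample_signal_dv(iv, 5, "binary")
  datab <- data; datab$dv_vector <- dvb
  datab$spec <- spec_bin(500, 3)
  spb <- split_dataset(datab, 0.8)
  fitb <- train_network(spb, network_config(7, "classification"))
  auc <- auc_rank(spb$test$dv_vector, predict_scores(fitb, spb$test$iv_matrix))
  expect_gt(auc, 0.8)
})

test_that("network weights survive a JSON round trip", {
  set.seed(77)
  net <- init_network(4, network_config(c(5L, 3L), "classification"))
  json <- network_to_json(net)
  back <- network_from_json(json)
  expect_equal(back$weights, net$weights)
  expect_equal(back$biases, net$biases)
  expect_identical(back$task, net$task)
  X <- matrix(rnorm(20), 5, 4)
  expect_equal(forward(back, X), forward(net, X))
})
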