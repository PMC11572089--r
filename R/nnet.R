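#' Configure the network and its training protocol
#'
#' The protocol is a deliberately minimal framework-default workflow: fully
#' connected layers, SELU hidden activations, one output neuron (identity for
#' regression, logistic sigmoid for classification), Adam optimisation on
#' shuffled mini-batches, and early stopping on the loss of a validation
#' subset held out of the training partition, restoring the best weights.
#'
#' @param hidden_sizes Integer vector of hidden-layer widths, e.g. `c(2)`,
#'   `c(7)`, `c(30)`, `c(10, 10)`, `c(50, 50)`.
#' @param task `"regression"` or `"classification"`.
#' @param max_epochs Hard cap on training epochs (default 100).
#' @param patience Epochs without strict validation-loss improvement before
#'   stopping (default 10).
#' @param validation_fraction Fraction of the training partition held out for
#'   early stopping (default 0.2).
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters
#'   (defaults .001, .9, .999, 1e-7).
#' @param batch_size Mini-batch size (default 32; the last batch may be
#'   smaller).
#' @param init_scheme Weight initialisation, always with zero biases:
#'   `"glorot_uniform"` (uniform on ±sqrt(6/(fan_in+fan_out)), the common
#'   framework default and this package's default), `"lecun_normal"`
#'   (Gaussian with SD 1/sqrt(fan_in), the scheme recommended for SELU), or
#'   `"zero"` for fixture tests.
#' @param standardize_dv Standardize a continuous DV with train statistics as
#'   well as the features? Default `FALSE` (features only; predictions are
#'   returned on the original DV scale either way).
#' @return An object of class `"nn_config"`.
#' @export
network_config <- function(hidden_sizes, task = c("regression", "classification"),
                           max_epochs = 100L, patience = 10L,
                           validation_fraction = 0.2,
                           learning_rate = 0.001, beta1 = 0.9, beta2 = 0.999,
                           epsilon = 1e-7, batch_size = 32L,
                           init_scheme = c("glorot_uniform", "lecun_normal",
                                           "zero"),
                           standardize_dv = FALSE) {
  task <- match.arg(task)
  init_scheme <- match.arg(init_scheme)
  hidden_sizes <- as.integer(hidden_sizes)
  if (length(hidden_sizes) < 1L || any(hidden_sizes < 1L)) {
    stop("`hidden_sizes` must be positive integers", call. = FALSE)
  }
  if (patience < 1L || patience > max_epochs) {
    stop("need 1 <= patience <= max_epochs", call. = FALSE)
  }
  if (validation_fraction <= 0 || validation_fraction >= 1) {
    stop("`validation_fraction` must lie strictly in (0, 1)", call. = FALSE)
  }
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    stop("`beta1` and `beta2` must lie in [0, 1)", call. = FALSE)
  }
  structure(
    list(hidden_sizes = hidden_sizes, task = task,
         max_epochs = as.integer(max_epochs), patience = as.integer(patience),
         validation_fraction = validation_fraction,
         learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
         epsilon = epsilon, batch_size = as.integer(batch_size),
         init_scheme = init_scheme, standardize_dv = standardize_dv),
    class = "nn_config"
  )
}

# SELU constants (fixed by the self-normalising derivation)
SELU_LAMBDA <- 1.05070098
SELU_ALPHA <- 1.67326324

#' Scaled exponential linear unit
#'
#' `lambda * x` for positive `x`, `lambda * alpha * (exp(x) - 1)` otherwise,
#' with lambda = 1.05070098 and alpha = 1.67326324. Vectorised.
#'
#' @param x Numeric vector or matrix.
#' @return Same shape as `x`.
#' @export
selu <- function(x) {
  ifelse(x > 0, SELU_LAMBDA * x, SELU_LAMBDA * SELU_ALPHA * (exp(x) - 1))
}

selu_deriv <- function(x) {
  ifelse(x > 0, SELU_LAMBDA, SELU_LAMBDA * SELU_ALPHA * exp(x))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Fit a feature scaler on training data
#'
#' Column means and standard deviations in the divisor-n (population)
#' convention. Columns that are constant on the training data get scale 1 so
#' that transformation maps them to exact zeros rather than dividing by zero.
#'
#' @param X Numeric matrix (training features).
#' @return Object of class `"nn_scaler"` with `mean` and `scale` vectors.
#' @export
fit_scaler <- function(X) {
  m <- colMeans(X)
  n <- nrow(X)
  s <- sqrt(colMeans(X^2) - m^2)
  s[!is.finite(s) | s < 1e-12] <- 1
  structure(list(mean = m, scale = s, n = n), class = "nn_scaler")
}

#' @rdname fit_scaler
#' @param scaler An `"nn_scaler"`.
#' @export
apply_scaler <- function(scaler, X) {
  stopifnot(inherits(scaler, "nn_scaler"))
  sweep(sweep(X, 2L, scaler$mean, "-"), 2L, scaler$scale, "/")
}

#' Standardize a train/test split with train statistics only
#'
#' The scaler is fitted on the training partition and applied to both
#' partitions, so no information flows from the test set into training. The
#' DV is left untouched unless `standardize_dv` (continuous DVs only).
#'
#' @param split An `nn_split` from [split_dataset()].
#' @param standardize_dv Also center/scale a continuous DV by its train
#'   statistics? Default `FALSE`.
#' @return List with `train_x`, `test_x` (numeric matrices), `train_y`,
#'   `test_y`, `scaler`, and (when used) `dv_scaler`.
#' @export
standardize <- function(split, standardize_dv = FALSE) {
  stopifnot(inherits(split, "nn_split"))
  scaler <- fit_scaler(split$train$iv_matrix)
  out <- list(
    train_x = apply_scaler(scaler, split$train$iv_matrix),
    test_x = apply_scaler(scaler, split$test$iv_matrix),
    train_y = split$train$dv_vector,
    test_y = split$test$dv_vector,
    scaler = scaler, dv_scaler = NULL
  )
  if (standardize_dv) {
    if (split$train$spec$dv_kind != "continuous") {
      stop("`standardize_dv` applies to continuous DVs only", call. = FALSE)
    }
    dvs <- fit_scaler(matrix(out$train_y, ncol = 1))
    out$train_y <- as.numeric(apply_scaler(dvs, matrix(out$train_y, ncol = 1)))
    out$test_y <- as.numeric(apply_scaler(dvs, matrix(out$test_y, ncol = 1)))
    out$dv_scaler <- dvs
  }
  out
}

#' Initialise a network
#'
#' Chains input dimension through `hidden_sizes` to a single output neuron.
#' Glorot-uniform weights with zero biases by default (see
#' [network_config()]'s `init_scheme`).
#'
#' @param n_in Number of input features.
#' @param config An [network_config()].
#' @return Object of class `"nn_network"` with `weights`, `biases`, `task`.
#' @export
init_network <- function(n_in, config) {
  stopifnot(inherits(config, "nn_config"))
  sizes <- c(n_in, config$hidden_sizes, 1L)
  weights <- biases <- vector("list", length(sizes) - 1L)
  for (l in seq_along(weights)) {
    fan_in <- sizes[l]
    fan_out <- sizes[l + 1L]
    weights[[l]] <- switch(config$init_scheme,
      zero = matrix(0, fan_in, fan_out),
      lecun_normal = matrix(
        stats::rnorm(fan_in * fan_out, sd = 1 / sqrt(fan_in)),
        fan_in, fan_out),
      glorot_uniform = {
        lim <- sqrt(6 / (fan_in + fan_out))
        matrix(stats::runif(fan_in * fan_out, -lim, lim), fan_in, fan_out)
      }
    )
    biases[[l]] <- rep(0, sizes[l + 1L])
  }
  structure(list(weights = weights, biases = biases, task = config$task,
                 sizes = sizes),
            class = "nn_network")
}

# Forward pass keeping pre-activations and activations for backprop.
forward_pass <- function(net, X) {
  L <- length(net$weights)
  A <- vector("list", L + 1L)
  Z <- vector("list", L)
  A[[1L]] <- X
  for (l in seq_len(L)) {
    Z[[l]] <- A[[l]] %*% net$weights[[l]] +
      rep(net$biases[[l]], each = nrow(X))
    A[[l + 1L]] <- if (l < L) selu(Z[[l]]) else Z[[l]]
  }
  out <- drop(A[[L + 1L]])
  if (net$task == "classification") out <- sigmoid(out)
  list(output = out, A = A, Z = Z)
}

#' Forward-propagate scaled features through a network
#'
#' @param net An `nn_network`.
#' @param X Scaled feature matrix whose column count matches the input layer.
#' @return Output vector: raw affine outputs for regression, sigmoid
#'   probabilities in (0, 1) for classification.
#' @export
forward <- function(net, X) {
  stopifnot(inherits(net, "nn_network"))
  X <- as.matrix(X)
  if (ncol(X) != net$sizes[1L]) {
    stop("input has ", ncol(X), " columns but the network expects ",
         net$sizes[1L], call. = FALSE)
  }
  forward_pass(net, X)$output
}

#' Training losses
#'
#' Mean squared error for regression; mean binary cross-entropy for
#' classification, with predictions clipped to `[1e-7, 1 - 1e-7]` before
#' taking logs.
#'
#' @param task `"regression"` or `"classification"`.
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return Single loss value.
#' @export
compute_loss <- function(task, y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (task == "regression") {
    mean((y_true - y_pred)^2)
  } else {
    p <- pmin(pmax(y_pred, 1e-7), 1 - 1e-7)
    -mean(y_true * log(p) + (1 - y_true) * log(1 - p))
  }
}

#' One Adam update for a parameter block
#'
#' Bias-corrected adaptive moment estimation:
#' `m <- beta1 m + (1 - beta1) g`, `v <- beta2 v + (1 - beta2) g^2`,
#' then `param <- param - lr * mhat / (sqrt(vhat) + epsilon)` with
#' `mhat = m / (1 - beta1^t)`, `vhat = v / (1 - beta2^t)`.
#'
#' @param param Numeric parameter array.
#' @param grad Gradient of the loss with respect to `param` (same shape).
#' @param state List with accumulators `m` and `v` (zeros before step 1).
#' @param t Step index, starting at 1.
#' @param learning_rate,beta1,beta2,epsilon Adam hyperparameters.
#' @return List with updated `param` and `state`.
#' @export
adam_step <- function(param, grad, state, t, learning_rate = 0.001,
                      beta1 = 0.9, beta2 = 0.999, epsilon = 1e-7) {
  m <- beta1 * state$m + (1 - beta1) * grad
  v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- m / (1 - beta1^t)
  vhat <- v / (1 - beta2^t)
  list(param = param - learning_rate * mhat / (sqrt(vhat) + epsilon),
       state = list(m = m, v = v))
}

#' Exact loss gradients by backpropagation
#'
#' Gradients of [compute_loss()] with respect to every weight matrix and bias
#' vector, averaged over the batch. For regression the output delta is
#' `2 (pred - y) / B`; for classification the sigmoid/cross-entropy pair gives
#' `(pred - y) / B`.
#'
#' @param net An `nn_network`.
#' @param X Scaled feature batch.
#' @param y Batch targets.
#' @return List with `weights` and `biases` gradient lists, plus the batch
#'   `loss` and `output`.
#' @export
backprop_gradients <- function(net, X, y) {
  X <- as.matrix(X)
  fp <- forward_pass(net, X)
  L <- length(net$weights)
  B <- nrow(X)
  gw <- gb <- vector("list", L)
  delta <- if (net$task == "regression") {
    matrix(2 * (fp$output - y) / B, ncol = 1)
  } else {
    matrix((fp$output - y) / B, ncol = 1)
  }
  for (l in L:1) {
    gw[[l]] <- crossprod(fp$A[[l]], delta)
    gb[[l]] <- colSums(delta)
    if (l > 1L) {
      delta <- (delta %*% t(net$weights[[l]])) * selu_deriv(fp$Z[[l - 1L]])
    }
  }
  list(weights = gw, biases = gb,
       loss = compute_loss(net$task, y, fp$output), output = fp$output)
}

#' Train a network on a standardized split with early stopping
#'
#' Implements the full fitting protocol: fit the scaler on the training
#' partition, hold out `validation_fraction` of the training rows (chosen
#' uniformly at random, fixed for the whole fit), then run mini-batch
#' backpropagation with Adam for at most `max_epochs` epochs, evaluating the
#' validation loss after every epoch. Training stops once the validation loss
#' has not strictly improved for `patience` consecutive epochs, and the
#' weights snapshotted at the best epoch are returned.
#'
#' Randomness (validation choice, weight init, batch shuffles) is consumed
#' from the current RNG stream, so the whole fit is reproducible from one
#' seed set before the call.
#'
#' @param split An `nn_split` from [split_dataset()].
#' @param config An [network_config()].
#' @param restore_best Return the weights snapshotted at the best validation
#'   epoch (`TRUE`, the protocol's contract) or the weights as of the last
#'   trained epoch (`FALSE`, the behaviour of early-stopping utilities that
#'   do not restore by default). The trace records `best_epoch` either way.
#' @return Object of class `"nn_fit"`: `network` (best weights), `trace`
#'   (class `"nn_trace"`: per-epoch `train_loss`, `val_loss`, `best_epoch`,
#'   `stopped_epoch`), `scaler`, `config`.
#' @export
train_network <- function(split, config, restore_best = TRUE) {
  stopifnot(inherits(split, "nn_split"), inherits(config, "nn_config"))
  std <- standardize(split, standardize_dv = config$standardize_dv &&
                       split$train$spec$dv_kind == "continuous")
  X <- std$train_x
  y <- std$train_y
  n <- nrow(X)
  n_val <- max(1L, round(config$validation_fraction * n))
  if (n_val >= n) {
    stop("training partition too small to hold out a validation subset",
         call. = FALSE)
  }
  val_idx <- sort(sample.int(n, n_val))
  fit_idx <- setdiff(seq_len(n), val_idx)
  Xf <- X[fit_idx, , drop = FALSE]
  yf <- y[fit_idx]
  Xv <- X[val_idx, , drop = FALSE]
  yv <- y[val_idx]

  net <- init_network(ncol(X), config)
  L <- length(net$weights)
  st_w <- lapply(net$weights, function(w) list(m = w * 0, v = w * 0))
  st_b <- lapply(net$biases, function(b) list(m = b * 0, v = b * 0))

  n_fit <- nrow(Xf)
  train_loss <- val_loss <- numeric(0)
  best_loss <- Inf
  best_epoch <- 0L
  best_w <- net$weights
  best_b <- net$biases
  wait <- 0L
  t_step <- 0L
  epoch <- 0L

  while (epoch < config$max_epochs) {
    epoch <- epoch + 1L
    ord <- sample.int(n_fit)
    starts <- seq(1L, n_fit, by = config$batch_size)
    batch_losses <- numeric(length(starts))
    for (bi in seq_along(starts)) {
      rows <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n_fit)]
      g <- backprop_gradients(net, Xf[rows, , drop = FALSE], yf[rows])
      batch_losses[bi] <- g$loss
      t_step <- t_step + 1L
      for (l in seq_len(L)) {
        up <- adam_step(net$weights[[l]], g$weights[[l]], st_w[[l]], t_step,
                        config$learning_rate, config$beta1, config$beta2,
                        config$epsilon)
        net$weights[[l]] <- up$param
        st_w[[l]] <- up$state
        up <- adam_step(net$biases[[l]], g$biases[[l]], st_b[[l]], t_step,
                        config$learning_rate, config$beta1, config$beta2,
                        config$epsilon)
        net$biases[[l]] <- up$param
        st_b[[l]] <- up$state
      }
    }
    train_loss[epoch] <- mean(batch_losses)
    vl <- compute_loss(net$task, yv, forward_pass(net, Xv)$output)
    val_loss[epoch] <- vl
    if (vl < best_loss) {
      best_loss <- vl
      best_epoch <- epoch
      best_w <- net$weights
      best_b <- net$biases
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  if (restore_best) {
    net$weights <- best_w
    net$biases <- best_b
  }
  structure(
    list(
      network = net,
      trace = structure(list(train_loss = train_loss, val_loss = val_loss,
                             best_epoch = best_epoch, stopped_epoch = epoch),
                        class = "nn_trace"),
      scaler = std$scaler, dv_scaler = std$dv_scaler, config = config
    ),
    class = "nn_fit"
  )
}

#' @export
print.nn_fit <- function(x, ...) {
  cat(sprintf(
    "<nn_fit> %s, shape (%s); stopped at epoch %d, best epoch %d (val loss %.5g)\n",
    x$network$task, paste(x$config$hidden_sizes, collapse = ","),
    x$trace$stopped_epoch, x$trace$best_epoch,
    x$trace$val_loss[x$trace$best_epoch]
  ))
  invisible(x)
}

#' Score raw (unscaled) features with a trained network
#'
#' Applies the stored train-fitted scaler and forward-propagates. For
#' classification the scores are sigmoid probabilities; class decisions are
#' made downstream by thresholding, not here. Pure function of its inputs.
#'
#' @param fit An `nn_fit` (or an `nn_network`, in which case `scaler` must be
#'   supplied).
#' @param X_raw Feature matrix on the original 1..5 scale.
#' @param scaler Optional `nn_scaler` when `fit` is a bare network.
#' @return Numeric score vector.
#' @export
predict_scores <- function(fit, X_raw, scaler = NULL) {
  if (inherits(fit, "nn_fit")) {
    net <- fit$network
    scaler <- fit$scaler
    dvs <- fit$dv_scaler
  } else {
    net <- fit
    dvs <- NULL
    if (is.null(scaler)) stop("`scaler` required with a bare network", call. = FALSE)
  }
  out <- forward(net, apply_scaler(scaler, as.matrix(X_raw)))
  if (!is.null(dvs)) out <- out * dvs$scale[1] + dvs$mean[1]
  out
}

#' @export
predict.nn_fit <- function(object, newdata, ...) predict_scores(object, newdata)

#' Serialize network weights to JSON and back
#'
#' Layer-ordered lists of weight matrices (row-major lists of rows) and bias
#' vectors, for fixture tests and cross-implementation checks.
#'
#' @param net An `nn_network`.
#' @param path Optional file path; when `NULL` the JSON string is returned.
#' @return [network_to_json()]: path (invisibly) or JSON string;
#'   [network_from_json()]: an `nn_network`.
#' @export
network_to_json <- function(net, path = NULL) {
  stopifnot(inherits(net, "nn_network"))
  payload <- list(
    task = net$task,
    sizes = net$sizes,
    layers = lapply(seq_along(net$weights), function(l) {
      list(weights = apply(net$weights[[l]], 1L, as.numeric, simplify = FALSE),
           biases = as.numeric(net$biases[[l]]))
    })
  )
  json <- jsonlite::toJSON(payload, digits = NA, auto_unbox = TRUE)
  if (is.null(path)) return(as.character(json))
  writeLines(json, path)
  invisible(path)
}

#' @rdname network_to_json
#' @param json JSON string or file path produced by [network_to_json()].
#' @export
network_from_json <- function(json) {
  payload <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  sizes <- as.integer(unlist(payload$sizes))
  weights <- lapply(seq_along(payload$layers), function(l) {
    do.call(rbind, lapply(payload$layers[[l]]$weights, unlist))
  })
  biases <- lapply(payload$layers, function(layer) as.numeric(unlist(layer$biases)))
  structure(list(weights = weights, biases = biases,
                 task = payload$task, sizes = sizes),
            class = "nn_network")
}
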