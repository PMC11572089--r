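# Shared builders for small test objects.

spec_cont <- function(n = 50, k = 3) {
  dataset_spec(n, k, "uniform", "continuous")
}

spec_bin <- function(n = 50, k = 3, p = 0.5, probs = "uniform") {
  dataset_spec(n, k, probs, "binary", dv_positive_rate = p)
}

# A tiny deterministic split for engine tests.
make_split <- function(n = 50, k = 3, dv_kind = "continuous", seed = 42,
                       p = 0.5) {
  spec <- dataset_spec(n, k, "uniform", dv_kind, dv_positive_rate = p)
  data <- generate_dataset(spec, seed = seed)
  split_dataset(data, 0.8)
}

# Hand-buildable network: set every weight/bias explicitly.
manual_network <- function(weights, biases, task = "regression") {
  sizes <- c(nrow(weights[[1]]), vapply(weights, ncol, integer(1)))
  structure(list(weights = weights, biases = biases, task = task,
                 sizes = sizes),
            class = "nn_network")
}

# Finite-difference gradient of compute_loss through the network, used as
# the independent oracle for backprop_gradients.
numeric_gradients <- function(net, X, y, h = 1e-5) {
  loss_at <- function(n2) compute_loss(n2$task, y, forward(n2, X))
  gw <- lapply(net$weights, function(w) w * 0)
  gb <- lapply(net$biases, function(b) b * 0)
  for (l in seq_along(net$weights)) {
    for (i in seq_along(net$weights[[l]])) {
      up <- net; up$weights[[l]][i] <- up$weights[[l]][i] + h
      dn <- net; dn$weights[[l]][i] <- dn$weights[[l]][i] - h
      gw[[l]][i] <- (loss_at(up) - loss_at(dn)) / (2 * h)
    }
    for (i in seq_along(net$biases[[l]])) {
      up <- net; up$biases[[l]][i] <- up$biases[[l]][i] + h
      dn <- net; dn$biases[[l]][i] <- dn$biases[[l]][i] - h
      gb[[l]][i] <- (loss_at(up) - loss_at(dn)) / (2 * h)
    }
  }
  list(weights = gw, biases = gb)
}

# Brute-force pairwise AUC oracle (independent of the rank implementation).
auc_bruteforce <- function(y, s) {
  pos <- s[y == 1]
  neg <- s[y == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}
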