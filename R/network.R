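## The network model family: a fully connected feed-forward classifier
## (14 -> n_layers x n_nodes ReLU -> 4-class softmax), Xavier-initialised,
## trained by full-batch gradient descent on the cross-entropy loss with
## inverted dropout on the hidden activations.

softmax_rows <- function(z) {
  z <- z - apply(z, 1, max)
  e <- exp(z)
  e / rowSums(e)
}

#' Train a neural-network fucosylation classifier
#'
#' Fits one candidate of the network family on a 14-ion feature table.
#' Weights are Xavier-initialised (Gaussian with variance 2 / (fan_in +
#' fan_out)) from `spec$seed`; training runs `spec$epochs` full-batch
#' gradient-descent steps at `spec$learning_rate` on the softmax
#' cross-entropy, with inverted dropout (keep probability
#' `spec$dropout_keep`) applied to hidden activations during training only.
#' Training is deterministic given the seed.
#'
#' @param features A feature tibble (from [extract_features()]) or numeric
#'   matrix with the 14 ion columns.
#' @param labels Fucosylation labels (`none`/`core`/`outer`/`dual`), one per
#'   row of `features`.
#' @param spec A [network_spec()].
#' @param trace_every Record the training loss every this many epochs (the
#'   trace is stored in `model$loss_trace`).
#' @return A fitted model of class `c("fuco_network", "fuco_model")`.
#' @export
train_network <- function(features, labels, spec = network_spec(),
                          trace_every = max(1L, spec$epochs %/% 20L)) {
  x <- feature_matrix(features)
  y <- as_fuco_factor(labels)
  n <- nrow(x)
  if (n == 0) abort("Cannot train on an empty feature set.")
  if (length(y) != n) abort("`labels` must have one entry per feature row.")
  if (anyNA(y)) abort("Training labels must not contain missing values.")
  if (dplyr::n_distinct(y) < 2) {
    warn("Training set contains a single class; the fitted model is degenerate.")
  }
  k <- length(FUCO_CLASSES)
  y_onehot <- matrix(0, n, k)
  y_onehot[cbind(seq_len(n), as.integer(y))] <- 1

  dims <- c(ncol(x), rep(spec$n_nodes, spec$n_layers), k)
  n_mats <- length(dims) - 1L
  lr <- spec$learning_rate
  keep <- spec$dropout_keep

  state <- withr::with_seed(spec$seed, {
    w <- vector("list", n_mats)
    b <- vector("list", n_mats)
    for (l in seq_len(n_mats)) {
      sd_l <- sqrt(2 / (dims[l] + dims[l + 1]))
      w[[l]] <- matrix(rnorm(dims[l] * dims[l + 1], 0, sd_l), dims[l], dims[l + 1])
      b[[l]] <- numeric(dims[l + 1])
    }
    loss_trace <- tibble(epoch = integer(0), loss = numeric(0))
    for (ep in seq_len(spec$epochs)) {
      # forward (with dropout)
      a <- vector("list", n_mats + 1L)
      a[[1]] <- x
      for (l in seq_len(n_mats)) {
        z <- sweep(a[[l]] %*% w[[l]], 2, b[[l]], "+")
        if (l < n_mats) {
          h <- pmax(z, 0)
          if (keep < 1) {
            mask <- matrix(stats::rbinom(length(h), 1L, keep), nrow(h)) / keep
            h <- h * mask
          }
          a[[l + 1]] <- h
        } else {
          a[[l + 1]] <- softmax_rows(z)
        }
      }
      p <- a[[n_mats + 1L]]
      if (ep %% trace_every == 0 || ep == spec$epochs) {
        loss <- -mean(log(pmax(rowSums(p * y_onehot), 1e-15)))
        loss_trace <- dplyr::bind_rows(loss_trace, tibble(epoch = ep, loss = loss))
      }
      # backward
      delta <- (p - y_onehot) / n
      for (l in rev(seq_len(n_mats))) {
        gw <- crossprod(a[[l]], delta)
        gb <- colSums(delta)
        if (l > 1) {
          # d(relu * mask)/dz = mask / keep where the unit is active and kept;
          # a[[l]] > 0 identifies exactly those units.
          delta <- (delta %*% t(w[[l]])) * (a[[l]] > 0) / keep
        }
        w[[l]] <- w[[l]] - lr * gw
        b[[l]] <- b[[l]] - lr * gb
      }
    }
    list(w = w, b = b, loss_trace = loss_trace)
  })

  structure(
    list(
      family = "network", spec = spec,
      weights = state$w, biases = state$b,
      loss_trace = state$loss_trace,
      class_order = FUCO_CLASSES
    ),
    class = c("fuco_network", "fuco_model")
  )
}

network_forward <- function(model, x) {
  n_mats <- length(model$weights)
  a <- x
  for (l in seq_len(n_mats)) {
    z <- sweep(a %*% model$weights[[l]], 2, model$biases[[l]], "+")
    a <- if (l < n_mats) pmax(z, 0) else softmax_rows(z)
  }
  colnames(a) <- model$class_order
  a
}
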