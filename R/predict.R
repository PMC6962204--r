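#' Class probabilities from a fitted model
#'
#' Returns the four-class probability simplex (columns `none`, `core`,
#' `outer`, `dual`, each row summing to 1) for every row of a feature
#' table. Predictions are deterministic given the fitted model.
#'
#' @param model A fitted `fuco_model` (from [train_network()] or
#'   [train_margin()]).
#' @param features A feature tibble or matrix with the 14 ion columns.
#' @return A tibble with one probability column per class.
#' @export
predict_probabilities <- function(model, features) {
  UseMethod("predict_probabilities")
}

#' @export
predict_probabilities.fuco_network <- function(model, features) {
  x <- feature_matrix(features)
  tibble::as_tibble(network_forward(model, x))
}

#' @export
predict_probabilities.fuco_margin <- function(model, features) {
  x <- feature_matrix(features)
  if (is.null(rownames(x))) rownames(x) <- seq_len(nrow(x))
  pred <- predict(model$fit, x, probability = TRUE)
  raw <- attr(pred, "probabilities")
  out <- matrix(0, nrow(x), length(model$class_order),
                dimnames = list(NULL, model$class_order))
  out[, colnames(raw)] <- raw
  tibble::as_tibble(out)
}

#' @export
predict_probabilities.default <- function(model, features) {
  abort("`model` must be a fitted fuco_model.")
}

#' Hard class call from class probabilities
#'
#' The argmax of each probability row; ties are broken deterministically in
#' favour of the earliest class in the fixed order `none`, `core`, `outer`,
#' `dual`.
#'
#' @param probs A probability tibble/matrix with the four class columns (as
#'   returned by [predict_probabilities()]).
#' @return A factor with levels `fuco_classes()`.
#' @export
classify <- function(probs) {
  p <- prob_matrix(probs)
  factor(FUCO_CLASSES[apply(p, 1, which.max)], levels = FUCO_CLASSES)
}

prob_matrix <- function(probs) {
  if (is.data.frame(probs)) probs <- as.matrix(probs)
  if (is.null(dim(probs))) probs <- matrix(probs, nrow = 1)
  missing_cols <- setdiff(FUCO_CLASSES, colnames(probs) %||% character(0))
  if (length(missing_cols) == 0) {
    probs <- probs[, FUCO_CLASSES, drop = FALSE]
  } else if (ncol(probs) != length(FUCO_CLASSES)) {
    abort("Probability table must have one column per fucosylation class.")
  }
  probs
}

#' Predict method for fucotyper models
#'
#' @param object A fitted `fuco_model`.
#' @param newdata A feature tibble or matrix.
#' @param type `"class"` for hard calls, `"prob"` for the probability
#'   simplex.
#' @param ... Unused.
#' @return A factor (`type = "class"`) or probability tibble
#'   (`type = "prob"`).
#' @export
predict.fuco_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  probs <- predict_probabilities(object, newdata)
  if (type == "prob") probs else classify(probs)
}

#' @export
print.fuco_model <- function(x, ...) {
  if (x$family == "network") {
    cat(sprintf(
      "<fucotyper network model> %d hidden layers x %d nodes, %d epochs, lr %.3g, dropout keep %.2f, seed %d\n",
      x$spec$n_layers, x$spec$n_nodes, x$spec$epochs,
      x$spec$learning_rate, x$spec$dropout_keep, x$spec$seed
    ))
  } else {
    cat(sprintf(
      "<fucotyper margin model> linear SVM, cost %.4g, seed %d\n",
      x$spec$cost, x$spec$seed
    ))
  }
  invisible(x)
}
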