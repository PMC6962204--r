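#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for fucotyper objects
#'
#' Broom-style methods. For fitted models, `tidy()` returns the
#' hyperparameters as a long tibble and `glance()` a one-row summary. For a
#' `fuco_roc`, `tidy()` returns the ROC curve and `glance()` the AUC. For a
#' `fuco_eval`, `tidy()` returns the confusion matrix in long form and
#' `glance()` the headline metrics.
#'
#' @param x The object to tidy.
#' @param ... Unused.
#' @return A tibble.
#' @name fucotyper-tidiers
NULL

#' @rdname fucotyper-tidiers
#' @export
tidy.fuco_model <- function(x, ...) {
  spec <- x$spec
  if (inherits(spec, "fuco_network_spec")) spec <- unclass(spec)
  tibble(
    term = names(spec),
    value = vapply(spec, function(v) as.character(v), character(1))
  )
}

#' @rdname fucotyper-tidiers
#' @export
glance.fuco_model <- function(x, ...) {
  if (x$family == "network") {
    n_par <- sum(vapply(x$weights, length, numeric(1))) +
      sum(vapply(x$biases, length, numeric(1)))
    tibble(family = "network", n_nodes = x$spec$n_nodes,
           n_layers = x$spec$n_layers, epochs = x$spec$epochs,
           seed = x$spec$seed, n_parameters = n_par)
  } else {
    tibble(family = "margin", cost = x$spec$cost, seed = x$spec$seed,
           n_support_vectors = x$fit$tot.nSV)
  }
}

#' @rdname fucotyper-tidiers
#' @export
tidy.fuco_roc <- function(x, ...) x$curve

#' @rdname fucotyper-tidiers
#' @export
glance.fuco_roc <- function(x, ...) tibble(auc = x$auc)

#' @rdname fucotyper-tidiers
#' @export
tidy.fuco_eval <- function(x, ...) {
  out <- as.data.frame(x$confusion, stringsAsFactors = FALSE)
  names(out) <- c("manual", "predicted", "n")
  tibble::as_tibble(out)
}

#' @rdname fucotyper-tidiers
#' @export
glance.fuco_eval <- function(x, ...) {
  tibble(accuracy = x$accuracy, sensitivity = x$sensitivity,
         n = x$n, n_classified = x$n_classified)
}
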