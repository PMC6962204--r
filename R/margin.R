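## The margin model family: a linear soft-margin multiclass SVM
## (C-classification, one-vs-one with pairwise-coupled probability
## calibration) fitted via e1071. The seed feeds the internal
## cross-validation split used by the probability calibration.

#' Train a linear SVM fucosylation classifier
#'
#' Fits one candidate of the margin family: a C-classification SVM with a
#' linear kernel and probability calibration, at a given soft-margin cost
#' and seed. Features are already bounded in \[0, 1\], so no rescaling is
#' applied.
#'
#' @param features A feature tibble or matrix with the 14 ion columns.
#' @param labels Fucosylation labels, one per row.
#' @param cost Positive soft-margin cost.
#' @param seed Integer seed (controls the probability-calibration split).
#' @return A fitted model of class `c("fuco_margin", "fuco_model")`.
#' @export
train_margin <- function(features, labels, cost = 1, seed = 1L) {
  if (cost <= 0) abort("`cost` must be > 0.")
  x <- feature_matrix(features)
  y <- as_fuco_factor(labels)
  if (nrow(x) == 0) abort("Cannot train on an empty feature set.")
  if (anyNA(y)) abort("Training labels must not contain missing values.")
  y <- droplevels(y)
  fit <- withr::with_seed(as.integer(seed), {
    e1071::svm(
      x = x, y = y, type = "C-classification", kernel = "linear",
      cost = cost, probability = TRUE, scale = FALSE
    )
  })
  structure(
    list(
      family = "margin",
      spec = list(cost = cost, seed = as.integer(seed), kernel = "linear"),
      fit = fit,
      class_order = FUCO_CLASSES
    ),
    class = c("fuco_margin", "fuco_model")
  )
}

#' Train the margin family over a cost-by-seed grid
#'
#' Fits one [train_margin()] model per (cost, seed) pair.
#'
#' @param features,labels Training data as in [train_margin()].
#' @param costs Positive cost values (default [default_cost_grid()]).
#' @param seeds Integer seeds (default 1..20).
#' @return A list of fitted `fuco_margin` models, ordered as
#'   `margin_grid(costs, seeds)`.
#' @export
train_margin_grid <- function(features, labels, costs = default_cost_grid(),
                              seeds = 1:20) {
  grid <- margin_grid(costs, seeds)
  purrr::pmap(grid, function(cost, seed) {
    train_margin(features, labels, cost = cost, seed = seed)
  })
}
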