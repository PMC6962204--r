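#' Hyperparameter grids for the two model families
#'
#' `network_grid()` enumerates the neural-network candidates: every
#' combination of node count \{8, 16, 32, 64, 128\}, hidden-layer count
#' \{3, 4, 5\} and epoch count \{10, 100, 500, 1000, 2000, 5000, 10000,
#' 20000\}, each replicated `replicates` times with a distinct seed —
#' 1,200 candidates at the defaults. `margin_grid()` enumerates the linear
#' SVM candidates as the cross of `costs` and `seeds` — 52 x 20 = 1,040 at
#' the defaults.
#'
#' @param nodes,layers,epochs Grid values for the network family.
#' @param replicates Seeded replicates per architecture.
#' @param learning_rate,dropout_keep Training constants (defaults 0.02 and
#'   keep probability 0.75).
#' @param base_seed First seed; replicate `r` of an architecture uses
#'   `base_seed + r - 1`.
#' @return A tibble with one row per candidate model specification.
#' @export
#' @examples
#' nrow(network_grid())  # 1200
#' nrow(margin_grid())   # 1040
network_grid <- function(nodes = c(8, 16, 32, 64, 128),
                         layers = c(3, 4, 5),
                         epochs = c(10, 100, 500, 1000, 2000, 5000, 10000, 20000),
                         replicates = 10,
                         learning_rate = 0.02,
                         dropout_keep = 0.75,
                         base_seed = 1L) {
  grid <- tidyr::expand_grid(
    n_nodes = nodes, n_layers = layers, epochs = epochs,
    replicate = seq_len(replicates)
  )
  dplyr::mutate(grid,
    learning_rate = learning_rate,
    dropout_keep = dropout_keep,
    seed = base_seed + .data$replicate - 1L
  )
}

#' @rdname network_grid
#' @param costs Cost values for the margin (SVM) family; defaults to
#'   [default_cost_grid()].
#' @param seeds Integer seeds (default 1..20); each (cost, seed) pair is one
#'   candidate.
#' @export
margin_grid <- function(costs = default_cost_grid(), seeds = 1:20) {
  if (length(costs) == 0) abort("Cost grid must be non-empty.")
  if (any(costs <= 0)) abort("All cost values must be > 0.")
  tidyr::expand_grid(cost = costs, seed = as.integer(seeds))
}

#' @rdname network_grid
#' @details `default_cost_grid()` is the union of four successively narrower
#'   search stages — powers of two from 2^-5 to 2^15, then 2^0..2^6, then the
#'   integers 4..16, then 8.0..11.0 in steps of 0.1 — deduplicated to 52
#'   distinct cost values.
#' @export
default_cost_grid <- function() {
  stages <- c(
    2^c(-5, -3, -1, 0, 1, 3, 5, 7, 9, 11, 13, 15),
    2^(0:6),
    4:16,
    seq(8, 11, by = 0.1)
  )
  sort(unique(round(stages, 6)))
}

#' Neural-network model specification
#'
#' One candidate of the network family: a fully connected net with 14
#' inputs, `n_layers` hidden layers of `n_nodes` rectified linear units and
#' a 4-class softmax output, trained by full-batch gradient descent with
#' inverted dropout.
#'
#' @param n_nodes Hidden-layer width.
#' @param n_layers Number of hidden layers.
#' @param epochs Gradient-descent steps (0 leaves the Xavier-initialised
#'   weights untrained).
#' @param learning_rate Step size (default 0.02).
#' @param dropout_keep Keep probability of hidden units during training
#'   (default 0.75; 1 disables dropout).
#' @param seed Integer seed controlling initialisation and dropout masks.
#' @return A list of class `fuco_network_spec`.
#' @export
network_spec <- function(n_nodes = 64, n_layers = 4, epochs = 2000,
                         learning_rate = 0.02, dropout_keep = 0.75,
                         seed = 1L) {
  if (n_nodes < 1 || n_layers < 1) abort("Network needs >= 1 node and >= 1 hidden layer.")
  if (epochs < 0) abort("`epochs` must be >= 0.")
  if (dropout_keep <= 0 || dropout_keep > 1) abort("`dropout_keep` must be in (0, 1].")
  structure(
    list(n_nodes = as.integer(n_nodes), n_layers = as.integer(n_layers),
         epochs = as.integer(epochs), learning_rate = learning_rate,
         dropout_keep = dropout_keep, seed = as.integer(seed)),
    class = "fuco_network_spec"
  )
}
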