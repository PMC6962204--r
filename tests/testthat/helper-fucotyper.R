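# Shared fixtures and independent oracles, built in code.

# All-pairs brute-force Mann-Whitney AUC (independent of the rank-based
# implementation under test).
brute_force_auc <- function(target, decoy) {
  pairs <- outer(target, decoy, function(t, d) (t > d) + 0.5 * (t == d))
  mean(pairs)
}

# Exhaustive threshold-search FDR cutoff oracle.
brute_force_fdr_cutoff <- function(target, decoy, q) {
  best <- list(cutoff = Inf, n_filtered = 0L)
  for (t in sort(unique(target))) {
    fdr <- sum(decoy >= t) / max(1, sum(target >= t))
    if (fdr < q) {
      return(list(cutoff = t, n_filtered = sum(target >= t)))
    }
  }
  best
}

# Linearly separable 4-class toy features: one indicator ion per class.
separable_features <- function(n_per_class = 12, seed = 42) {
  classes <- fuco_classes()
  marker <- c(none = "Y1", core = "Y1F", outer = "B2F", dual = "B3SF")
  withr::with_seed(seed, {
    rows <- lapply(rep(classes, each = n_per_class), function(cl) {
      v <- stats::setNames(as.list(stats::runif(14, 0, 0.05)), ion_labels())
      v[[marker[[cl]]]] <- stats::runif(1, 0.8, 1)
      tibble::as_tibble(v)
    })
    feats <- dplyr::bind_rows(rows)
    feats$label <- factor(rep(classes, each = n_per_class),
                          levels = classes)
    feats
  })
}

# A small labelled synthetic cohort with a train/test split.
small_cohort <- function(n = 80, seed = 7) {
  generate_dataset(n = n, seed = seed, test_fraction = 0.4)
}

# A fast pipeline configuration (smoke-sized grids).
smoke_config <- function(ds, seed = 3, out_dir = NULL) {
  pipeline_config(
    spectra = ds$spectra, gsm = ds$gsm, out_dir = out_dir,
    network = network_grid(nodes = 16, layers = 3, epochs = 400,
                           replicates = 1, base_seed = 9),
    margin = margin_grid(costs = 1, seeds = 435),
    seed = seed
  )
}

random_probs <- function(n, seed = 1) {
  withr::with_seed(seed, {
    p <- matrix(stats::rexp(n * 4), n, 4)
    p <- p / rowSums(p)
    colnames(p) <- fuco_classes()
    tibble::as_tibble(p)
  })
}
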