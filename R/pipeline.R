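#' Pipeline configuration
#'
#' Bundles every tunable of the train/classify pipeline: input paths (or
#' in-memory tables), extraction parameters, the two model-family grids, the
#' decoy and FDR settings and the consensus rule. The defaults reproduce the
#' full search grids (1,200 network and 1,040 margin candidates).
#'
#' @param mgf_path,gsm_path Input file paths (MGF spectra and GSM TSV).
#'   Ignored when `spectra` / `gsm` tibbles are supplied directly.
#' @param spectra,gsm Optional in-memory inputs (as from [read_mgf()],
#'   [read_gsm_table()] or [generate_dataset()]).
#' @param out_dir Output directory; `NULL` disables file output.
#' @param extraction An [extraction_params()] object.
#' @param network A [network_grid()] tibble of network candidates.
#' @param margin A [margin_grid()] tibble of margin candidates.
#' @param fdr_q Target false discovery rate for Pscore filtering.
#' @param decoy_repeats Number of decoy replicates to average over.
#' @param decoy_method `"spectrum"` (default): rearrange intensities among
#'   each spectrum's peaks and re-extract features
#'   ([make_spectrum_decoys()]); `"features"`: permute the 14 extracted
#'   feature values within each vector ([make_decoys()]).
#' @param consensus_rule `"union"` or `"intersection"` (see [consensus()]).
#' @param seed Master seed for decoy generation.
#' @return A list of class `fuco_config`.
#' @export
pipeline_config <- function(mgf_path = NULL, gsm_path = NULL,
                            spectra = NULL, gsm = NULL, out_dir = NULL,
                            extraction = extraction_params(),
                            network = network_grid(),
                            margin = margin_grid(),
                            fdr_q = 0.01, decoy_repeats = 5,
                            decoy_method = c("spectrum", "features"),
                            consensus_rule = c("union", "intersection"),
                            seed = 1L) {
  structure(
    list(
      mgf_path = mgf_path, gsm_path = gsm_path,
      spectra = spectra, gsm = gsm, out_dir = out_dir,
      extraction = extraction, network = network, margin = margin,
      fdr_q = fdr_q, decoy_repeats = decoy_repeats,
      decoy_method = match.arg(decoy_method),
      consensus_rule = match.arg(consensus_rule), seed = as.integer(seed)
    ),
    class = "fuco_config"
  )
}

load_inputs <- function(config) {
  spectra <- config$spectra %||% read_mgf(config$mgf_path)
  gsm <- config$gsm %||% read_gsm_table(config$gsm_path)
  list(spectra = spectra, gsm = gsm)
}

config_hash <- function(config) {
  rlang::hash(config[setdiff(names(config), c("spectra", "gsm", "out_dir"))])
}

provenance_header <- function(config) {
  c(
    sprintf("# fucotyper %s", as.character(utils::packageVersion("fucotyper"))),
    sprintf("# config_hash=%s", config_hash(config)),
    sprintf("# seed=%d fdr_q=%g decoy_repeats=%d consensus_rule=%s",
            config$seed, config$fdr_q, config$decoy_repeats,
            config$consensus_rule)
  )
}

write_result_tsv <- function(tbl, path, config) {
  out <- dplyr::mutate(tbl, dplyr::across(dplyr::where(is.factor), as.character))
  writeLines(provenance_header(config), path)
  suppressWarnings(readr::write_tsv(out, path, append = TRUE,
                                    col_names = TRUE, progress = FALSE))
  invisible(path)
}

build_decoy_sets <- function(features, spectra, config) {
  if (config$decoy_method == "spectrum") {
    make_spectrum_decoys(features, spectra, config$decoy_repeats,
                         config$seed, config$extraction)
  } else {
    make_decoys(features, config$decoy_repeats, config$seed)
  }
}

## Evaluate one fitted model on a labelled feature set: accuracy vs manual
## labels, target-decoy AUC on mean decoy Pscores, Euclidean length and the
## Pscore cutoff at config$fdr_q.
assess_model <- function(model, features, decoy_sets, config) {
  probs <- predict_probabilities(model, features)
  pred <- classify(probs)
  target <- pscore(probs)
  decoy <- decoy_pscores(model, decoy_sets)
  acc <- mean(pred == features$label)
  roc <- roc_auc(target, decoy)
  cut <- fdr_cutoff(target, decoy, config$fdr_q)
  model_performance(acc, roc$auc, cut$cutoff, cut$n_filtered)
}

#' Train both model families and select the best of each
#'
#' Extracts features for a labelled GSM set, splits it into training and
#' test subsets on the `source` column (`source == "test"` is held out; the
#' paper-style split by acquisition set rather than at random), fits every
#' candidate in the network and margin grids, assesses each on the test set
#' (accuracy, target-decoy AUC from `decoy_repeats` shuffled replicates,
#' Pscore cutoff at `fdr_q`), and keeps the candidate with the longest
#' Euclidean length per family.
#'
#' @param config A [pipeline_config()]. The GSM table must carry labels and
#'   a `source` column with at least one `"test"` row.
#' @return A list of class `fuco_bundle`: the two winning models
#'   (`network`, `margin`), the full `performance` table and the selection
#'   indices. When `config$out_dir` is set, the bundle (RDS) and performance
#'   table (TSV with provenance header) are written there.
#' @export
run_train <- function(config) {
  inputs <- load_inputs(config)
  gsm <- inputs$gsm
  if (nrow(gsm) == 0) abort("Training requires a non-empty GSM table.")
  if (all(is.na(gsm$label))) {
    abort("Training requires manual labels; for unlabeled data run run_classify() with an existing bundle.")
  }
  if (anyNA(gsm$label)) abort("Every training GSM must carry a manual label.")
  features <- extract_features(gsm, inputs$spectra, config$extraction)
  is_test <- !is.na(features$source) & features$source == "test"
  if (!any(is_test) || all(is_test)) {
    abort("The GSM `source` column must mark a non-empty strict subset as \"test\".")
  }
  train_f <- features[!is_test, , drop = FALSE]
  test_f <- features[is_test, , drop = FALSE]
  decoy_sets <- build_decoy_sets(test_f, inputs$spectra, config)

  net_perf <- purrr::map(seq_len(nrow(config$network)), function(i) {
    g <- config$network[i, ]
    spec <- network_spec(g$n_nodes, g$n_layers, g$epochs,
                         g$learning_rate, g$dropout_keep, g$seed)
    model <- train_network(train_f, train_f$label, spec)
    perf <- assess_model(model, test_f, decoy_sets, config)
    list(model = model, perf = dplyr::bind_cols(
      tibble(family = "network", candidate = i,
             n_nodes = g$n_nodes, n_layers = g$n_layers,
             epochs = g$epochs, cost = NA_real_, seed = g$seed),
      perf
    ))
  })
  svm_perf <- purrr::map(seq_len(nrow(config$margin)), function(i) {
    g <- config$margin[i, ]
    model <- train_margin(train_f, train_f$label, cost = g$cost, seed = g$seed)
    perf <- assess_model(model, test_f, decoy_sets, config)
    list(model = model, perf = dplyr::bind_cols(
      tibble(family = "margin", candidate = i,
             n_nodes = NA_real_, n_layers = NA_real_, epochs = NA_real_,
             cost = g$cost, seed = g$seed),
      perf
    ))
  })

  net_tbl <- dplyr::bind_rows(purrr::map(net_perf, "perf"))
  svm_tbl <- dplyr::bind_rows(purrr::map(svm_perf, "perf"))
  best_net <- select_best_model(net_tbl)
  best_svm <- select_best_model(svm_tbl)
  bundle <- structure(
    list(
      network = net_perf[[best_net]]$model,
      margin = svm_perf[[best_svm]]$model,
      performance = dplyr::bind_rows(net_tbl, svm_tbl),
      best = list(network = best_net, margin = best_svm),
      config_hash = config_hash(config)
    ),
    class = "fuco_bundle"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    saveRDS(bundle, file.path(config$out_dir, "model_bundle.rds"), version = 3)
    write_result_tsv(bundle$performance,
                     file.path(config$out_dir, "performance.tsv"), config)
  }
  bundle
}

#' @export
print.fuco_bundle <- function(x, ...) {
  cat("<fucotyper model bundle>\n")
  print(x$network)
  print(x$margin)
  best <- dplyr::group_by(x$performance, .data$family)
  best <- dplyr::slice_max(best, .data$euclidean_length, n = 1, with_ties = FALSE)
  print(dplyr::select(dplyr::ungroup(best), "family", "accuracy", "auc",
                      "euclidean_length", "pscore_cutoff", "n_filtered"))
  invisible(x)
}

#' Classify a GSM set and build the consensus table
#'
#' Applies both winning models to a (labelled or unlabeled) GSM set:
#' computes class probabilities and Pscores, builds per-set decoys, derives
#' each model's Pscore cutoff at `fdr_q` on this same set, and forms the
#' consensus classification (see [consensus()]). When manual labels are
#' present, evaluation metrics are added.
#'
#' @param config A [pipeline_config()].
#' @param bundle A fitted `fuco_bundle` from [run_train()].
#' @return A list of class `fuco_classification` with `results` (per-GSM
#'   tibble), `cutoffs`, `summary` (consensus counts by class and
#'   antennarity) and, for labelled input, `metrics` (a `fuco_eval`). With
#'   `config$out_dir` set, `results.tsv` and `summary.tsv` are written with
#'   a provenance header.
#' @export
run_classify <- function(config, bundle) {
  inputs <- load_inputs(config)
  gsm <- inputs$gsm
  if (nrow(gsm) == 0) {
    empty <- consensus(
      tibble(title = character(), class = factor(levels = FUCO_CLASSES),
             pscore = numeric()),
      tibble(title = character(), class = factor(levels = FUCO_CLASSES),
             pscore = numeric()),
      cutoffs = list(dnn = Inf, svm = Inf), rule = config$consensus_rule
    )
    return(structure(
      list(results = empty, cutoffs = list(dnn = Inf, svm = Inf),
           summary = tibble(), metrics = NULL),
      class = "fuco_classification"
    ))
  }
  features <- extract_features(gsm, inputs$spectra, config$extraction)
  decoy_sets <- build_decoy_sets(features, inputs$spectra, config)

  per_model <- lapply(
    list(dnn = bundle$network, svm = bundle$margin),
    function(model) {
      probs <- predict_probabilities(model, features)
      target <- pscore(probs)
      decoy <- decoy_pscores(model, decoy_sets)
      cut <- fdr_cutoff(target, decoy, config$fdr_q)
      list(
        results = tibble(title = features$title, class = classify(probs),
                         pscore = target),
        cutoff = cut$cutoff
      )
    }
  )
  cutoffs <- list(dnn = per_model$dnn$cutoff, svm = per_model$svm$cutoff)
  cons <- consensus(per_model$dnn$results, per_model$svm$results,
                    cutoffs, rule = config$consensus_rule)
  results <- dplyr::left_join(
    dplyr::select(features, dplyr::any_of(c("title", "glycopeptide_id",
                                            "label", "source"))),
    cons, by = "title"
  )
  comp <- parse_glycopeptide_id(results$glycopeptide_id)
  results$antennarity <- antennarity_class(comp$n_hex, comp$n_hexnac)
  summary_tbl <- dplyr::count(
    dplyr::filter(results, !is.na(.data$consensus_class)),
    .data$antennarity, .data$consensus_class, name = "n_gsm"
  )
  metrics <- NULL
  if (!all(is.na(results$label))) {
    metrics <- evaluate(results$consensus_class, results$label)
  }
  out <- structure(
    list(results = results, cutoffs = cutoffs, summary = summary_tbl,
         metrics = metrics),
    class = "fuco_classification"
  )
  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_result_tsv(results, file.path(config$out_dir, "results.tsv"), config)
    write_result_tsv(summary_tbl, file.path(config$out_dir, "summary.tsv"), config)
  }
  out
}

#' @export
print.fuco_classification <- function(x, ...) {
  n <- nrow(x$results)
  n_cons <- sum(!is.na(x$results$consensus_class))
  cat(sprintf(
    "<fucotyper classification> %d GSMs, %d consensus-classified (Pscore cutoffs: dnn %.3f, svm %.3f)\n",
    n, n_cons, x$cutoffs$dnn, x$cutoffs$svm
  ))
  if (n_cons > 0) print(table(x$results$consensus_class))
  if (!is.null(x$metrics)) print(x$metrics)
  invisible(x)
}

#' Evaluate a classification against manual labels
#'
#' Joins a results table to a manually labelled GSM table by `title` and
#' computes accuracy, sensitivity, the 4x4 confusion matrix and per-class
#' consensus counts.
#'
#' @param classification A `fuco_classification` from [run_classify()], or
#'   its `results` tibble.
#' @param manual A GSM tibble with `title` and `label` columns.
#' @return A list with `accuracy`, `sensitivity`, `confusion`,
#'   `class_counts` and `n`.
#' @export
run_evaluate <- function(classification, manual) {
  results <- if (inherits(classification, "fuco_classification")) {
    classification$results
  } else {
    classification
  }
  merged <- dplyr::inner_join(
    dplyr::select(results, "title", "consensus_class"),
    dplyr::select(manual, "title", manual_label = "label"),
    by = "title"
  )
  if (nrow(merged) == 0) abort("No overlapping titles between results and manual labels.")
  ev <- evaluate(merged$consensus_class, merged$manual_label)
  list(
    accuracy = ev$accuracy, sensitivity = ev$sensitivity,
    confusion = ev$confusion,
    class_counts = as.list(table(merged$consensus_class)),
    n = ev$n, n_classified = ev$n_classified
  )
}
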