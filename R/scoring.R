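#' Pscore: confidence from the top-two probability gap
#'
#' `Pscore = -ln(1 - (P1 - P2))`, where P1 and P2 are the highest and
#' second-highest class probabilities of a prediction. The gap is clamped at
#' `1 - 1e-12`, so the score is finite, non-negative and capped at
#' `-ln(1e-12) ~ 27.63`. A flat top pair (P1 = P2) scores 0; the score is
#' strictly increasing in the gap.
#'
#' @param probs A probability tibble/matrix (rows summing to 1 over the four
#'   class columns), as from [predict_probabilities()].
#' @return A non-negative numeric vector, one score per row.
#' @export
#' @examples
#' pscore(tibble::tibble(none = 0.9, core = 0.1, outer = 0, dual = 0))
pscore <- function(probs) {
  p <- prob_matrix(probs)
  gap <- apply(p, 1, function(row) {
    s <- sort(row, decreasing = TRUE)
    s[1] - s[2]
  })
  gap <- pmin(gap, 1 - 1e-12)
  -log(1 - gap)
}

#' Per-spectrum feature-shuffle decoys
#'
#' Builds decoy feature sets by permuting the 14 diagnostic-ion values
#' within each GSM's feature vector, uniformly at random. Each vector's
#' multiset of values is conserved exactly; only the assignment of values to
#' ion slots is scrambled. Generation is seeded and reproducible.
#'
#' @param features A feature tibble with the 14 ion columns (other columns
#'   are carried through unchanged).
#' @param n_repeats Number of independent decoy replicates (default 5).
#' @param seed Integer seed.
#' @return A list of `n_repeats` tibbles shaped like `features`.
#' @export
make_decoys <- function(features, n_repeats = 5, seed = 1L) {
  if (n_repeats < 1) abort("`n_repeats` must be >= 1.")
  x <- feature_matrix(features)
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_repeats), function(r) {
      shuffled <- t(apply(x, 1, sample))
      colnames(shuffled) <- ION_LABELS
      out <- features
      out[, ION_LABELS] <- tibble::as_tibble(shuffled)
      out
    })
  })
}

#' Spectrum-level decoys
#'
#' Builds decoy feature sets by randomly rearranging the intensity values
#' among the peaks of each spectrum (the peak m/z positions stay fixed) and
#' re-running feature extraction. A diagnostic m/z window then carries the
#' intensity of a randomly chosen peak — usually a noise peak — so decoy
#' vectors are sparse and incoherent while each spectrum's intensity
#' multiset (and hence its noise estimate and base peak) is conserved. This
#' is the decoy construction the classification pipeline uses by default;
#' [make_decoys()] permutes the already-extracted 14 feature values instead.
#'
#' @param gsm A GSM tibble.
#' @param spectra The matching spectra tibble.
#' @param n_repeats Number of decoy replicates (default 5).
#' @param seed Integer seed.
#' @param params [extraction_params()] used for re-extraction.
#' @return A list of `n_repeats` feature tibbles aligned with `gsm`.
#' @export
make_spectrum_decoys <- function(gsm, spectra, n_repeats = 5, seed = 1L,
                                 params = extraction_params()) {
  if (n_repeats < 1) abort("`n_repeats` must be >= 1.")
  gsm <- dplyr::select(gsm, !dplyr::any_of(ION_LABELS))
  withr::with_seed(as.integer(seed), {
    lapply(seq_len(n_repeats), function(r) {
      shuffled <- spectra
      shuffled$peaks <- lapply(shuffled$peaks, function(pk) {
        pk$intensity <- sample(pk$intensity)
        pk
      })
      extract_features(gsm, shuffled, params)
    })
  })
}

#' Mean decoy Pscore per GSM
#'
#' Applies a fitted model to each decoy replicate and averages the resulting
#' Pscores per GSM across replicates.
#'
#' @param model A fitted `fuco_model`.
#' @param decoy_sets A list of decoy feature tibbles from [make_decoys()].
#' @return A numeric vector of per-GSM mean decoy Pscores.
#' @export
decoy_pscores <- function(model, decoy_sets) {
  scores <- vapply(
    decoy_sets,
    function(d) pscore(predict_probabilities(model, d)),
    numeric(nrow(decoy_sets[[1]]))
  )
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1)
  rowMeans(scores)
}

#' Target-decoy ROC curve and AUC
#'
#' Treats target scores as positives and decoy scores as negatives. The AUC
#' is the Mann-Whitney statistic (probability that a random target outscores
#' a random decoy, ties counted half), computed from ranks; the curve is the
#' standard ROC polygon from (0,0) to (1,1).
#'
#' @param target_scores,decoy_scores Non-empty numeric score vectors.
#' @return An object of class `fuco_roc`: a list with `auc` and `curve` (a
#'   tibble of `fpr`, `tpr`).
#' @export
roc_auc <- function(target_scores, decoy_scores) {
  if (length(target_scores) == 0 || length(decoy_scores) == 0) {
    abort("Both score lists must be non-empty.")
  }
  nt <- length(target_scores)
  nd <- length(decoy_scores)
  r <- rank(c(target_scores, decoy_scores))
  auc <- (sum(r[seq_len(nt)]) - nt * (nt + 1) / 2) / (nt * nd)
  thresholds <- sort(unique(c(target_scores, decoy_scores)), decreasing = TRUE)
  curve <- tibble(
    fpr = c(0, vapply(thresholds, function(t) mean(decoy_scores >= t), numeric(1)), 1),
    tpr = c(0, vapply(thresholds, function(t) mean(target_scores >= t), numeric(1)), 1)
  )
  curve <- dplyr::distinct(curve)
  structure(list(auc = auc, curve = curve), class = "fuco_roc")
}

#' @export
print.fuco_roc <- function(x, ...) {
  cat(sprintf("<fucotyper target-decoy ROC> AUC = %.4f (%d curve points)\n",
              x$auc, nrow(x$curve)))
  invisible(x)
}

#' Pscore cutoff at a target false discovery rate
#'
#' Estimates, for each candidate threshold `t` (the observed target scores),
#' `FDR(t) = #\{decoy >= t\} / max(1, #\{target >= t\})`, and returns the
#' smallest target score whose estimated FDR is below `q`, together with the
#' number of targets at or above it. If no threshold qualifies, the cutoff
#' is `Inf` and nothing is filtered in.
#'
#' @param target_scores Non-empty numeric vector of target Pscores.
#' @param decoy_scores Numeric vector of decoy Pscores.
#' @param q Target FDR in (0, 1); default 0.01.
#' @return A list with `cutoff` and `n_filtered`.
#' @export
fdr_cutoff <- function(target_scores, decoy_scores, q = 0.01) {
  if (length(target_scores) == 0) abort("`target_scores` must be non-empty.")
  if (q <= 0 || q >= 1) abort("`q` must be in (0, 1).")
  candidates <- sort(unique(target_scores))
  for (t in candidates) {
    fdr <- sum(decoy_scores >= t) / max(1, sum(target_scores >= t))
    if (fdr < q) {
      return(list(cutoff = t, n_filtered = sum(target_scores >= t)))
    }
  }
  list(cutoff = Inf, n_filtered = 0L)
}

#' Model performance and Euclidean-length selection
#'
#' `model_performance()` assembles one performance row (the Euclidean length
#' is `sqrt(accuracy^2 + auc^2)`); `select_best_model()` returns the index
#' of the row with the longest Euclidean length, ties going to the lowest
#' index.
#'
#' @param accuracy Test-set classification accuracy in \[0, 1\].
#' @param auc Target-decoy AUC in \[0, 1\].
#' @param pscore_cutoff Pscore cutoff at the FDR threshold.
#' @param n_filtered Number of GSMs passing the cutoff.
#' @return `model_performance()`: a one-row tibble with an added
#'   `euclidean_length` column.
#' @export
model_performance <- function(accuracy, auc, pscore_cutoff = NA_real_,
                              n_filtered = NA_integer_) {
  tibble(
    accuracy = accuracy, auc = auc,
    euclidean_length = sqrt(accuracy^2 + auc^2),
    pscore_cutoff = pscore_cutoff, n_filtered = n_filtered
  )
}

#' @rdname model_performance
#' @param performances A tibble with an `euclidean_length` column (or
#'   `accuracy` and `auc` columns from which it is computed).
#' @return `select_best_model()`: the integer index of the best row.
#' @export
select_best_model <- function(performances) {
  if (nrow(performances) == 0) abort("`performances` must be non-empty.")
  el <- performances$euclidean_length %||%
    sqrt(performances$accuracy^2 + performances$auc^2)
  which.max(el)
}

#' Consensus classification across the two model families
#'
#' A GSM receives a consensus class when (a) it passes the FDR-based Pscore
#' filter — by default in at least one of the two models (the union rule;
#' `rule = "intersection"` requires both) — and (b) both models predict the
#' same class. GSMs failing either condition get `NA`.
#'
#' @param dnn_results,svm_results Tibbles with columns `title`, `class`,
#'   `pscore` covering the same GSM set.
#' @param cutoffs Named list with elements `dnn` and `svm`, the per-model
#'   Pscore cutoffs.
#' @param rule `"union"` (default) or `"intersection"`.
#' @return A tibble with `title`, per-model classes/Pscores/pass flags and
#'   `consensus_class`.
#' @export
consensus <- function(dnn_results, svm_results, cutoffs,
                      rule = c("union", "intersection")) {
  rule <- match.arg(rule)
  if (nrow(dnn_results) == 0 && nrow(svm_results) == 0) {
    return(tibble(
      title = character(), dnn_class = factor(levels = FUCO_CLASSES),
      dnn_pscore = numeric(), dnn_pass = logical(),
      svm_class = factor(levels = FUCO_CLASSES),
      svm_pscore = numeric(), svm_pass = logical(),
      consensus_class = factor(levels = FUCO_CLASSES)
    ))
  }
  if (!setequal(dnn_results$title, svm_results$title) ||
      nrow(dnn_results) != nrow(svm_results)) {
    abort("The two result tables must cover the same GSM titles.")
  }
  merged <- dplyr::inner_join(
    dplyr::rename(dnn_results, dnn_class = "class", dnn_pscore = "pscore"),
    dplyr::rename(svm_results, svm_class = "class", svm_pscore = "pscore"),
    by = "title"
  )
  merged <- dplyr::mutate(
    merged,
    dnn_pass = .data$dnn_pscore >= cutoffs$dnn,
    svm_pass = .data$svm_pscore >= cutoffs$svm,
    passed = if (rule == "union") .data$dnn_pass | .data$svm_pass
             else .data$dnn_pass & .data$svm_pass,
    consensus_class = dplyr::if_else(
      .data$passed & .data$dnn_class == .data$svm_class,
      .data$dnn_class, factor(NA, levels = FUCO_CLASSES)
    )
  )
  dplyr::select(merged, "title", "dnn_class", "dnn_pscore", "dnn_pass",
                "svm_class", "svm_pscore", "svm_pass", "consensus_class")
}

#' Evaluate predicted against manual classifications
#'
#' Accuracy is the fraction of all GSMs whose prediction matches the manual
#' class (an unclassified `NA` prediction counts as a miss). Sensitivity is
#' `TP / (TP + FN)` over the classified GSMs only, a correct class counting
#' as a true positive and an incorrect one as a false negative. The
#' confusion matrix (rows = manual, columns = predicted) covers classified
#' GSMs.
#'
#' @param predicted Predicted classes (factor or character; `NA` =
#'   unclassified).
#' @param manual Manual classes of the same length.
#' @return An object of class `fuco_eval`: a list with `accuracy`,
#'   `sensitivity`, `confusion`, `n`, `n_classified`.
#' @export
evaluate <- function(predicted, manual) {
  if (length(predicted) != length(manual)) {
    abort("`predicted` and `manual` must have equal length.")
  }
  predicted <- as_fuco_factor(predicted)
  manual <- as_fuco_factor(manual)
  n <- length(manual)
  classified <- !is.na(predicted)
  correct <- classified & predicted == manual
  tp <- sum(correct)
  fn <- sum(classified & predicted != manual)
  confusion <- table(
    manual = manual[classified], predicted = predicted[classified]
  )
  structure(
    list(
      accuracy = if (n > 0) tp / n else NaN,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NaN,
      confusion = confusion,
      n = n, n_classified = sum(classified)
    ),
    class = "fuco_eval"
  )
}

#' @export
print.fuco_eval <- function(x, ...) {
  cat(sprintf(
    "<fucotyper evaluation> %d GSMs (%d classified): accuracy %.4f, sensitivity %.4f\n",
    x$n, x$n_classified, x$accuracy, x$sensitivity
  ))
  print(x$confusion)
  invisible(x)
}
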