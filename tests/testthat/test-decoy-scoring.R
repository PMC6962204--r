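test_that("Pscore maps the top-two probability gap as -ln(1 - gap), clamped", {
  expect_equal(pscore(c(none = 0.5, core = 0.5, outer = 0, dual = 0)), 0)
  expect_equal(pscore(c(none = 0.9, core = 0.1, outer = 0, dual = 0)),
               -log(0.2), tolerance = 1e-9)
  expect_equal(pscore(c(none = 1, core = 0, outer = 0, dual = 0)),
               -log(1e-12), tolerance = 1e-6)
  # strictly increasing in the gap
  gaps <- seq(0, 0.999, length.out = 50)
  scores <- vapply(gaps, function(g) {
    p1 <- (1 + g) / 2
    pscore(c(none = p1, core = p1 - g, outer = 0, dual = 0))
  }, numeric(1))
  expect_true(all(diff(scores) > 0))
  expect_true(all(scores >= 0 & is.finite(scores)))
})

test_that("feature-shuffle decoys conserve each vector's value multiset", {
  ds <- small_cohort(n = 20, seed = 13)
  feats <- extract_features(ds$gsm, ds$spectra)
  decs <- make_decoys(feats, n_repeats = 5, seed = 99)
  expect_length(decs, 5)
  x <- as.matrix(feats[, ion_labels()])
  for (d in decs) {
    xd <- as.matrix(d[, ion_labels()])
    for (i in seq_len(nrow(x))) {
      expect_equal(sort(xd[i, ]), sort(x[i, ]), ignore_attr = TRUE)
    }
  }
  # seeded and reproducible; different replicates differ for generic vectors
  decs2 <- make_decoys(feats, n_repeats = 5, seed = 99)
  expect_identical(decs, decs2)
  expect_false(identical(decs[[1]], decs[[2]]))

  # a constant vector is invariant under permutation
  const <- feats[1, ]
  const[, ion_labels()] <- as.list(rep(0.3, 14))
  dc <- make_decoys(const, n_repeats = 1, seed = 1)[[1]]
  expect_equal(as.numeric(dc[1, ion_labels()]), rep(0.3, 14))
})

test_that("spectrum-shuffle decoys conserve each spectrum's intensity multiset", {
  ds <- small_cohort(n = 10, seed = 17)
  decs <- make_spectrum_decoys(ds$gsm, ds$spectra, n_repeats = 2, seed = 4)
  expect_length(decs, 2)
  expect_equal(nrow(decs[[1]]), nrow(ds$gsm))
  # decoy features are sparser than target features on average
  targ <- extract_features(ds$gsm, ds$spectra)
  expect_lt(mean(as.matrix(decs[[1]][, ion_labels()]) > 0),
            mean(as.matrix(targ[, ion_labels()]) > 0))
  expect_identical(decs, make_spectrum_decoys(ds$gsm, ds$spectra, 2, 4))
})

test_that("decoy Pscores average per GSM across replicates", {
  feats <- separable_features(n_per_class = 6)
  svm <- train_margin(feats, feats$label, cost = 1, seed = 1)
  decs <- make_decoys(feats, n_repeats = 1, seed = 2)
  single <- decoy_pscores(svm, decs)
  expect_equal(single, pscore(predict_probabilities(svm, decs[[1]])))
  decs5 <- make_decoys(feats, n_repeats = 5, seed = 2)
  manual_mean <- rowMeans(vapply(
    decs5, function(d) pscore(predict_probabilities(svm, d)),
    numeric(nrow(feats))
  ))
  expect_equal(decoy_pscores(svm, decs5), manual_mean)
})

test_that("ROC AUC equals the Mann-Whitney statistic with a valid curve", {
  expect_equal(roc_auc(c(3, 4), c(1, 2))$auc, 1)
  expect_equal(roc_auc(c(1, 2, 3), c(1, 2, 3))$auc, 0.5)
  expect_equal(roc_auc(c(2, 0), 1)$auc, 0.5)
  r <- roc_auc(rnorm(20), rnorm(20))
  expect_equal(r$curve$fpr[1], 0)
  expect_equal(r$curve$tpr[1], 0)
  expect_equal(r$curve$fpr[nrow(r$curve)], 1)
  expect_true(all(diff(r$curve$fpr) >= 0))
  expect_true(all(diff(r$curve$tpr) >= 0))
  expect_error(roc_auc(numeric(0), 1), "non-empty")
})

test_that("rank-based AUC agrees with the all-pairs oracle and pROC", {
  withr::with_seed(19, {
    for (i in 1:20) {
      nt <- sample(2:40, 1)
      nd <- sample(2:40, 1)
      t_sc <- round(rnorm(nt), sample(0:2, 1))
      d_sc <- round(rnorm(nd), sample(0:2, 1))
      expect_equal(roc_auc(t_sc, d_sc)$auc, brute_force_auc(t_sc, d_sc),
                   tolerance = 1e-12)
    }
  })
  t_sc <- c(3.2, 1.1, 4.8, 2.2, 2.2)
  d_sc <- c(0.5, 2.2, 1.0, 3.0)
  ext <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 5), rep(0, 4)), predictor = c(t_sc, d_sc),
    quiet = TRUE, direction = "<"
  )))
  expect_equal(roc_auc(t_sc, d_sc)$auc, ext, tolerance = 1e-12)
})

test_that("the FDR cutoff matches exhaustive threshold search", {
  res <- fdr_cutoff(c(5, 4, 3, 2), c(1, 0.5, 0.2, 0.1), q = 0.01)
  expect_equal(res$cutoff, 2)
  expect_equal(res$n_filtered, 4L)

  res2 <- fdr_cutoff(c(1, 1), c(5, 5), q = 0.01)
  expect_equal(res2$cutoff, Inf)
  expect_equal(res2$n_filtered, 0L)

  res3 <- fdr_cutoff(10, 1, q = 0.01)
  expect_equal(res3$cutoff, 10)
  expect_equal(res3$n_filtered, 1L)

  withr::with_seed(23, {
    for (i in 1:25) {
      t_sc <- round(rexp(sample(3:30, 1)), 2)
      d_sc <- round(rexp(sample(3:30, 1)), 2)
      q <- sample(c(0.01, 0.05, 0.2, 0.5), 1)
      expect_equal(fdr_cutoff(t_sc, d_sc, q),
                   brute_force_fdr_cutoff(t_sc, d_sc, q))
    }
  })
  expect_error(fdr_cutoff(numeric(0), 1), "non-empty")
})

test_that("more permissive FDR thresholds never filter fewer GSMs", {
  withr::with_seed(29, {
    t_sc <- rexp(50, 0.5)
    d_sc <- rexp(50, 2)
    ns <- vapply(c(0.01, 0.05, 0.1, 0.3, 0.6, 0.9),
                 function(q) fdr_cutoff(t_sc, d_sc, q)$n_filtered, integer(1))
    expect_true(all(diff(ns) >= 0))
    # near q = 1 every target above the minimum qualifies
    res <- fdr_cutoff(t_sc, d_sc, q = 0.999)
    expect_equal(res$cutoff, min(t_sc))
    expect_equal(res$n_filtered, length(t_sc))
  })
})

test_that("Euclidean-length selection picks the best accuracy-AUC pair", {
  expect_equal(model_performance(1, 1)$euclidean_length, sqrt(2))
  expect_equal(model_performance(0.6, 0.8)$euclidean_length, 1)
  perfs <- dplyr::bind_rows(
    model_performance(0.6, 0.8),
    model_performance(0.9, 0.92),
    model_performance(0.95, 0.85)
  )
  expect_equal(select_best_model(perfs), 2L)
  ties <- dplyr::bind_rows(model_performance(0.8, 0.6),
                           model_performance(0.6, 0.8))
  expect_equal(select_best_model(ties), 1L)
  expect_error(select_best_model(perfs[0, ]), "non-empty")
})

test_that("consensus requires class agreement within the filtered union", {
  dnn <- tibble::tibble(
    title = c("a", "b", "c", "d"),
    class = factor(c("core", "core", "outer", "none"), levels = fuco_classes()),
    pscore = c(5, 5, 0.1, 5)
  )
  svm <- tibble::tibble(
    title = c("a", "b", "c", "d"),
    class = factor(c("core", "outer", "outer", "none"), levels = fuco_classes()),
    pscore = c(5, 5, 0.2, 0.1)
  )
  cuts <- list(dnn = 1, svm = 1)
  out <- consensus(dnn, svm, cuts)
  expect_equal(as.character(out$consensus_class),
               c("core", NA, NA, "none"))
  # intersection rule additionally drops the one-sided pass
  out2 <- consensus(dnn, svm, cuts, rule = "intersection")
  expect_equal(as.character(out2$consensus_class), c("core", NA, NA, NA))
  # symmetric in the model order under the union rule
  swapped <- consensus(svm, dnn, list(dnn = cuts$svm, svm = cuts$dnn))
  expect_equal(swapped$consensus_class[order(swapped$title)],
               out$consensus_class[order(out$title)])
  # empty inputs give an empty result
  expect_equal(nrow(consensus(dnn[0, ], svm[0, ], cuts)), 0)
  expect_error(consensus(dnn, svm[1:3, ], cuts), "same GSM")
})

test_that("evaluation metrics count matches, misses and unclassified GSMs", {
  manual <- c("none", "core", "outer", "dual")
  ev <- evaluate(manual, manual)
  expect_equal(ev$accuracy, 1)
  expect_equal(ev$sensitivity, 1)

  ev2 <- evaluate(c("none", "core", "outer", "none"), manual)
  expect_equal(ev2$accuracy, 0.75)
  expect_equal(ev2$sensitivity, 0.75)

  # NA predictions count against accuracy but not sensitivity
  ev3 <- evaluate(c("none", "core", NA, NA), manual)
  expect_equal(ev3$accuracy, 0.5)
  expect_equal(ev3$sensitivity, 1)
  expect_equal(ev3$n_classified, 2)

  # confusion rows sum to manual class counts among classified GSMs
  pred <- c("none", "core", "core", "dual")
  ev4 <- evaluate(pred, manual)
  expect_equal(unname(rowSums(ev4$confusion)),
               unname(table(factor(manual, levels = fuco_classes()))),
               ignore_attr = TRUE)
  expect_error(evaluate(pred[1:2], manual), "equal length")
  g <- glance(ev4)
  expect_equal(g$accuracy, 0.75)
  expect_equal(sum(tidy(ev4)$n), 4)
})
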