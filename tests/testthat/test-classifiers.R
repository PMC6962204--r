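test_that("both families are deterministic under a fixed seed", {
  feats <- separable_features(n_per_class = 8)
  spec <- network_spec(n_nodes = 8, n_layers = 3, epochs = 50, seed = 5)
  m1 <- train_network(feats, feats$label, spec)
  m2 <- train_network(feats, feats$label, spec)
  expect_identical(predict_probabilities(m1, feats),
                   predict_probabilities(m2, feats))

  s1 <- train_margin(feats, feats$label, cost = 1, seed = 435)
  s2 <- train_margin(feats, feats$label, cost = 1, seed = 435)
  expect_identical(predict_probabilities(s1, feats),
                   predict_probabilities(s2, feats))
})

test_that("separable indicator features are learned to perfect training accuracy", {
  feats <- separable_features(n_per_class = 12)
  net <- train_network(feats, feats$label,
                       network_spec(n_nodes = 32, n_layers = 3, epochs = 1500,
                                    seed = 1))
  expect_equal(mean(predict(net, feats) == feats$label), 1)

  svm <- train_margin(feats, feats$label, cost = 8.7, seed = 435)
  expect_equal(mean(predict(svm, feats) == feats$label), 1)
})

test_that("an untrained network predicts near-uniform probabilities", {
  feats <- separable_features(n_per_class = 10)
  net <- train_network(feats, feats$label,
                       network_spec(n_nodes = 16, n_layers = 3, epochs = 0,
                                    seed = 2))
  p <- predict_probabilities(net, feats)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  # Xavier-initialised logits are near zero, so no class dominates
  expect_true(max(abs(as.matrix(p) - 0.25)) < 0.2)
  acc <- mean(classify(p) == feats$label)
  expect_lt(acc, 0.6)
})

test_that("training loss is non-increasing at logged intervals without dropout", {
  feats <- separable_features(n_per_class = 10)
  net <- train_network(feats, feats$label,
                       network_spec(n_nodes = 16, n_layers = 3, epochs = 600,
                                    dropout_keep = 1, seed = 3),
                       trace_every = 50)
  expect_true(all(diff(net$loss_trace$loss) <= 1e-8))
})

test_that("predicted probabilities form a simplex and argmax ties break by class order", {
  feats <- separable_features(n_per_class = 6)
  net <- train_network(feats, feats$label,
                       network_spec(n_nodes = 8, n_layers = 3, epochs = 100,
                                    seed = 4))
  p <- predict_probabilities(net, feats)
  expect_true(all(abs(rowSums(p) - 1) < 1e-9))
  expect_true(all(as.matrix(p) >= 0))
  expect_error(predict_probabilities(net, feats[, 1:5]), "ion column")

  expect_equal(as.character(classify(c(none = 0.7, core = 0.1, outer = 0.1,
                                       dual = 0.1))), "none")
  expect_equal(as.character(classify(c(none = 0.25, core = 0.25, outer = 0.25,
                                       dual = 0.25))), "none")
  expect_equal(as.character(classify(c(none = 0.1, core = 0.2, outer = 0.6,
                                       dual = 0.1))), "outer")
  expect_equal(as.character(classify(c(none = 0.1, core = 0.4, outer = 0.4,
                                       dual = 0.1))), "core")
})

test_that("training rejects empty or unlabeled input and warns on one class", {
  feats <- separable_features(n_per_class = 4)
  expect_error(train_network(feats[0, ], character(0)), "empty")
  expect_error(train_network(feats, rep(NA, nrow(feats))), "missing")
  one <- feats[feats$label == "core", ]
  expect_warning(
    train_network(one, one$label,
                  network_spec(n_nodes = 8, n_layers = 3, epochs = 10, seed = 1)),
    "single class"
  )
})

test_that("the margin grid trains one model per cost-seed pair", {
  feats <- separable_features(n_per_class = 5)
  models <- train_margin_grid(feats, feats$label, costs = 1, seeds = 435)
  expect_length(models, 1)
  expect_equal(models[[1]]$spec$cost, 1)
  expect_equal(models[[1]]$spec$seed, 435L)
  expect_error(train_margin_grid(feats, feats$label, costs = numeric(0)),
               "non-empty")
})

test_that("tidiers summarise fitted models", {
  feats <- separable_features(n_per_class = 4)
  net <- train_network(feats, feats$label,
                       network_spec(n_nodes = 8, n_layers = 3, epochs = 10,
                                    seed = 1))
  g <- glance(net)
  expect_equal(g$family, "network")
  expect_equal(g$n_parameters,
               14 * 8 + 8 + 2 * (8 * 8 + 8) + 8 * 4 + 4)
  expect_true("epochs" %in% tidy(net)$term)

  svm <- train_margin(feats, feats$label, cost = 2, seed = 1)
  expect_equal(glance(svm)$cost, 2)
})
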