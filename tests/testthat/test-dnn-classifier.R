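# A small separable paired dataset: two informative features shifted
# between classes plus noise columns.
make_paired <- function(n_per_class = 120, n_features = 8, shift = 3, seed = 1) {
  set.seed(seed)
  n <- 2 * n_per_class
  x <- matrix(rnorm(n * n_features), nrow = n)
  y <- rep(c("tumor", "normal"), each = n_per_class)
  x[y == "tumor", 1:2] <- x[y == "tumor", 1:2] + shift
  colnames(x) <- paste0("f", seq_len(n_features))
  list(features = x, labels = y)
}

test_that("bce_loss matches its closed form, including clipping", {
  expect_equal(bce_loss(1, 0.5), log(2), tolerance = 1e-12)
  expect_equal(bce_loss(0, 0.9), -log(0.1), tolerance = 1e-12)
  expect_lt(bce_loss(1, 1), 1e-6)           # perfect-prediction limit via clipping
  set.seed(3)
  y <- sample(0:1, 1000, replace = TRUE)
  yh <- runif(1000, 0.001, 0.999)
  expect_equal(bce_loss(y, yh), -y * log(yh) - (1 - y) * log(1 - yh),
               tolerance = 1e-9)
})

test_that("the network separates planted-signal pairs and trains stably", {
  train <- make_paired(seed = 10)
  test <- make_paired(seed = 11)
  # small dataset: shrink the batch so each epoch takes enough Adam steps
  cfg <- dnn_config(epochs = 40, batch_size = 32, seed = 99)
  model <- dnn_train(train, cfg)
  expect_length(model$history, cfg$epochs)
  expect_lt(model$history[cfg$epochs], model$history[1])  # loss decreased

  pred <- dnn_predict(model, test)
  expect_true(all(pred$score > 0 & pred$score < 1))
  expect_gte(mean(pred$label == test$labels), 0.95)
})

test_that("label-shuffled training yields chance-level held-out AUC", {
  # the network must be trained to convergence on the shuffled labels: an
  # undertrained (near-random) network is a random projection that can
  # correlate with the class-separating direction by chance
  train <- make_paired(seed = 20)
  set.seed(21)
  train$labels <- sample(train$labels)
  test <- make_paired(seed = 22)
  model <- dnn_train(train, dnn_config(epochs = 60, batch_size = 32,
                                       dropout_rate = 0.1, seed = 5))
  auc <- auc_score(dnn_predict(model, test)$score, test$labels)
  expect_gte(auc, 0.4)
  expect_lte(auc, 0.6)
})

test_that("inference is deterministic and training is seed-reproducible", {
  train <- make_paired(n_per_class = 60, seed = 30)
  cfg <- dnn_config(epochs = 3, dropout_rate = 0, seed = 42)
  m1 <- dnn_train(train, cfg)
  m2 <- dnn_train(train, cfg)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$layers, m2$layers)

  p1 <- dnn_predict(m1, train)
  p2 <- dnn_predict(m1, train)
  expect_identical(p1$score, p2$score)
  # identical input rows get identical scores
  dup <- list(features = train$features[c(1, 1), , drop = FALSE])
  sc <- dnn_predict(m1, dup)$score
  expect_identical(sc[1], sc[2])
  # thresholding contract
  expect_equal(unique(p1$label[p1$score > cfg$decision_threshold]), "tumor")

  bad <- list(features = train$features[, 1:3, drop = FALSE])
  expect_error(dnn_predict(m1, bad), "feature length mismatch")
  expect_error(dnn_train(list(features = train$features,
                              labels = rep("tumor", nrow(train$features)))),
               "single class")
})

test_that("models survive a JSON save/load round trip", {
  train <- make_paired(n_per_class = 40, n_features = 4, seed = 50)
  model <- dnn_train(train, dnn_config(n_hidden_layers = 2, units_per_layer = 8,
                                       epochs = 2, seed = 1))
  path <- tempfile(fileext = ".json")
  on.exit(unlink(path))
  dnn_save(model, path)
  back <- dnn_load(path)
  expect_equal(back$layers, model$layers, tolerance = 1e-12)
  expect_equal(dnn_predict(back, train)$score, dnn_predict(model, train)$score,
               tolerance = 1e-12)
})

test_that("baseline adapters honour the shared fit/predict contract", {
  expect_setequal(baseline_classifier_names(), c("knn", "svm", "nb"))
  expect_error(baseline_classifier("forest"), "should be one of")

  # unanimous neighbourhood: 5-NN predicts the only class present
  knn <- baseline_classifier("knn")
  x <- matrix(rnorm(10), 5, 2)
  fit <- knn$fit(x, rep(1, 5))
  expect_equal(unname(knn$predict_score(fit, matrix(0, 2, 2))), c(1, 1))

  # separable Gaussians: nb and svm both >= 0.95 held-out accuracy
  train <- make_paired(n_per_class = 60, n_features = 4, seed = 60)
  test <- make_paired(n_per_class = 60, n_features = 4, seed = 61)
  ytr <- as.integer(train$labels == "tumor")
  yte <- as.integer(test$labels == "tumor")
  for (name in c("nb", "svm", "knn")) {
    ad <- baseline_classifier(name)
    sc <- ad$predict_score(ad$fit(train$features, ytr), test$features)
    expect_gte(mean((sc > 0.5) == yte), 0.95)
  }
})
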