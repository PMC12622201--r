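test_that("paper-scale configurations carry the published hyperparameters", {
  cfg <- catree_config(paper_scale = TRUE)
  expect_equal(cfg$n_estimators, 20000L)
  expect_equal(cfg$max_depth, 7L)
  expect_equal(cfg$min_samples_split, 3L)
  expect_equal(cfg$learning_rate, 0.05)
  expect_equal(cfg$max_features, "sqrt")
  expect_equal(cfg$subsample, 0.4)
  expect_equal(cfg$repetitions, 10L)

  reg <- canet_config("regression", paper_scale = TRUE)
  expect_equal(reg$hidden_layers, 6L)
  expect_equal(reg$width, 15000L)
  expect_equal(reg$learning_rate, 0.001)
  expect_equal(reg$epochs, 200L)
  expect_equal(reg$batch_size, 32L)
  expect_equal(canet_config("multiclass3")$batch_size, 50L)
})

test_that("CATree fits separable data perfectly and is seed-deterministic", {
  withr::with_seed(11L, {
    X <- matrix(rnorm(200L * 10L), 200L, 10L)
    y <- factor(ifelse(X[, 2L] - X[, 5L] > 0, "pos", "neg"))
  })
  cfg <- catree_config(n_estimators = 100L, repetitions = 3L, seed = 7L)
  m <- train_catree(X, y, cfg)
  expect_equal(predict(m, X, type = "class"), as.character(y))
  m2 <- train_catree(X, y, cfg)
  expect_identical(predict(m2, X), predict(m, X))
  expect_error(train_catree(X[1:2, ], y[1:2], cfg), "min_samples_split")
})

test_that("CATree recovers planted structure out of sample", {
  d <- make_planted_data(seed = 1L)
  m <- train_catree(d$X_train, factor(d$y_train),
                    catree_config(seed = 1L, repetitions = 3L))
  yhat <- as.integer(predict(m, d$X_test) >= 0.5)
  expect_gt(balanced_accuracy(d$y_test, yhat), 0.9)
})

test_that("CATree handles regression and three-class tasks", {
  withr::with_seed(3L, {
    X <- matrix(rnorm(150L * 8L), 150L, 8L)
    yreg <- X[, 1L] * 2 + rnorm(150L, sd = 0.1)
  })
  mr <- train_catree(X, yreg, catree_config(n_estimators = 150L,
                                            repetitions = 2L, seed = 2L))
  met <- evaluate_predictions(yreg, predict(mr, X), "regression")
  expect_gt(met$value[met$metric == "PCC"], 0.95)

  ymc <- cut(X[, 2L], c(-Inf, -0.4, 0.4, Inf),
             labels = c("decrease", "unchanged", "increase"))
  mm <- train_catree(X, ymc, catree_config(n_estimators = 150L,
                                           repetitions = 2L, seed = 2L))
  prob <- predict(mm, X)
  expect_equal(dim(prob), c(150L, 3L))
  expect_equal(unname(rowSums(prob)), rep(1, 150L), tolerance = 1e-6)
  expect_gt(mean(predict(mm, X, type = "class") == as.character(ymc)), 0.9)
})

test_that("a narrow CANet overfits a small sample to near-zero training loss", {
  withr::with_seed(5L, {
    X <- matrix(rnorm(50L * 5L), 50L, 5L)
    y <- rnorm(50L)
  })
  net <- train_canet(X, y, canet_config("regression", width = 32L, seed = 5L))
  expect_lt(sqrt(mean((predict(net, X) - y)^2)), 0.1)
  # deterministic given the seed
  net2 <- train_canet(X, y, canet_config("regression", width = 32L, seed = 5L))
  expect_identical(predict(net2, X), predict(net, X))
})

test_that("CANet classification heads learn and validate their label sets", {
  withr::with_seed(6L, {
    X <- matrix(rnorm(120L * 6L), 120L, 6L)
    yb <- as.integer(X[, 1L] + X[, 2L] > 0)
  })
  nb <- train_canet(X, yb, canet_config("binary", width = 32L, epochs = 100L,
                                        seed = 6L))
  met <- evaluate_predictions(yb, predict(nb, X), "binary")
  expect_gt(met$value[met$metric == "AUC"], 0.95)

  ymc <- c("decrease", "increase", "unchanged")[1L + (seq_len(120L) %% 3L)]
  expect_error(
    train_canet(X, replace(ymc, 1L, "stable"),
                canet_config("multiclass3", width = 16L, epochs = 1L)),
    "decrease, increase, unchanged")
  nm <- train_canet(X[1:30, ], ymc[1:30],
                    canet_config("multiclass3", width = 32L, epochs = 150L,
                                 seed = 7L))
  expect_gt(mean(predict(nm, X[1:30, ], type = "class") == ymc[1:30]), 0.9)
})

test_that("evaluation metrics match hand computations and handle edge cases", {
  perfect <- evaluate_predictions(c(0, 1, 0, 1), c(0, 1, 0, 1), "binary")
  expect_equal(perfect$value[perfect$metric == "MCC"], 1)
  expect_equal(perfect$value[perfect$metric == "F1"], 1)

  # confusion matrix [[2,1],[1,2]] has MCC exactly 1/3
  m <- evaluate_predictions(c(0, 0, 0, 1, 1, 1), c(0, 0, 1, 0, 1, 1), "binary")
  expect_equal(m$value[m$metric == "MCC"], 1 / 3)

  r <- evaluate_predictions(c(1.5, 2, 3), c(1.5, 2, 3), "regression")
  expect_equal(r$value, c(1, 0))

  expect_warning(s <- evaluate_predictions(c(1, 1, 1), c(0.2, 0.9, 0.8),
                                           "binary"),
                 "single class")
  expect_true(is.na(s$value[s$metric == "AUC"]))

  # permuting labels consistently leaves metrics unchanged
  yt <- c(0, 1, 0, 1, 1, 0, 1)
  ys <- c(0.1, 0.8, 0.4, 0.7, 0.55, 0.2, 0.35)
  perm <- c(3L, 1L, 7L, 2L, 5L, 4L, 6L)
  expect_equal(evaluate_predictions(yt[perm], ys[perm], "binary"),
               evaluate_predictions(yt, ys, "binary"))

  # three-class normalized accuracy is the macro recall
  yt3 <- rep(c("decrease", "increase", "unchanged"), times = c(4L, 3L, 3L))
  yp3 <- c("decrease", "decrease", "decrease", "increase",
           "increase", "increase", "increase", "unchanged", "unchanged",
           "unchanged")
  m3 <- evaluate_predictions(yt3, yp3, "multiclass3")
  expect_equal(m3$value[m3$metric == "normalized_accuracy"],
               mean(c(3 / 4, 1, 1)))
})
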