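# synthetic classification data whose labels depend only on a planted
# informative coordinate hidden among noise columns, with label noise
# applied to training rows.  The check is whether the learner finds the
# planted coordinate under square-root feature sampling, not whether it
# can approximate an oblique decision boundary.
make_planted_data <- function(n = 500L, p = 60L, seed = 1L, noise = 0.1) {
  withr::with_seed(seed, {
    X <- matrix(rnorm(n * p), n, p)
    planted <- 11L
    y <- as.integer(X[, planted] > 0)
    train <- sample.int(n, floor(0.7 * n))
    y_train <- y[train]
    flip <- sample(seq_along(y_train), round(noise * length(y_train)))
    y_train[flip] <- 1L - y_train[flip]
    list(X_train = X[train, ], y_train = y_train,
         X_test = X[-train, ], y_test = y[-train], planted = planted)
  })
}

balanced_accuracy <- function(y_true, y_hat) {
  mean(c(mean(y_hat[y_true == 1] == 1), mean(y_hat[y_true == 0] == 0)))
}
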