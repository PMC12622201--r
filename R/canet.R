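#' CANet configuration
#'
#' Fully connected feed-forward network settings.  At paper scale the
#' network has six hidden layers of 15000 neurons, learning rate 0.001 and
#' 200 epochs, with batch size 32 for regression/binary tasks and 50 for
#' the three-class solubility task.  The default test scale keeps the
#' depth and optimizer settings but reduces the width to 64.
#'
#' @param task `"binary"`, `"regression"` or `"multiclass3"`.
#' @param paper_scale logical; use the 15000-neuron width.
#' @param hidden_layers number of hidden layers.
#' @param width neurons per hidden layer.
#' @param learning_rate Adam learning rate.
#' @param epochs training epochs.
#' @param batch_size minibatch size; defaults to 50 for `multiclass3` and
#'   32 otherwise.
#' @param seed random seed for initialization and shuffling.
#' @return list of class `canet_config`.
#' @export
canet_config <- function(task = c("binary", "regression", "multiclass3"),
                         paper_scale = FALSE, hidden_layers = 6L,
                         width = if (paper_scale) 15000L else 64L,
                         learning_rate = 0.001, epochs = 200L,
                         batch_size = NULL, seed = 1L) {
  task <- match.arg(task)
  if (is.null(batch_size))
    batch_size <- if (task == "multiclass3") 50L else 32L
  structure(list(task = task, hidden_layers = as.integer(hidden_layers),
                 width = as.integer(width), learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed),
                 paper_scale = paper_scale),
            class = "canet_config")
}

solubility_classes <- c("decrease", "increase", "unchanged")

canet_forward <- function(W, b, X) {
  A <- list(X)
  L <- length(W)
  for (l in seq_len(L)) {
    Z <- A[[l]] %*% W[[l]]
    Z <- sweep(Z, 2L, b[[l]], `+`)
    A[[l + 1L]] <- if (l < L) pmax(Z, 0) else Z
  }
  A
}

#' Train a CANet feed-forward network
#'
#' Plain fully connected ReLU network trained with Adam on minibatches;
#' the output head and loss follow the task: linear/MSE for regression,
#' sigmoid/cross-entropy for binary labels, softmax/cross-entropy for the
#' three solubility classes (`decrease`, `increase`, `unchanged`).
#' Training is deterministic for a fixed seed on a single device.
#'
#' @param X numeric feature matrix.
#' @param y response: numeric (regression), 0/1 or 2-level factor
#'   (binary), or labels among the three solubility classes (multiclass3).
#' @param cfg a [canet_config()].
#' @return Object of class `canet` with a [predict][predict.canet] method.
#' @export
train_canet <- function(X, y, cfg = canet_config("regression")) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n != length(y)) stop("rows(X) must equal length(y)")
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, `/`)

  if (cfg$task == "regression") {
    Y <- matrix(as.numeric(y), ncol = 1L)
    k_out <- 1L
  } else if (cfg$task == "binary") {
    yt <- if (is.factor(y)) as.integer(y) - 1L else as.integer(y)
    if (!all(yt %in% c(0L, 1L))) stop("binary task requires 0/1 labels")
    Y <- matrix(yt, ncol = 1L)
    k_out <- 1L
  } else {
    yc <- as.character(y)
    bad <- setdiff(unique(yc), solubility_classes)
    if (length(bad))
      stop("multiclass3 labels must be among ",
           paste(solubility_classes, collapse = ", "),
           "; found: ", paste(bad, collapse = ", "))
    Y <- outer(yc, solubility_classes, `==`) * 1
    k_out <- 3L
  }

  dims <- c(ncol(X), rep(cfg$width, cfg$hidden_layers), k_out)
  L <- length(dims) - 1L
  withr::with_seed(cfg$seed, {
    W <- lapply(seq_len(L), function(l)
      matrix(rnorm(dims[l] * dims[l + 1L], sd = sqrt(2 / dims[l])),
             dims[l], dims[l + 1L]))
    b <- lapply(seq_len(L), function(l) numeric(dims[l + 1L]))
    mW <- lapply(W, function(w) w * 0); vW <- mW
    mb <- lapply(b, function(x) x * 0); vb <- mb
    b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
    step <- 0L
    for (epoch in seq_len(cfg$epochs)) {
      perm <- sample.int(n)
      for (start in seq(1L, n, by = cfg$batch_size)) {
        idx <- perm[start:min(start + cfg$batch_size - 1L, n)]
        Xb <- Xs[idx, , drop = FALSE]
        Yb <- Y[idx, , drop = FALSE]
        A <- canet_forward(W, b, Xb)
        out <- A[[L + 1L]]
        pred <- switch(cfg$task,
          regression = out,
          binary = 1 / (1 + exp(-out)),
          multiclass3 = {
            e <- exp(out - apply(out, 1L, max))
            e / rowSums(e)
          })
        # gradient of MSE / cross-entropy at the pre-activation: pred - y
        delta <- (pred - Yb) / nrow(Xb)
        step <- step + 1L
        corr <- sqrt(1 - b2^step) / (1 - b1^step)
        for (l in seq.int(L, 1L)) {
          gW <- crossprod(A[[l]], delta)
          gb <- colSums(delta)
          if (l > 1L)
            delta <- (delta %*% t(W[[l]])) * (A[[l]] > 0)
          mW[[l]] <- b1 * mW[[l]] + (1 - b1) * gW
          vW[[l]] <- b2 * vW[[l]] + (1 - b2) * gW^2
          mb[[l]] <- b1 * mb[[l]] + (1 - b1) * gb
          vb[[l]] <- b2 * vb[[l]] + (1 - b2) * gb^2
          W[[l]] <- W[[l]] - cfg$learning_rate * corr * mW[[l]] /
            (sqrt(vW[[l]]) + eps)
          b[[l]] <- b[[l]] - cfg$learning_rate * corr * mb[[l]] /
            (sqrt(vb[[l]]) + eps)
        }
      }
    }
  })
  structure(list(W = W, b = b, center = ctr, scale = scl, cfg = cfg),
            class = "canet")
}

#' Predict from a CANet network
#'
#' @param object a trained [train_canet()] model.
#' @param newdata numeric feature matrix.
#' @param type `"response"` (scores/probabilities/predictions) or
#'   `"class"` for hard labels on classification tasks.
#' @param ... unused.
#' @return Numeric vector, probability matrix (multiclass response) or
#'   character labels.
#' @export
predict.canet <- function(object, newdata, type = c("response", "class"),
                          ...) {
  type <- match.arg(type)
  Xs <- sweep(sweep(as.matrix(newdata), 2L, object$center), 2L,
              object$scale, `/`)
  out <- canet_forward(object$W, object$b, Xs)[[length(object$W) + 1L]]
  task <- object$cfg$task
  if (task == "regression") return(drop(out))
  if (task == "binary") {
    p <- drop(1 / (1 + exp(-out)))
    return(if (type == "class") as.integer(p >= 0.5) else p)
  }
  e <- exp(out - apply(out, 1L, max))
  prob <- e / rowSums(e)
  colnames(prob) <- solubility_classes
  if (type == "class") solubility_classes[max.col(prob)] else prob
}
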