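#' CATree configuration
#'
#' Gradient-boosted-tree ensemble settings.  At paper scale the defaults
#' are 20000 estimators, maximum depth 7, minimum sample split 3, learning
#' rate 0.05, square-root feature sampling, 0.4 subsample and 10
#' repetitions.  The default test scale keeps every setting except the
#' estimator count, reduced to 200 so the ensemble fits in seconds.
#'
#' @param paper_scale logical; use the full-scale estimator count.
#' @param n_estimators boosting rounds per repetition.
#' @param max_depth tree depth cap.
#' @param min_samples_split minimal samples required to split a node.
#' @param learning_rate shrinkage.
#' @param max_features `"sqrt"` for square-root feature sampling per split.
#' @param subsample row subsample fraction per round.
#' @param repetitions independently seeded models averaged at prediction.
#' @param seed base random seed.
#' @return list of class `catree_config`.
#' @export
catree_config <- function(paper_scale = FALSE,
                          n_estimators = if (paper_scale) 20000L else 200L,
                          max_depth = 7L, min_samples_split = 3L,
                          learning_rate = 0.05, max_features = "sqrt",
                          subsample = 0.4, repetitions = 10L, seed = 1L) {
  structure(list(n_estimators = as.integer(n_estimators),
                 max_depth = as.integer(max_depth),
                 min_samples_split = as.integer(min_samples_split),
                 learning_rate = learning_rate, max_features = max_features,
                 subsample = subsample, repetitions = as.integer(repetitions),
                 seed = as.integer(seed), paper_scale = paper_scale),
            class = "catree_config")
}

infer_task <- function(y) {
  if (is.numeric(y) && length(unique(y)) > 3L) return("regression")
  k <- length(unique(as.character(y)))
  if (k == 2L) "binary" else if (k == 3L) "multiclass3" else "regression"
}

#' Train a CATree ensemble
#'
#' Fits `repetitions` gradient-boosted-tree models (xgboost backend) with
#' distinct seeds and averages their outputs: class probabilities for
#' classification, predictions for regression.  The task is inferred from
#' the label type: numeric responses give regression, 2-level labels binary
#' classification, 3-level labels multiclass classification.
#'
#' @param X numeric feature matrix, one row per sample.
#' @param y labels/response aligned with the rows of `X`.
#' @param cfg a [catree_config()].
#' @return Object of class `catree` with a [predict][predict.catree] method.
#' @export
train_catree <- function(X, y, cfg = catree_config()) {
  X <- as.matrix(X)
  if (nrow(X) != length(y)) stop("rows(X) must equal length(y)")
  if (nrow(X) < cfg$min_samples_split)
    stop("need at least min_samples_split = ", cfg$min_samples_split,
         " samples, got ", nrow(X))
  task <- infer_task(y)
  classes <- NULL
  if (task == "regression") {
    lab <- as.numeric(y)
    objective <- "reg:squarederror"
  } else {
    classes <- levels(factor(y))
    lab <- as.integer(factor(y, classes)) - 1L
    objective <- if (task == "binary") "binary:logistic" else "multi:softprob"
  }
  p <- ncol(X)
  colsample <- if (identical(cfg$max_features, "sqrt"))
    max(1, floor(sqrt(p))) / p else 1
  params <- list(objective = objective, eta = cfg$learning_rate,
                 max_depth = cfg$max_depth, subsample = cfg$subsample,
                 colsample_bynode = colsample, nthread = 1L)
  if (task == "multiclass3") params$num_class <- 3L
  dtrain <- xgboost::xgb.DMatrix(X, label = lab, nthread = 1L)
  boosters <- lapply(seq_len(cfg$repetitions), function(r) {
    pr <- params
    pr$seed <- cfg$seed + r - 1L
    set.seed(pr$seed)
    xgboost::xgb.train(params = pr, data = dtrain,
                       nrounds = cfg$n_estimators, verbose = 0)
  })
  structure(list(boosters = boosters, task = task, classes = classes,
                 cfg = cfg, n_features = p),
            class = "catree")
}

#' Predict from a CATree ensemble
#'
#' @param object a trained [train_catree()] model.
#' @param newdata numeric feature matrix.
#' @param type `"response"` for averaged scores/predictions or `"class"`
#'   for hard labels (classification tasks).
#' @param ... unused.
#' @return Numeric vector (regression/binary scores), probability matrix
#'   (multiclass response), or character labels (`type = "class"`).
#' @export
predict.catree <- function(object, newdata, type = c("response", "class"),
                           ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  dm <- xgboost::xgb.DMatrix(newdata, nthread = 1L)
  preds <- lapply(object$boosters, function(b) predict(b, dm))
  avg <- Reduce(`+`, preds) / length(preds)
  if (object$task == "multiclass3") {
    prob <- if (is.matrix(avg)) avg else matrix(avg, ncol = 3L, byrow = TRUE)
    dimnames(prob) <- list(NULL, object$classes)
    if (type == "class") return(object$classes[max.col(prob)])
    return(prob)
  }
  if (type == "class" && object$task == "binary")
    return(object$classes[1L + (avg >= 0.5)])
  avg
}
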