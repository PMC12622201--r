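#' Evaluate predictions for mutation-effect tasks
#'
#' Binary classification reports the Matthews correlation coefficient,
#' area under the ROC curve, F1 score and balanced accuracy; regression
#' reports the Pearson correlation coefficient and root-mean-square error;
#' three-class solubility tasks report normalized accuracy (the mean of the
#' per-class recalls, i.e. balanced accuracy generalized to three classes)
#' and the generalized squared correlation GC2, computed as the confusion
#' matrix chi-square statistic divided by `N * (K - 1)`.
#'
#' @param y_true observed labels (binary: 0/1 or 2-level factor;
#'   regression: numeric; multiclass: 3-level factor/character).
#' @param y_pred predictions: scores/probabilities for binary (class
#'   decided at 0.5), numeric for regression, labels or a probability
#'   matrix for multiclass.
#' @param task one of `"binary"`, `"regression"`, `"multiclass3"`.
#' @return `data.frame` with columns `metric` and `value`.
#' @export
evaluate_predictions <- function(y_true, y_pred,
                                 task = c("binary", "regression",
                                          "multiclass3")) {
  task <- match.arg(task)
  if (task == "regression") {
    y_true <- as.numeric(y_true)
    y_pred <- as.numeric(y_pred)
    return(data.frame(
      metric = c("PCC", "RMSE"),
      value = c(cor(y_true, y_pred), sqrt(mean((y_true - y_pred)^2)))
    ))
  }
  if (task == "binary") {
    yt <- if (is.factor(y_true)) as.integer(y_true) - 1L else as.integer(y_true)
    stopifnot(all(yt %in% c(0L, 1L)))
    score <- as.numeric(y_pred)
    yp <- as.integer(score >= 0.5)
    tp <- sum(yt == 1 & yp == 1); tn <- sum(yt == 0 & yp == 0)
    fp <- sum(yt == 0 & yp == 1); fn <- sum(yt == 1 & yp == 0)
    denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
    mcc <- if (denom == 0) 0 else (tp * tn - fp * fn) / denom
    f1 <- if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
    bacc <- mean(c(if (tp + fn > 0) tp / (tp + fn),
                   if (tn + fp > 0) tn / (tn + fp)))
    auc <- if (length(unique(yt)) < 2L) {
      warning("AUC undefined: y_true contains a single class")
      NA_real_
    } else {
      as.numeric(pROC::auc(pROC::roc(yt, score, quiet = TRUE,
                                     direction = "<", levels = c(0, 1))))
    }
    return(data.frame(metric = c("MCC", "AUC", "F1", "balanced_accuracy"),
                      value = c(mcc, auc, f1, bacc)))
  }
  # multiclass3
  yt <- as.character(y_true)
  yp <- if (is.matrix(y_pred)) colnames(y_pred)[max.col(y_pred)] else
    as.character(y_pred)
  classes <- sort(unique(c(yt, yp)))
  cm <- table(factor(yt, classes), factor(yp, classes))
  recalls <- diag(cm) / pmax(rowSums(cm), 1L)
  recalls <- recalls[rowSums(cm) > 0]
  n <- sum(cm)
  expd <- outer(rowSums(cm), colSums(cm)) / n
  chi2 <- sum(ifelse(expd > 0, (cm - expd)^2 / expd, 0))
  gc2 <- chi2 / (n * (length(classes) - 1L))
  data.frame(metric = c("normalized_accuracy", "GC2"),
             value = c(mean(recalls), gc2))
}
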