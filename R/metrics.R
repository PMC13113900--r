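#' Balanced accuracy
#'
#' Mean of the per-class recalls over the classes present in `truth`
#' (robust to class imbalance). If a class is absent from `truth` it simply
#' does not contribute.
#'
#' @param truth,pred Factors or character vectors of equal length.
#' @return A real in `[0, 1]`.
#' @export
balanced_accuracy <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  cls <- unique(truth)
  mean(vapply(cls, function(k)
    mean(pred[truth == k] == k), numeric(1)))
}

#' Macro-averaged F1 score
#'
#' Unweighted mean of per-class F1 over the classes present in `truth`;
#' a class with zero precision + recall contributes 0.
#'
#' @inheritParams balanced_accuracy
#' @return A real in `[0, 1]`.
#' @export
macro_f1 <- function(truth, pred) {
  truth <- as.character(truth); pred <- as.character(pred)
  stopifnot(length(truth) == length(pred))
  cls <- unique(truth)
  f1 <- vapply(cls, function(k) {
    tp <- sum(truth == k & pred == k)
    fp <- sum(truth != k & pred == k)
    fn <- sum(truth == k & pred != k)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, numeric(1))
  mean(f1)
}
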