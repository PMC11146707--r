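# Evaluation metrics for the binary (AF / non-AF) and four-class
# (Normal / AF / Other / Noise) tasks.

#' Binary confusion counts
#'
#' @param n_tp,n_tn,n_fp,n_fn Non-negative integer tallies. `n_tp` counts
#'   AF segments assigned as AF, `n_tn` non-AF assigned non-AF, `n_fp`
#'   non-AF assigned AF, `n_fn` AF assigned non-AF.
#' @return An object of class `confusion_counts`.
#' @export
confusion_counts <- function(n_tp, n_tn, n_fp, n_fn) {
  v <- c(n_tp = n_tp, n_tn = n_tn, n_fp = n_fp, n_fn = n_fn)
  if (any(v < 0) || any(v != round(v)))
    stop("counts must be non-negative integers", call. = FALSE)
  if (sum(v) == 0) stop("at least one count must be positive",
                        call. = FALSE)
  structure(as.list(v), class = "confusion_counts")
}

#' Tally binary confusion counts from labels
#'
#' @param truth,pred Character/factor vectors of labels.
#' @param positive The positive (AF) label.
#' @return A [confusion_counts()].
#' @export
tally_binary <- function(truth, pred, positive = "af") {
  stopifnot(length(truth) == length(pred))
  tp <- truth == positive
  pp <- pred == positive
  confusion_counts(n_tp = sum(tp & pp), n_tn = sum(!tp & !pp),
                   n_fp = sum(!tp & pp), n_fn = sum(tp & !pp))
}

#' Sensitivity and specificity
#'
#' `Se = TP / (TP + FN)`, `Sp = TN / (TN + FP)`.
#'
#' @param c A [confusion_counts()].
#' @return Named numeric vector `c(sensitivity, specificity)`, both in
#'   \[0, 1\].
#' @examples
#' sensitivity_specificity(confusion_counts(9, 18, 2, 1))  # 0.9 0.9
#' @export
sensitivity_specificity <- function(c) {
  stopifnot(inherits(c, "confusion_counts"))
  if (c$n_tp + c$n_fn == 0)
    stop("sensitivity undefined: no positive-class samples (TP + FN = 0)",
         call. = FALSE)
  if (c$n_tn + c$n_fp == 0)
    stop("specificity undefined: no negative-class samples (TN + FP = 0)",
         call. = FALSE)
  c(sensitivity = c$n_tp / (c$n_tp + c$n_fn),
    specificity = c$n_tn / (c$n_tn + c$n_fp))
}

FOUR_CLASSES <- c("normal", "af", "other", "noise")

#' Four-class confusion matrix
#'
#' A 4x4 count matrix over (true, predicted) in Normal / AF / Other /
#' Noise, rows = truth, columns = prediction.
#'
#' @param m 4x4 non-negative numeric matrix (dimnames optional; assumed in
#'   canonical order `normal, af, other, noise` when absent).
#' @return An object of class `multiclass_counts`.
#' @export
multiclass_counts <- function(m) {
  m <- as.matrix(m)
  if (!all(dim(m) == c(4, 4)))
    stop("`m` must be a 4x4 matrix", call. = FALSE)
  if (any(m < 0)) stop("counts must be non-negative", call. = FALSE)
  if (is.null(dimnames(m)))
    dimnames(m) <- list(truth = FOUR_CLASSES, pred = FOUR_CLASSES)
  structure(m, class = c("multiclass_counts", "matrix"))
}

#' Tally a four-class confusion matrix from labels
#'
#' @param truth,pred Label vectors over the four classes.
#' @param classes Class order (default canonical).
#' @return A [multiclass_counts()].
#' @export
tally_multiclass <- function(truth, pred, classes = FOUR_CLASSES) {
  stopifnot(length(truth) == length(pred))
  m <- table(factor(truth, levels = classes),
             factor(pred, levels = classes))
  multiclass_counts(unclass(as.matrix(m)))
}

#' Per-class and macro F1 scores
#'
#' For each class X, `F1x = 2 * diag_X / (row marginal + column
#' marginal)`; the macro score `F1all` is their unweighted mean.
#'
#' @param m A [multiclass_counts()] (or plain 4x4 matrix).
#' @return Named numeric vector `c(F1n, F1a, F1o, F1p, F1all)`.
#' @export
f1_scores <- function(m) {
  if (!inherits(m, "multiclass_counts")) m <- multiclass_counts(m)
  f1 <- numeric(4)
  for (k in 1:4) {
    denom <- sum(m[k, ]) + sum(m[, k])
    if (denom == 0)
      stop(sprintf(
        "F1 undefined for class '%s': no true or predicted samples",
        FOUR_CLASSES[k]), call. = FALSE)
    f1[k] <- 2 * m[k, k] / denom
  }
  c(F1n = f1[1], F1a = f1[2], F1o = f1[3], F1p = f1[4],
    F1all = mean(f1))
}
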