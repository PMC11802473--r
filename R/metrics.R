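# Slide-level evaluation metrics: accuracy, F1-score and AUC.
#
# Accuracy and F1 threshold binary probabilities at 0.5 (multi-class:
# argmax); AUC is the pairwise positive-vs-negative comparison
# sum I(p_pos > p_neg) / (P * N), with ties counted 0.5 by default
# (Mann-Whitney convention) or 0 in strict mode. Multi-class metrics are
# macro one-vs-rest averages.

check_scores <- function(y_true, prob) {
  stopifnot(length(y_true) >= 1L)
  if (is.matrix(prob)) stopifnot(nrow(prob) == length(y_true))
  else stopifnot(length(prob) == length(y_true))
  invisible(TRUE)
}

predicted_class <- function(prob) {
  if (is.matrix(prob)) max.col(prob, ties.method = "first") - 1L
  else as.integer(prob >= 0.5)
}

#' Classification accuracy
#'
#' Fraction of correctly predicted slides, `(TP + TN) / total`, with binary
#' probabilities thresholded at 0.5 and multi-class probabilities reduced by
#' argmax.
#'
#' @param y_true Integer class labels (0-based).
#' @param prob Numeric vector of positive-class probabilities (binary) or an
#'   n x C probability matrix (multi-class).
#' @return Accuracy in `[0, 1]`.
#' @export
compute_accuracy <- function(y_true, prob) {
  check_scores(y_true, prob)
  mean(predicted_class(prob) == y_true)
}

auc_binary <- function(pos, neg, ties) {
  cmp <- outer(pos, neg, `-`)
  wins <- sum(cmp > 0) + if (ties == "half") 0.5 * sum(cmp == 0) else 0
  wins / (length(pos) * length(neg))
}

#' Area under the ROC curve
#'
#' Pairwise enumeration over all positive/negative pairs:
#' `AUC = sum I(p_pos > p_neg) / (P * N)`. Ties contribute 0.5 by default
#' (the Mann-Whitney convention used by reference implementations); set
#' `ties = "strict"` for the bare indicator. Multi-class input is scored as
#' the macro one-vs-rest average.
#'
#' @inheritParams compute_accuracy
#' @param ties `"half"` (default) or `"strict"`.
#' @return AUC in `[0, 1]`.
#' @export
compute_auc <- function(y_true, prob, ties = c("half", "strict")) {
  ties <- match.arg(ties)
  check_scores(y_true, prob)
  if (!is.matrix(prob)) {
    pos <- prob[y_true == 1L]
    neg <- prob[y_true == 0L]
    if (length(pos) == 0L || length(neg) == 0L)
      stop("undefined metric: AUC needs at least one positive and one ",
           "negative sample")
    auc_binary(pos, neg, ties)
  } else {
    classes <- seq_len(ncol(prob)) - 1L
    present <- classes[classes %in% y_true]
    if (length(present) < 2L)
      stop("undefined metric: AUC needs at least two observed classes")
    mean(vapply(present, function(cl) {
      auc_binary(prob[y_true == cl, cl + 1L], prob[y_true != cl, cl + 1L],
                 ties)
    }, 0))
  }
}

f1_from_counts <- function(TP, FP, FN) {
  den <- 2 * TP + FP + FN
  if (den == 0) 0 else 2 * TP / den
}

#' F1-score
#'
#' `2 TP / (2 TP + FP + FN)` at threshold 0.5, defined as 0 when the
#' denominator vanishes. Multi-class: macro average over classes.
#'
#' @inheritParams compute_accuracy
#' @return F1 in `[0, 1]`.
#' @export
compute_f1 <- function(y_true, prob) {
  check_scores(y_true, prob)
  pred <- predicted_class(prob)
  if (!is.matrix(prob)) {
    f1_from_counts(sum(pred == 1L & y_true == 1L),
                   sum(pred == 1L & y_true == 0L),
                   sum(pred == 0L & y_true == 1L))
  } else {
    classes <- seq_len(ncol(prob)) - 1L
    mean(vapply(classes, function(cl) {
      f1_from_counts(sum(pred == cl & y_true == cl),
                     sum(pred == cl & y_true != cl),
                     sum(pred != cl & y_true == cl))
    }, 0))
  }
}

#' Metrics report for an evaluation split
#'
#' Bundles accuracy, F1 and AUC with the confusion counts (binary) or the
#' per-class breakdown (multi-class).
#'
#' @inheritParams compute_auc
#' @param n_classes Number of classes (inferred when omitted).
#' @return An object of class `mil_metrics_report`.
#' @export
mil_metrics <- function(y_true, prob, n_classes = NULL, ties = "half") {
  check_scores(y_true, prob)
  pred <- predicted_class(prob)
  if (is.null(n_classes))
    n_classes <- if (is.matrix(prob)) ncol(prob) else 2L
  rep <- list(n = length(y_true), n_classes = n_classes,
              accuracy = compute_accuracy(y_true, prob),
              f1 = compute_f1(y_true, prob),
              auc = compute_auc(y_true, prob, ties = ties))
  if (!is.matrix(prob)) {
    rep$TP <- sum(pred == 1L & y_true == 1L)
    rep$TN <- sum(pred == 0L & y_true == 0L)
    rep$FP <- sum(pred == 1L & y_true == 0L)
    rep$FN <- sum(pred == 0L & y_true == 1L)
    rep$P <- sum(y_true == 1L)
    rep$N_neg <- sum(y_true == 0L)
  } else {
    rep$per_class <- lapply(seq_len(n_classes) - 1L, function(cl) {
      list(class = cl,
           TP = sum(pred == cl & y_true == cl),
           FP = sum(pred == cl & y_true != cl),
           FN = sum(pred != cl & y_true == cl),
           support = sum(y_true == cl))
    })
  }
  structure(rep, class = "mil_metrics_report")
}

#' @export
print.mil_metrics_report <- function(x, ...) {
  cat(sprintf("MIL metrics over %d slides (%d classes)\n", x$n, x$n_classes))
  cat(sprintf("  accuracy %.4f | F1 %.4f | AUC %.4f\n", x$accuracy, x$f1,
              x$auc))
  if (!is.null(x$TP))
    cat(sprintf("  TP %d TN %d FP %d FN %d (P = %d, N = %d)\n", x$TP, x$TN,
                x$FP, x$FN, x$P, x$N_neg))
  invisible(x)
}

#' Write a metrics report as JSON
#'
#' @param report A `mil_metrics_report`.
#' @param path Output path.
#' @export
write_metrics_json <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
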