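# Evaluation measures: confusion counts, accuracy / sensitivity /
# specificity (as percentages), the Matthews correlation coefficient,
# and the rank-based (Mann-Whitney) ROC AUC. Cleavage (+1) is the
# positive class throughout.

#' Cross-tabulate true and predicted labels
#'
#' @param truth,predicted equal-length integer vectors over `{+1, -1}`;
#'   `+1` (cleavage) is the positive class.
#' @return named list with non-negative integers `TP`, `FP`, `TN`, `FN`.
#' @export
confusionCounts <- function(truth, predicted) {
  if (length(truth) != length(predicted))
    stop("'truth' and 'predicted' must have equal length", call. = FALSE)
  if (!all(truth %in% c(-1L, 1L)) || !all(predicted %in% c(-1L, 1L)))
    stop("labels must be +1 or -1", call. = FALSE)
  list(TP = sum(truth == 1L & predicted == 1L),
       FP = sum(truth == -1L & predicted == 1L),
       TN = sum(truth == -1L & predicted == -1L),
       FN = sum(truth == 1L & predicted == -1L))
}

.checkCounts <- function(c) {
  stopifnot(is.list(c), all(c("TP", "FP", "TN", "FN") %in% names(c)))
  if (any(unlist(c[c("TP", "FP", "TN", "FN")]) < 0))
    stop("confusion counts must be non-negative", call. = FALSE)
  c
}

#' Classification rates from confusion counts
#'
#' `accuracy()`, `sensitivity()` and `specificity()` return percentages;
#' an undefined rate (zero denominator) returns `NA_real_` rather than
#' erroring.
#'
#' @param counts a list with `TP`, `FP`, `TN`, `FN` (see
#'   [confusionCounts()]).
#' @return percentage in `[0, 100]`, or `NA_real_` when undefined.
#' @name rates
NULL

#' @rdname rates
#' @export
accuracy <- function(counts) {
  c <- .checkCounts(counts)
  tot <- c$TP + c$TN + c$FP + c$FN
  if (tot == 0) return(NA_real_)
  100 * (c$TP + c$TN) / tot
}

#' @rdname rates
#' @export
sensitivity <- function(counts) {
  c <- .checkCounts(counts)
  if (c$TP + c$FN == 0) return(NA_real_)
  100 * c$TP / (c$TP + c$FN)
}

#' @rdname rates
#' @export
specificity <- function(counts) {
  c <- .checkCounts(counts)
  if (c$TN + c$FP == 0) return(NA_real_)
  100 * c$TN / (c$TN + c$FP)
}

#' Matthews correlation coefficient
#'
#' `MCC = (TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, a
#' balanced measure usable under class imbalance. When any factor of the
#' denominator is zero the MCC is defined as 0.
#'
#' @inheritParams accuracy
#' @return dimensionless value in `[-1, 1]`.
#' @export
mccScore <- function(counts) {
  c <- .checkCounts(counts)
  # products overflow integer range for a few thousand samples; use double
  d <- as.numeric(c$TP + c$FP) * (c$TP + c$FN) *
    (c$TN + c$FP) * (c$TN + c$FN)
  if (d == 0) return(0)
  (as.numeric(c$TP) * c$TN - as.numeric(c$FP) * c$FN) / sqrt(d)
}

#' Area under the ROC curve (rank statistic)
#'
#' Threshold-independent performance: the Mann-Whitney probability that a
#' random positive outscores a random negative, with ties counted 1/2:
#' `AUC = (concordant + 0.5 * tied) / (n_pos * n_neg)`.
#'
#' @param truth integer labels over `{+1, -1}`.
#' @param scores finite numeric decision values, larger = more
#'   cleavage-like.
#' @return AUC in `[0, 1]`, or `NA_real_` when only one class is present.
#' @export
aucScore <- function(truth, scores) {
  if (length(truth) != length(scores))
    stop("'truth' and 'scores' must have equal length", call. = FALSE)
  if (!all(truth %in% c(-1L, 1L)))
    stop("labels must be +1 or -1", call. = FALSE)
  if (!all(is.finite(scores)))
    stop("'scores' must be finite", call. = FALSE)
  npos <- sum(truth == 1L)
  nneg <- sum(truth == -1L)
  if (npos == 0L || nneg == 0L) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[truth == 1L]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Assemble a metrics report
#'
#' Computes all five evaluation measures from labels, predictions and
#' decision values. Percentages are reported to 2 decimals, MCC and AUC
#' to 4, matching the conventional table formatting for this method.
#'
#' @param truth integer labels over `{+1, -1}`.
#' @param predicted integer predicted labels over `{+1, -1}`.
#' @param scores numeric decision values (for AUC); optional.
#' @return list with `MCC`, `AUC`, `Acc`, `Sen`, `Spe` (unrounded) and
#'   a `formatted` character vector.
#' @export
metricsReport <- function(truth, predicted, scores = NULL) {
  cc <- confusionCounts(truth, predicted)
  out <- list(
    MCC = mccScore(cc),
    AUC = if (is.null(scores)) NA_real_ else aucScore(truth, scores),
    Acc = accuracy(cc), Sen = sensitivity(cc), Spe = specificity(cc))
  out$formatted <- c(
    MCC = sprintf("%.4f", out$MCC),
    AUC = if (is.na(out$AUC)) "NA" else sprintf("%.4f", out$AUC),
    Acc = sprintf("%.2f", out$Acc),
    Sen = sprintf("%.2f", out$Sen),
    Spe = sprintf("%.2f", out$Spe))
  out
}

#' Write a metrics report as JSON or one-row TSV
#'
#' The TSV column order is MCC, AUC, Acc, Sen, Spe.
#'
#' @param report a list from [metricsReport()].
#' @param path output path.
#' @param format `"json"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
writeMetrics <- function(report, path, format = c("json", "tsv")) {
  format <- match.arg(format)
  vals <- report[c("MCC", "AUC", "Acc", "Sen", "Spe")]
  if (format == "json")
    jsonlite::write_json(vals, path, digits = NA, auto_unbox = TRUE)
  else
    utils::write.table(as.data.frame(vals), path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(path)
}
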