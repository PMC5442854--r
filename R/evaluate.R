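# Confusion matrices and diagnostic metrics, with tumour as the positive
# class throughout, plus the sample-level aggregation rule used in the
# ex-vivo validation experiments.

#' Confusion matrix and diagnostic metrics
#'
#' Builds a 2 x 3 confusion matrix (truth normal/tumour by call
#' normal/tumour/other, where "other" collects outlier and indeterminate
#' calls) and reports sensitivity (tumour recall), specificity (normal
#' recall) and overall accuracy as percentages. Other-calls are excluded
#' from the 2 x 2 metrics but counted and reported. The report refuses to
#' construct metrics inconsistent with its own matrix.
#'
#' @param truth Character vector of true labels in
#'   `c("normal", "tumour")`.
#' @param predicted Character vector of calls in `c("normal", "tumour",
#'   "outlier", "indeterminate")`, same length.
#' @param n_patients Optional patient count carried in the report.
#' @return Object of class `metrics_report`: `confusion` (2 x 3 matrix),
#'   `sensitivity`, `specificity`, `accuracy` (percent), `n_samples`,
#'   `n_classified`, `n_other`, `n_patients`.
#' @examples
#' metrics_report(rep(c("tumour", "normal"), c(99, 161)),
#'                rep(c("tumour", "normal", "normal", "tumour"),
#'                    c(90, 9, 159, 2)))
#' @export
metrics_report <- function(truth, predicted, n_patients = NA_integer_) {
  truth <- as.character(truth)
  predicted <- as.character(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  if (!all(truth %in% c("normal", "tumour")))
    stop("truth labels must be 'normal' or 'tumour'")
  allowed <- c("normal", "tumour", "outlier", "indeterminate")
  if (!all(predicted %in% allowed))
    stop("predicted labels outside the model's class set: ",
         paste(setdiff(unique(predicted), allowed), collapse = ", "))
  call3 <- ifelse(predicted %in% c("normal", "tumour"), predicted, "other")
  confusion <- table(factor(truth, c("normal", "tumour")),
                     factor(call3, c("normal", "tumour", "other")))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("truth", "call")
  TP <- confusion["tumour", "tumour"]
  FN <- confusion["tumour", "normal"]
  TN <- confusion["normal", "normal"]
  FP <- confusion["normal", "tumour"]
  n_classified <- TP + FN + TN + FP
  pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  out <- structure(list(
    confusion = confusion,
    sensitivity = pct(TP, TP + FN),
    specificity = pct(TN, TN + FP),
    accuracy = pct(TP + TN, n_classified),
    n_samples = length(truth), n_classified = n_classified,
    n_other = sum(confusion[, "other"]),
    n_patients = n_patients), class = "metrics_report")
  stopifnot(sum(out$confusion) == out$n_samples,
            isTRUE(is.na(out$accuracy)) ||
              abs(out$accuracy - 100 * (TP + TN) / n_classified) < 1e-9)
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Confusion matrix (rows = histology, columns = call):\n")
  print(x$confusion)
  fmt <- function(v) if (is.na(v)) "NA" else sprintf("%.1f%%", v)
  cat(sprintf("sensitivity %s  specificity %s  accuracy %s  (n = %d",
              fmt(x$sensitivity), fmt(x$specificity), fmt(x$accuracy),
              x$n_samples))
  if (!is.na(x$n_patients)) cat(sprintf(", patients = %d", x$n_patients))
  if (x$n_other > 0) cat(sprintf(", other calls = %d", x$n_other))
  cat(")\n")
  invisible(x)
}

#' Build a metrics report from confusion-matrix counts
#'
#' Convenience wrapper expanding counts into label vectors so the report is
#' constructed through the same validated path as [metrics_report()].
#'
#' @param tp,fn,tn,fp Counts (tumour = positive class).
#' @param n_patients Optional patient count.
#' @return A [metrics_report()].
#' @examples
#' metrics_from_counts(tp = 90, fn = 9, tn = 159, fp = 2)
#' @export
metrics_from_counts <- function(tp, fn, tn, fp,
                                n_patients = NA_integer_) {
  truth <- rep(c("tumour", "tumour", "normal", "normal"),
               c(tp, fn, tn, fp))
  predicted <- rep(c("tumour", "normal", "normal", "tumour"),
                   c(tp, fn, tn, fp))
  metrics_report(truth, predicted, n_patients = n_patients)
}

#' Aggregate per-burn predictions to sample level and score
#'
#' Applies the sample-level decision rule — tumour if at least one
#' non-outlier burn is called tumour, normal only if every non-outlier
#' burn is normal, indeterminate if all burns are outliers — then builds a
#' [metrics_report()] at the sample level.
#'
#' @param dataset A [reims_dataset()] providing truth labels (B3/B4
#'   samples are excluded from scoring).
#' @param per_burn_predictions Named list, sample_id -> character vector of
#'   per-burn calls (`"normal"`, `"tumour"`, `"outlier"`). Every scored
#'   sample needs at least one prediction.
#' @return List with `sample_calls` (data.frame) and `metrics`.
#' @export
aggregate_and_score <- function(dataset, per_burn_predictions) {
  meta <- summary(dataset)
  meta <- meta[meta$tissue_class %in% c("normal", "tumour"), ,
               drop = FALSE]
  calls <- vapply(meta$sample_id, function(sid) {
    p <- per_burn_predictions[[sid]]
    if (is.null(p) || !length(p))
      stop("sample ", sid, " has no burn predictions")
    informative <- p[p != "outlier"]
    if (!length(informative)) "indeterminate"
    else if (any(informative == "tumour")) "tumour"
    else "normal"
  }, character(1))
  sample_calls <- data.frame(sample_id = meta$sample_id,
                             truth = meta$tissue_class,
                             call = unname(calls),
                             stringsAsFactors = FALSE)
  list(sample_calls = sample_calls,
       metrics = metrics_report(sample_calls$truth, sample_calls$call,
                                n_patients =
                                  length(unique(meta$patient_id))))
}
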