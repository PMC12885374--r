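#' One-vs-rest confusion counts
#'
#' Binarizes truth and prediction against `positive_class` and tallies the
#' four cells of the 2x2 table.
#'
#' @param y_true,y_pred equal-length label vectors.
#' @param positive_class the label treated as positive.
#' @return An object of class `confusion_counts` with fields `TP`, `TN`,
#'   `FP`, `FN` summing to `length(y_true)`.
#' @export
confusion_counts <- function(y_true, y_pred, positive_class) {
  if (length(y_true) != length(y_pred))
    stop_config("y_true and y_pred lengths differ (%d vs %d)",
                length(y_true), length(y_pred))
  if (length(y_true) == 0L) stop_config("empty label vectors")
  tp <- y_true == positive_class
  pp <- y_pred == positive_class
  structure(list(TP = sum(tp & pp), TN = sum(!tp & !pp),
                 FP = sum(!tp & pp), FN = sum(tp & !pp)),
            class = "confusion_counts")
}

safe_div <- function(num, den) if (den == 0) NA_real_ else num / den

#' Binary performance metrics from confusion counts
#'
#' Evaluates the standard confusion-table formulas: accuracy, error
#' (1 - accuracy), recall (sensitivity), specificity, precision, false
#' positive rate, F1, the Matthews correlation coefficient
#' \deqn{MCC = \frac{TP\cdot TN - FP\cdot FN}
#'   {\sqrt{(TP+FP)(TP+FN)(TN+FP)(TN+FN)}},}
#' and Cohen's kappa `(Po - Pe)/(1 - Pe)` with observed agreement
#' `Po = (TP+TN)/n` and expected agreement
#' `Pe = ((TP+FP)(TP+FN) + (FN+TN)(FP+TN)) / n^2`.
#' Any zero denominator yields `NA` rather than an error.
#'
#' @param cc a [confusion_counts()].
#' @return Named list of class `metrics_report` with the nine scalars.
#' @export
compute_metrics <- function(cc) {
  stopifnot(inherits(cc, "confusion_counts"))
  TP <- cc$TP; TN <- cc$TN; FP <- cc$FP; FN <- cc$FN
  n <- TP + TN + FP + FN
  if (n == 0) stop_config("no evaluated samples")
  acc <- (TP + TN) / n
  prec <- safe_div(TP, TP + FP)
  rec <- safe_div(TP, TP + FN)
  f1 <- if (is.na(prec) || is.na(rec) || (prec + rec) == 0) NA_real_
        else 2 * prec * rec / (prec + rec)
  mcc_den <- sqrt(as.numeric(TP + FP)) * sqrt(as.numeric(TP + FN)) *
             sqrt(as.numeric(TN + FP)) * sqrt(as.numeric(TN + FN))
  mcc <- if (mcc_den == 0) NA_real_ else
    (as.numeric(TP) * TN - as.numeric(FP) * FN) / mcc_den
  po <- acc
  pe <- (as.numeric(TP + FP) * (TP + FN) + as.numeric(FN + TN) * (FP + TN)) / n^2
  kappa <- if (pe == 1) NA_real_ else (po - pe) / (1 - pe)
  structure(list(accuracy = acc, error = 1 - acc, recall = rec,
                 specificity = safe_div(TN, TN + FP), precision = prec,
                 fpr = safe_div(FP, FP + TN), f1 = f1, mcc = mcc,
                 kappa = kappa),
            class = "metrics_report")
}

#' Macro-averaged multiclass metrics
#'
#' Computes one-vs-rest metrics for every class and reports their unweighted
#' (macro) mean, except accuracy/error which are computed globally from the
#' multiclass confusion matrix trace. Classes absent from `y_true` are
#' excluded from the macro mean with a warning.
#'
#' @param y_true,y_pred label vectors.
#' @param classes class set; defaults to the labels observed in either
#'   vector.
#' @return A `metrics_report` list with an extra `per_class` data.frame
#'   (one-vs-rest metrics per class).
#' @export
macro_metrics <- function(y_true, y_pred, classes = NULL) {
  if (is.null(classes)) classes <- sort(unique(c(y_true, y_pred)))
  if (length(classes) < 2L) stop_config("need at least 2 classes")
  present <- classes %in% y_true
  if (any(!present))
    warning(sprintf("class(es) %s absent from y_true; excluded from macro mean",
                    paste(classes[!present], collapse = ", ")))
  per <- lapply(classes[present], function(k)
    compute_metrics(confusion_counts(y_true, y_pred, k)))
  per_df <- cbind(data.frame(class = classes[present]),
                  do.call(rbind, lapply(per, function(m)
                    as.data.frame(unclass(m)))))
  macro <- function(field) mean(vapply(per, `[[`, numeric(1), field), na.rm = TRUE)
  acc <- mean(y_true == y_pred)
  structure(list(accuracy = acc, error = 1 - acc,
                 recall = macro("recall"), specificity = macro("specificity"),
                 precision = macro("precision"), fpr = macro("fpr"),
                 f1 = macro("f1"), mcc = macro("mcc"), kappa = macro("kappa"),
                 per_class = per_df),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  flds <- c("accuracy", "error", "recall", "specificity", "precision",
            "fpr", "f1", "mcc", "kappa")
  cat("<metrics_report>\n")
  for (f in flds) cat(sprintf("  %-12s %.4f\n", f, x[[f]]))
  invisible(x)
}

#' One-sample Student t test
#'
#' `t = (mean - mu0) / (sd / sqrt(n))` with `df = n - 1` and a two-tailed
#' p-value from the t distribution.
#'
#' @param values numeric vector, length >= 2, nonzero variance.
#' @param mu0 hypothesized mean.
#' @return List with `t`, `df`, `p_two_tailed`.
#' @export
one_sample_t_test <- function(values, mu0) {
  if (length(values) < 2L) stop_config("need at least 2 values")
  s <- sd(values)
  if (s == 0) stop_config("zero variance; t statistic undefined")
  n <- length(values)
  t <- (mean(values) - mu0) / (s / sqrt(n))
  df <- n - 1L
  list(t = t, df = df, p_two_tailed = t_test_p_value(t, df))
}

#' Two-tailed p-value kernel
#'
#' @param t t statistic.
#' @param df degrees of freedom.
#' @return `2 * P(T_df > |t|)`.
#' @export
t_test_p_value <- function(t, df) 2 * pt(abs(t), df, lower.tail = FALSE)

#' Confidence interval for a mean
#'
#' `mean +/- t_{df,(1+level)/2} * sd / sqrt(n)`. Constant values give a
#' zero-width interval at the constant.
#'
#' @param values numeric vector, length >= 2.
#' @param level confidence level in (0, 1), default 0.95.
#' @return Numeric `c(lo, hi)`.
#' @export
mean_confidence_interval <- function(values, level = 0.95) {
  if (length(values) < 2L) stop_config("need at least 2 values")
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop_config("level must lie in (0, 1)")
  m <- mean(values)
  s <- sd(values)
  if (s == 0) return(c(lo = m, hi = m))
  half <- qt((1 + level) / 2, length(values) - 1L) * s / sqrt(length(values))
  c(lo = m - half, hi = m + half)
}
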