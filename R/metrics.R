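# Confusion-matrix diagnostics, the weighted FNR/FPR cross-validation
# fitness, and repeated-run summary statistics.

#' Construct a confusion matrix for one binary evaluation
#'
#' Counts follow the diagnostic convention: the positive class is the
#' diseased class, so a false negative is a missed diagnosis and a false
#' positive a misdiagnosis.
#'
#' @param tp,fn,fp,tn non-negative integer counts of true positives, false
#'   negatives, false positives and true negatives.
#' @return An object of class `"confusion_matrix"`: a list with fields
#'   `tp`, `fn`, `fp`, `tn`.
#' @examples
#' confusion_matrix(tp = 16, fn = 0, fp = 1, tn = 39)
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  cm <- list(
    tp = check_count(tp, "tp", min = 0L),
    fn = check_count(fn, "fn", min = 0L),
    fp = check_count(fp, "fp", min = 0L),
    tn = check_count(tn, "tn", min = 0L)
  )
  if (cm$tp + cm$fn + cm$fp + cm$tn < 1L) {
    stopf("confusion matrix must contain at least one sample")
  }
  structure(cm, class = "confusion_matrix")
}

#' Tabulate a confusion matrix from labels and predictions
#'
#' @param truth,predicted vectors over \{+1, -1\} (numeric or factor with
#'   those levels) of equal length.
#' @return A [confusion_matrix()].
#' @export
confusion_from_predictions <- function(truth, predicted) {
  truth <- as.numeric(as.character(truth))
  predicted <- as.numeric(as.character(predicted))
  if (length(truth) != length(predicted)) {
    stopf("`truth` and `predicted` must have equal length")
  }
  if (!all(truth %in% c(-1, 1)) || !all(predicted %in% c(-1, 1))) {
    stopf("labels must lie in {+1, -1}")
  }
  confusion_matrix(
    tp = sum(truth == 1 & predicted == 1),
    fn = sum(truth == 1 & predicted == -1),
    fp = sum(truth == -1 & predicted == 1),
    tn = sum(truth == -1 & predicted == -1)
  )
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2, byrow = TRUE,
              dimnames = list(c("actual +1", "actual -1"),
                              c("pred +1", "pred -1")))
  print(m)
  invisible(x)
}

#' Diagnostic rates from a confusion matrix
#'
#' Computes the false positive rate FP/N, false negative rate FN/P,
#' accuracy (TP+TN)/(P+N), precision TP/(TP+FP), recall TP/P, and the F1
#' value 2/(1/precision + 1/recall). FNR is the missed-diagnosis rate
#' (complement of sensitivity); FPR is the misdiagnosis rate (complement
#' of specificity).
#'
#' Both classes must be present (P >= 1 and N >= 1); otherwise the rates
#' are undefined and an error names the empty class. When no sample is
#' predicted positive, precision is undefined and reported as `NA`; F1 is
#' defined as 0 whenever `tp == 0` so comparison harnesses never crash on
#' degenerate classifiers.
#'
#' @param cm a [confusion_matrix()].
#' @return An object of class `"classification_metrics"`: a list with
#'   fields `fpr`, `fnr`, `accuracy`, `precision`, `recall`, `f1`, all in
#'   `[0, 1]` (precision possibly `NA`).
#' @examples
#' rates_from_confusion(confusion_matrix(16, 0, 1, 39))
#' @export
rates_from_confusion <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  p <- cm$tp + cm$fn
  n <- cm$fp + cm$tn
  if (p < 1L) stopf("invalid evaluation: positive class is empty (P = 0)")
  if (n < 1L) stopf("invalid evaluation: negative class is empty (N = 0)")
  recall <- cm$tp / p
  precision <- if (cm$tp + cm$fp >= 1L) cm$tp / (cm$tp + cm$fp) else NA_real_
  f1 <- if (cm$tp == 0L) 0 else 2 / (1 / precision + 1 / recall)
  structure(
    list(
      fpr = cm$fp / n,
      fnr = cm$fn / p,
      accuracy = (cm$tp + cm$tn) / (p + n),
      precision = precision,
      recall = recall,
      f1 = f1
    ),
    class = "classification_metrics"
  )
}

#' @export
print.classification_metrics <- function(x, ...) {
  cat(sprintf(
    "FPR %.4f  FNR %.4f  Accuracy %.4f  Precision %s  F1 %.4f\n",
    x$fpr, x$fnr, x$accuracy,
    if (is.na(x$precision)) "NA" else sprintf("%.4f", x$precision), x$f1
  ))
  invisible(x)
}

#' Fitness configuration for the weighted cross-validation objective
#'
#' @param k_folds number of cross-validation folds K (default 5).
#' @param fnr_weight weight `w` in `[0, 1]` given to the false negative
#'   rate; the false positive rate receives `1 - w`. The default 0.9
#'   encodes that a missed diagnosis is far costlier than a false alarm.
#' @return An object of class `"fitness_config"`.
#' @export
fitness_config <- function(k_folds = 5L, fnr_weight = 0.9) {
  structure(
    list(
      k_folds = check_count(k_folds, "k_folds", min = 2L),
      fnr_weight = check_prob(fnr_weight, "fnr_weight")
    ),
    class = "fitness_config"
  )
}

#' Weighted mean of per-fold FNR and FPR
#'
#' The smell-concentration determination function: the mean over K folds
#' of `w * FNR_k + (1 - w) * FPR_k`. Smaller is better; the value lies in
#' `[0, 1]`.
#'
#' @param fold_rates a matrix or data frame with one row per fold and
#'   columns `fnr` and `fpr`, each rate in `[0, 1]`.
#' @param w weight of the false negative rate, in `[0, 1]`.
#' @return The fitness, a single number in `[0, 1]`.
#' @examples
#' weighted_cv_fitness(data.frame(fnr = c(0.5, 0), fpr = c(0.1, 0.2)), w = 0.9)
#' @export
weighted_cv_fitness <- function(fold_rates, w) {
  w <- check_prob(w, "w")
  fold_rates <- as.data.frame(fold_rates)
  if (nrow(fold_rates) < 1L) stopf("`fold_rates` must contain at least one fold")
  if (!all(c("fnr", "fpr") %in% names(fold_rates))) {
    stopf("`fold_rates` must have columns `fnr` and `fpr`")
  }
  fnr <- as.numeric(fold_rates$fnr)
  fpr <- as.numeric(fold_rates$fpr)
  if (anyNA(fnr) || anyNA(fpr) || any(fnr < 0 | fnr > 1) ||
      any(fpr < 0 | fpr > 1)) {
    stopf("fold rates must be numbers in [0, 1]")
  }
  mean(w * fnr + (1 - w) * fpr)
}

#' Mean and sample standard deviation of repeated-run results
#'
#' Summarizes a column of repeated-run results as the arithmetic mean and
#' the sample standard deviation (denominator n - 1). A single value has
#' standard deviation 0 by convention.
#'
#' @param values numeric vector, length >= 1.
#' @return A list with fields `mean` and `sample_std`.
#' @examples
#' summarize_runs(c(0, 2))
#' @export
summarize_runs <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 1L || anyNA(values)) {
    stopf("`values` must be a non-empty numeric vector without NA")
  }
  s <- if (length(values) == 1L) 0 else stats::sd(values)
  list(mean = mean(values), sample_std = s)
}

#' Write a per-run metrics report as CSV
#'
#' Writes one row per run with columns `run`, `C`, `gamma`, `FPR`, `FNR`,
#' `Accuracy`, `Precision`, `F1`, followed by trailing `mu` and `s` rows
#' (mean and sample standard deviation). Rate columns are formatted as
#' percentages with two decimals in the per-run and `mu` rows; the `s` row
#' keeps the proportion scale, matching the reporting convention for
#' repeated diagnostic experiments.
#'
#' @param runs data frame with numeric columns `C`, `gamma`, `FPR`, `FNR`,
#'   `Accuracy`, `Precision`, `F1` (rates as proportions in `[0, 1]`).
#' @param path output file path.
#' @return Invisibly, the formatted data frame that was written.
#' @export
write_metrics_report <- function(runs, path) {
  cols <- c("C", "gamma", "FPR", "FNR", "Accuracy", "Precision", "F1")
  if (!all(cols %in% names(runs))) {
    stopf("`runs` must have columns %s", paste(cols, collapse = ", "))
  }
  rate_cols <- c("FPR", "FNR", "Accuracy", "Precision", "F1")
  pct <- function(x) sprintf("%.2f%%", 100 * x)
  body <- data.frame(run = as.character(seq_len(nrow(runs))),
                     stringsAsFactors = FALSE)
  for (cc in c("C", "gamma")) body[[cc]] <- sprintf("%.6g", runs[[cc]])
  for (cc in rate_cols) body[[cc]] <- pct(runs[[cc]])
  mu <- data.frame(run = "mu",
                   C = sprintf("%.6g", mean(runs$C)),
                   gamma = sprintf("%.6g", mean(runs$gamma)),
                   stringsAsFactors = FALSE)
  s <- data.frame(run = "s",
                  C = sprintf("%.6g", summarize_runs(runs$C)$sample_std),
                  gamma = sprintf("%.6g", summarize_runs(runs$gamma)$sample_std),
                  stringsAsFactors = FALSE)
  for (cc in rate_cols) {
    mu[[cc]] <- pct(mean(runs[[cc]]))
    s[[cc]] <- sprintf("%.4f", summarize_runs(runs[[cc]])$sample_std)
  }
  out <- rbind(body, mu, s)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(out)
}
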