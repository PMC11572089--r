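#' Test-set coefficient of determination
#'
#' `1 - SS_res / SS_tot` with the total sum of squares taken around the
#' test-set mean. Out-of-sample R-squared can be negative (the model predicts
#' worse than the test mean); it never exceeds 1.
#'
#' @param y_true Observed test values (length >= 2, not all identical).
#' @param y_pred Predicted values.
#' @return Single number, at most 1.
#' @export
r_squared <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred))
  if (length(y_true) < 2L) stop("need at least 2 observations", call. = FALSE)
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) {
    stop("all true values are identical: R-squared is undefined ",
         "(degenerate test truth)", call. = FALSE)
  }
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Rank-based AUC (Mann-Whitney form)
#'
#' The fraction of (positive, negative) pairs in which the positive case
#' receives the higher score, ties counting one half — equivalently the area
#' under the ROC curve. Computed from midranks, so it is exact under ties and
#' invariant to any strictly increasing transformation of the scores.
#'
#' @param y_true 0/1 vector with at least one positive and one negative.
#' @param scores Numeric scores (higher = more positive).
#' @return AUC in \[0, 1\].
#' @export
auc_rank <- function(y_true, scores) {
  stopifnot(length(y_true) == length(scores))
  y_true <- as.numeric(y_true)
  n_pos <- sum(y_true == 1)
  n_neg <- sum(y_true == 0)
  if (n_pos == 0 || n_neg == 0) {
    stop("AUC undefined with a single-class truth vector; ",
         "check exclusion status first", call. = FALSE)
  }
  r <- rank(scores, ties.method = "average")
  (sum(r[y_true == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Balanced accuracy at a fixed decision threshold
#'
#' Scores at or above `threshold` are classified positive; the result is the
#' mean of sensitivity (true-positive rate) and specificity (true-negative
#' rate), which is invariant to class prevalence given fixed per-class error
#' rates.
#'
#' @param y_true 0/1 vector with both classes present.
#' @param scores Numeric scores.
#' @param threshold Decision cutoff (default 0.5 on the sigmoid output).
#' @return Balanced accuracy in \[0, 1\].
#' @export
balanced_accuracy <- function(y_true, scores, threshold = 0.5) {
  stopifnot(length(y_true) == length(scores))
  y_true <- as.numeric(y_true)
  if (all(y_true == 1) || all(y_true == 0)) {
    stop("balanced accuracy undefined with a single-class truth vector; ",
         "check exclusion status first", call. = FALSE)
  }
  pred <- as.numeric(scores >= threshold)
  sens <- sum(pred == 1 & y_true == 1) / sum(y_true == 1)
  spec <- sum(pred == 0 & y_true == 0) / sum(y_true == 0)
  (sens + spec) / 2
}

#' Classify a replication's exclusion status
#'
#' Two degenerate outcomes are removed from decision-error estimation, on the
#' grounds that a researcher would recognise the fit as uninformative:
#' \describe{
#'   \item{`DEGENERATE_TEST_TRUTH`}{all true DV values in the test partition
#'     are identical, so performance can be judged on one subgroup only.
#'     Checked first.}
#'   \item{`CONSTANT_PREDICTION`}{the model scores every test row the same
#'     way — for classification, all thresholded classes agree (all 0 or all
#'     1); for regression, the predictions have zero range (< 1e-12).}
#' }
#' Everything else is `INCLUDED`.
#'
#' @param y_true_test True test-set DV values.
#' @param scores Model scores on the test set.
#' @param task `"regression"` or `"classification"`.
#' @param threshold Class-decision cutoff for classification (default 0.5).
#' @return One of `"INCLUDED"`, `"CONSTANT_PREDICTION"`,
#'   `"DEGENERATE_TEST_TRUTH"`.
#' @export
exclusion_status <- function(y_true_test, scores,
                             task = c("regression", "classification"),
                             threshold = 0.5) {
  task <- match.arg(task)
  if (length(y_true_test) == 0L) stop("empty test set", call. = FALSE)
  if (length(unique(y_true_test)) == 1L) {
    return("DEGENERATE_TEST_TRUTH")
  }
  constant <- if (task == "classification") {
    length(unique(scores >= threshold)) == 1L
  } else {
    diff(range(scores)) < 1e-12
  }
  if (constant) "CONSTANT_PREDICTION" else "INCLUDED"
}

#' Bundle test-set metrics for one replication
#'
#' Computes the task-appropriate metrics and the exclusion status. Metrics
#' that would be undefined for an excluded run are reported as `NA`.
#'
#' @param y_true_test True test-set DV values.
#' @param scores Model scores on the test set.
#' @param task `"regression"` or `"classification"`.
#' @param threshold Class-decision cutoff (classification).
#' @return Object of class `"nn_metrics"`: `task`, `exclusion`, and `r2`
#'   (regression) or `auc`, `balanced_accuracy`,
#'   `predicted_class_counts` (classification).
#' @export
metrics_report <- function(y_true_test, scores,
                           task = c("regression", "classification"),
                           threshold = 0.5) {
  task <- match.arg(task)
  excl <- exclusion_status(y_true_test, scores, task, threshold)
  out <- list(task = task, exclusion = excl)
  if (task == "regression") {
    out$r2 <- if (excl == "DEGENERATE_TEST_TRUTH") NA_real_ else
      r_squared(y_true_test, scores)
  } else {
    pred <- as.numeric(scores >= threshold)
    out$predicted_class_counts <- c(neg = sum(pred == 0), pos = sum(pred == 1))
    if (excl == "DEGENERATE_TEST_TRUTH") {
      out$auc <- NA_real_
      out$balanced_accuracy <- NA_real_
    } else {
      out$auc <- auc_rank(y_true_test, scores)
      out$balanced_accuracy <- balanced_accuracy(y_true_test, scores, threshold)
    }
  }
  structure(out, class = "nn_metrics")
}

#' @export
print.nn_metrics <- function(x, ...) {
  if (x$task == "regression") {
    cat(sprintf("<nn_metrics> regression: R2 = %s [%s]\n",
                format(x$r2), x$exclusion))
  } else {
    cat(sprintf("<nn_metrics> classification: AUC = %s, BA = %s [%s]\n",
                format(x$auc), format(x$balanced_accuracy), x$exclusion))
  }
  invisible(x)
}

#' Decision-error criteria
#'
#' A criterion is a metric identifier plus an inclusive threshold defining
#' "acceptable performance". The study set pairs R-squared >= .1 for
#' continuous DVs with AUC and balanced-accuracy thresholds .6, .65 and .7
#' for binary DVs.
#'
#' @param metric One of `"R2"`, `"AUC"`, `"BA"`.
#' @param threshold Inclusive threshold.
#' @return Object of class `"nn_criterion"`.
#' @export
de_criterion <- function(metric = c("R2", "AUC", "BA"), threshold) {
  metric <- match.arg(metric)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  structure(list(metric = metric, threshold = threshold),
            class = "nn_criterion")
}

#' The criteria used for one DV type in replication mode
#'
#' @param dv_kind `"continuous"` (R2 >= .1) or `"binary"` (AUC and BA at
#'   .6, .65, .7).
#' @return List of [de_criterion()] objects.
#' @export
default_criteria <- function(dv_kind = c("continuous", "binary")) {
  dv_kind <- match.arg(dv_kind)
  if (dv_kind == "continuous") {
    list(de_criterion("R2", 0.1))
  } else {
    c(lapply(c(0.6, 0.65, 0.7), function(th) de_criterion("AUC", th)),
      lapply(c(0.6, 0.65, 0.7), function(th) de_criterion("BA", th)))
  }
}

criterion_key <- function(cr) sprintf("%s>=%g", cr$metric, cr$threshold)

#' Flag decision errors for one replication
#'
#' A decision error is recorded when the metric value meets or exceeds the
#' criterion threshold (inclusive, as the thresholds are quoted). For an
#' excluded replication every flag is `NA`.
#'
#' @param report An [metrics_report()].
#' @param criteria List of [de_criterion()] objects.
#' @return Named logical vector, one flag per criterion (names like
#'   `"AUC>=0.6"`).
#' @export
evaluate_criteria <- function(report, criteria) {
  stopifnot(inherits(report, "nn_metrics"))
  if (inherits(criteria, "nn_criterion")) criteria <- list(criteria)
  vals <- vapply(criteria, function(cr) {
    value <- switch(cr$metric,
      R2 = if (report$task == "regression") report$r2 else
        stop("criterion R2 does not apply to a classification report",
             call. = FALSE),
      AUC = if (report$task == "classification") report$auc else
        stop("criterion AUC does not apply to a regression report",
             call. = FALSE),
      BA = if (report$task == "classification") report$balanced_accuracy else
        stop("criterion BA does not apply to a regression report",
             call. = FALSE)
    )
    if (report$exclusion != "INCLUDED" || is.na(value)) NA else
      value >= cr$threshold
  }, logical(1))
  names(vals) <- vapply(criteria, criterion_key, character(1))
  vals
}

#' Serialize a metrics report as a one-line JSON record
#'
#' @param report An [metrics_report()].
#' @param extra Optional named list merged into the record (e.g. condition
#'   fields, seed).
#' @return Single JSON string (no trailing newline), suitable for JSONL logs.
#' @export
metrics_to_json <- function(report, extra = NULL) {
  stopifnot(inherits(report, "nn_metrics"))
  rec <- c(extra, unclass(report))
  rec$predicted_class_counts <- as.list(rec$predicted_class_counts)
  as.character(jsonlite::toJSON(rec, digits = NA, auto_unbox = TRUE,
                                na = "null"))
}
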