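# Evaluation metrics: confusion matrices, F1, Matthews correlation
# coefficient, Brier Skill Score, subject-level aggregation and the
# cross-fold evaluation report. Convention throughout: healthy = negative /
# inlier class, pathology = positive / outlier class.

#' Build a confusion matrix from counts or from labels
#'
#' @param tn,fp,fn,tp non-negative counts, or
#' @param truth,predicted logical/0-1 vectors (positive = outlier) used when
#'   counts are not supplied.
#' @return a named list of class `confusion_matrix` with `tn`, `fp`, `fn`,
#'   `tp`.
#' @export
confusion_matrix <- function(tn = NULL, fp = NULL, fn = NULL, tp = NULL,
                             truth = NULL, predicted = NULL) {
  if (is.null(tn)) {
    stopifnot(length(truth) == length(predicted))
    truth <- as.logical(truth); predicted <- as.logical(predicted)
    tn <- sum(!truth & !predicted); fp <- sum(!truth & predicted)
    fn <- sum(truth & !predicted); tp <- sum(truth & predicted)
  }
  stopifnot(tn >= 0, fp >= 0, fn >= 0, tp >= 0)
  structure(list(tn = tn, fp = fp, fn = fn, tp = tp),
            class = "confusion_matrix")
}

#' Matthews correlation coefficient
#'
#' `(tp*tn - fp*fn) / sqrt((tp+fp)(tp+fn)(tn+fp)(tn+fn))`; defined as 0
#' when any marginal is zero.
#'
#' @param cm a [confusion_matrix()].
#' @return scalar in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  tp <- as.numeric(cm$tp); tn <- as.numeric(cm$tn)
  fp <- as.numeric(cm$fp); fn <- as.numeric(cm$fn)
  denom <- (tp + fp) * (tp + fn) * (tn + fp) * (tn + fn)
  if (denom == 0) return(0)
  (tp * tn - fp * fn) / sqrt(denom)
}

#' F1 score
#'
#' `2*tp / (2*tp + fp + fn)`; defined as 0 when the denominator is zero.
#'
#' @param cm a [confusion_matrix()].
#' @return scalar in `[0, 1]`.
#' @export
f1 <- function(cm) {
  denom <- 2 * as.numeric(cm$tp) + as.numeric(cm$fp) + as.numeric(cm$fn)
  if (denom == 0) return(0)
  2 * as.numeric(cm$tp) / denom
}

#' Brier Skill Score
#'
#' `1 - BS / BS_naive`, where `BS` is the mean squared error of the
#' forecast probabilities against the binary labels and `BS_naive` the
#' Brier score of the constant base-rate forecast (the empirical positive
#' fraction of `labels`). 1 = perfect, 0 = no skill beyond the base rate,
#' negative = worse than the naive forecast. Appropriate for (partly)
#' imbalanced classes.
#'
#' @param probabilities forecast probabilities in `[0, 1]`.
#' @param labels 0/1 outcomes.
#' @return scalar (at most 1).
#' @export
brier_skill_score <- function(probabilities, labels) {
  p <- as.numeric(probabilities); y <- as.numeric(labels)
  stopifnot(length(p) == length(y), all(p >= 0 & p <= 1), all(y %in% c(0, 1)))
  base <- mean(y)
  bs_naive <- mean((base - y)^2)
  if (bs_naive == 0) {
    stop("degenerate single-class label set: naive Brier score is 0")
  }
  1 - mean((p - y)^2) / bs_naive
}

#' Aggregate per-sample outlier probabilities to subject level
#'
#' A subject's prediction is the mean outlier probability over its repeated
#' measurements; the subject is classified as an outlier when the mean
#' reaches `threshold`. The class probability difference `|2*mean - 1|`
#' flags low-confidence subjects (difference below `low_conf_margin`).
#'
#' @param predictions data frame with columns `subject_id`,
#'   `outlier_probability`, and optionally `group`.
#' @param threshold classification threshold on the mean probability
#'   (default 0.5).
#' @param low_conf_margin low-confidence margin on `|2*mean - 1|`
#'   (default 0.2).
#' @return data frame with one row per subject: `subject_id`, `group` (if
#'   available), `mean_outlier_probability`, `sd_outlier_probability`,
#'   `predicted_class`, `probability_difference`, `low_confidence`.
#' @export
aggregate_subject_predictions <- function(predictions, threshold = 0.5,
                                          low_conf_margin = 0.2) {
  stopifnot(all(c("subject_id", "outlier_probability") %in% names(predictions)))
  sp <- split_c(predictions, predictions$subject_id)
  out <- do.call(rbind, lapply(sp, function(d) {
    m <- mean(d$outlier_probability)
    data.frame(
      subject_id = d$subject_id[1],
      group = if ("group" %in% names(d)) d$group[1] else NA_character_,
      n_samples = nrow(d),
      mean_outlier_probability = m,
      sd_outlier_probability = if (nrow(d) > 1) sd(d$outlier_probability) else 0,
      predicted_class = if (m >= threshold) "outlier" else "healthy",
      probability_difference = abs(2 * m - 1),
      low_confidence = abs(2 * m - 1) < low_conf_margin,
      stringsAsFactors = FALSE
    )
  }))
  rownames(out) <- NULL
  out[order(-out$mean_outlier_probability), , drop = FALSE]
}

#' Assemble the cross-fold evaluation report
#'
#' @param per_fold_results list with one element per fold, each a list with
#'   `cm` (a [confusion_matrix()]), `f1`, `mcc`, `bss`, and `predictions`
#'   (per-sample data frame incl. `subject_id`, `group`,
#'   `outlier_probability`, `fold`).
#' @param threshold,low_conf_margin passed to
#'   [aggregate_subject_predictions()].
#' @return a list of class `evaluation_report`: `per_fold` (metric data
#'   frame), `mean`/`sd` (named F1/MCC/BSS summaries across folds, sample
#'   SD), `confusion` (summed counts), `predictions` (pooled per-sample),
#'   `subjects` (per-subject aggregation).
#' @export
build_report <- function(per_fold_results, threshold = 0.5,
                         low_conf_margin = 0.2) {
  stopifnot(length(per_fold_results) >= 1)
  per_fold <- data.frame(
    fold = seq_along(per_fold_results),
    f1 = vapply(per_fold_results, function(r) r$f1, numeric(1)),
    mcc = vapply(per_fold_results, function(r) r$mcc, numeric(1)),
    bss = vapply(per_fold_results, function(r) r$bss, numeric(1))
  )
  summed <- Reduce(function(a, b) Map(`+`, a, b),
                   lapply(per_fold_results, function(r) unclass(r$cm)))
  preds <- do.call(rbind, lapply(per_fold_results, function(r) r$predictions))
  structure(list(
    per_fold = per_fold,
    mean = c(f1 = mean(per_fold$f1), mcc = mean(per_fold$mcc),
             bss = mean(per_fold$bss)),
    sd = c(f1 = sd(per_fold$f1), mcc = sd(per_fold$mcc),
           bss = sd(per_fold$bss)),
    confusion = do.call(confusion_matrix, summed),
    predictions = preds,
    subjects = aggregate_subject_predictions(preds, threshold, low_conf_margin)
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report>\n")
  for (m in c("f1", "mcc", "bss")) {
    cat(sprintf("  %-4s %.3f +/- %.3f\n", toupper(m), x$mean[[m]], x$sd[[m]]))
  }
  cm <- x$confusion
  cat(sprintf("  summed CM (rows = predicted, cols = true):\n"))
  cat(sprintf("    healthy  %5d %5d\n", cm$tn, cm$fn))
  cat(sprintf("    outlier  %5d %5d\n", cm$fp, cm$tp))
  invisible(x)
}
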