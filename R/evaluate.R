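#' Confusion counts with malignant as the positive class
#'
#' @param truth,pred Aligned label vectors (benign/malignant).
#' @return A `confusion_counts` list: `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, pred) {
  if (length(truth) != length(pred)) stopf("truth and pred must be the same length")
  check_labels(truth, "truth")
  check_labels(pred, "pred")
  structure(list(
    tp = sum(truth == "malignant" & pred == "malignant"),
    fp = sum(truth == "benign" & pred == "malignant"),
    tn = sum(truth == "benign" & pred == "benign"),
    fn = sum(truth == "malignant" & pred == "benign")
  ), class = "confusion_counts")
}

#' Build confusion counts directly
#'
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @return A `confusion_counts`.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stopf("counts must be non-negative integers")
  }
  structure(as.list(counts), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion_counts> tp=%d fp=%d tn=%d fn=%d (malignant = positive)\n",
              x$tp, x$fp, x$tn, x$fn))
  invisible(x)
}

#' Performance metrics from confusion counts
#'
#' Sensitivity `tp/(tp+fn)`, specificity `tn/(tn+fp)`, PPV `tp/(tp+fp)`,
#' NPV `tn/(tn+fn)` and accuracy `(tp+tn)/n`, as percentages at full
#' precision; any metric with a zero denominator is `NA` with
#' `defined = FALSE`. Use [format_metrics()] for the one-decimal half-up
#' display convention.
#'
#' @param cc A `confusion_counts` (from [confusion()] or
#'   [confusion_counts()]).
#' @return Tibble: `metric`, `numerator`, `denominator`, `value`
#'   (percent), `defined`.
#' @export
metrics <- function(cc) {
  n <- cc$tp + cc$fp + cc$tn + cc$fn
  if (n == 0L) stopf("no observations")
  num <- c(sensitivity = cc$tp, specificity = cc$tn, ppv = cc$tp,
           npv = cc$tn, accuracy = cc$tp + cc$tn)
  den <- c(sensitivity = cc$tp + cc$fn, specificity = cc$tn + cc$fp,
           ppv = cc$tp + cc$fp, npv = cc$tn + cc$fn, accuracy = n)
  tibble::tibble(
    metric = names(num),
    numerator = unname(num),
    denominator = unname(den),
    value = unname(ifelse(den > 0, 100 * num / den, NA_real_)),
    defined = unname(den > 0)
  )
}

#' Format a metric table for display
#'
#' Rounds percentage values half-up to `digits` decimals (the convention of
#' the clinical performance tables) and renders undefined metrics as `"--"`.
#'
#' @param m A [metrics()] tibble.
#' @param digits Decimal places (default 1).
#' @return The tibble with an added `display` column.
#' @export
format_metrics <- function(m, digits = 1) {
  m$display <- ifelse(
    m$defined,
    sprintf(paste0("%.", digits, "f (%d/%d)"),
            round_half_up(m$value, digits), m$numerator, m$denominator),
    "--"
  )
  m
}

#' McNemar test between two paired classifiers
#'
#' Counts the discordant lesions `b` (A correct, B wrong) and `c` (A wrong,
#' B correct). For `b + c < exact_limit` the exact two-sided binomial p is
#' used (`2 * P[X <= min(b, c)]` at p = 1/2, capped at 1); otherwise the
#' continuity-corrected chi-square `(|b - c| - 1)^2 / (b + c)` on 1 df.
#' `b + c = 0` returns p = 1 by convention.
#'
#' @param pred_a,pred_b Aligned prediction label vectors.
#' @param truth Aligned truth labels.
#' @param exact_limit Switch point between exact and chi-square (default 25).
#' @return Tibble row: `b`, `c`, `method`, `statistic`, `p_value`.
#' @export
mcnemar_paired <- function(pred_a, pred_b, truth, exact_limit = 25L) {
  if (length(pred_a) != length(truth) || length(pred_b) != length(truth)) {
    stopf("prediction and truth vectors must be aligned")
  }
  a_ok <- pred_a == truth
  b_ok <- pred_b == truth
  b <- sum(a_ok & !b_ok)
  c <- sum(!a_ok & b_ok)
  if (b + c == 0L) {
    return(tibble::tibble(b = b, c = c, method = "none",
                          statistic = NA_real_, p_value = 1))
  }
  if (b + c < exact_limit) {
    p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
    tibble::tibble(b = b, c = c, method = "exact", statistic = NA_real_,
                   p_value = p)
  } else {
    stat <- (abs(b - c) - 1)^2 / (b + c)
    tibble::tibble(b = b, c = c, method = "chisq",
                   statistic = stat,
                   p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE))
  }
}
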