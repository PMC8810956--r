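# normalise labels to logical (TRUE = positive)
.as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1")
    return(labels == 1)
  }
  if (is.character(labels) || is.factor(labels)) {
    labels <- as.character(labels)
    if (!all(labels %in% c("positive", "negative"))) {
      stop("character labels must be 'positive'/'negative'")
    }
    return(labels == "positive")
  }
  stop("unsupported label type")
}

#' Confusion counts at a probability threshold
#'
#' A patch is predicted positive iff its probability is greater than or
#' equal to the threshold.
#'
#' @param probs Numeric probabilities in `[0, 1]`.
#' @param labels Ground truth: logical, 0/1 or `"positive"`/`"negative"`.
#' @param threshold Decision threshold in `[0, 1]`.
#' @return An object of class `confusion_counts` with fields `tp`, `fp`,
#'   `tn`, `fn`.
#' @export
confusion_at_threshold <- function(probs, labels, threshold) {
  if (length(probs) == 0L) stop("empty input")
  labels <- .as_binary_labels(labels)
  if (length(probs) != length(labels)) stop("probs and labels differ in length")
  if (threshold < 0 || threshold > 1) stop("threshold must be in [0, 1]")
  pred <- probs >= threshold
  confusion_counts(tp = sum(pred & labels), fp = sum(pred & !labels),
                   tn = sum(!pred & !labels), fn = sum(!pred & labels))
}

#' @rdname confusion_at_threshold
#' @param tp,fp,tn,fn Non-negative integer counts.
#' @export
confusion_counts <- function(tp, fp, tn, fn) {
  counts <- c(tp = tp, fp = fp, tn = tn, fn = fn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  structure(lapply(as.list(counts), as.integer), class = "confusion_counts")
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("<confusion> tp=%d fp=%d tn=%d fn=%d (n=%d)\n",
              x$tp, x$fp, x$tn, x$fn, x$tp + x$fp + x$tn + x$fn))
  invisible(x)
}

#' Proportion metrics from confusion counts
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), ppv = tp/(tp+fp),
#' accuracy = (tp+tn)/n. A metric whose denominator is zero is returned as
#' `NA` and named in the `undefined` attribute instead of silently
#' propagating NaN.
#'
#' @param counts A [confusion_counts()].
#' @return Named list of proportions in `[0, 1]` (class
#'   `metrics_fragment`) with attribute `undefined` listing any metrics
#'   whose denominator was zero.
#' @export
metrics_from_confusion <- function(counts) {
  stopifnot(inherits(counts, "confusion_counts"))
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  out <- list(
    sensitivity = rate(counts$tp, counts$tp + counts$fn),
    specificity = rate(counts$tn, counts$tn + counts$fp),
    ppv = rate(counts$tp, counts$tp + counts$fp),
    accuracy = rate(counts$tp + counts$tn,
                    counts$tp + counts$fp + counts$tn + counts$fn)
  )
  undef <- names(out)[vapply(out, is.na, TRUE)]
  structure(out, undefined = undef, class = "metrics_fragment")
}

#' @export
print.metrics_fragment <- function(x, ...) {
  for (k in names(x)) {
    if (is.na(x[[k]])) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", k))
    } else {
      cat(sprintf("  %-12s %6.2f%%\n", k, 100 * x[[k]]))
    }
  }
  invisible(x)
}

#' Area under the ROC curve
#'
#' The AUC equals the Mann-Whitney probability that a random positive
#' scores above a random negative (ties counted half).
#'
#' @param probs Numeric scores.
#' @param labels Ground truth (both classes must be present).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(probs, labels) {
  labels <- .as_binary_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes are required to compute an ROC curve")
  }
  r <- pROC::roc(response = labels, predictor = probs,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  as.numeric(pROC::auc(r))
}

#' ROC curve points
#'
#' @inheritParams roc_auc
#' @return Data frame with columns `threshold`, `sensitivity`,
#'   `specificity` suitable for plotting or CSV export.
#' @export
roc_curve <- function(probs, labels) {
  labels <- .as_binary_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes are required")
  r <- pROC::roc(response = labels, predictor = probs,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  data.frame(threshold = r$thresholds, sensitivity = r$sensitivities,
             specificity = r$specificities)
}

#' Precision-recall curve and average precision
#'
#' Average precision is the step-wise (non-interpolated) sum
#' `AP = sum_k (R_k - R_(k-1)) * P_k` over descending distinct score
#' thresholds.
#'
#' @inheritParams roc_auc
#' @return List with `curve` (data frame `threshold, recall, precision`)
#'   and `average_precision`.
#' @export
pr_curve <- function(probs, labels) {
  labels <- .as_binary_labels(labels)
  if (length(unique(labels)) < 2L) {
    stop("both classes are required to compute a precision-recall curve")
  }
  ord <- order(probs, decreasing = TRUE)
  p <- probs[ord]; y <- labels[ord]
  n_pos <- sum(y)
  tp <- cumsum(y)
  fp <- cumsum(!y)
  # evaluate at the last index of every distinct score (all ties included)
  last <- which(p != c(p[-1], NA) | seq_along(p) == length(p))
  recall <- tp[last] / n_pos
  precision <- tp[last] / (tp[last] + fp[last])
  ap <- sum(diff(c(0, recall)) * precision)
  list(curve = data.frame(threshold = p[last], recall = recall,
                          precision = precision),
       average_precision = ap)
}

#' Select the operating threshold on the validation split
#'
#' Maximises the average of sensitivity and specificity over all distinct
#' probability cut points (prediction positive iff probability >=
#' threshold). Ties are broken toward the cut with higher specificity,
#' then toward the larger threshold. When a gap separates the winning cut
#' from the next lower score the midpoint of the gap is returned — any
#' threshold in the gap yields the same predictions.
#'
#' @param probs_val,labels_val Validation probabilities and labels (both
#'   classes required).
#' @return The selected threshold.
#' @export
select_threshold <- function(probs_val, labels_val) {
  labels_val <- .as_binary_labels(labels_val)
  if (length(unique(labels_val)) < 2L) {
    stop("validation set must contain both classes")
  }
  cand <- sort(unique(probs_val), decreasing = TRUE)
  if (length(cand) == 1L) {
    warning("all validation probabilities are identical (", cand,
            "); threshold is degenerate")
    return(cand)
  }
  best <- NULL
  for (t in cand) {
    cc <- confusion_at_threshold(probs_val, labels_val, t)
    m <- metrics_from_confusion(cc)
    score <- (m$sensitivity + m$specificity) / 2
    better <- is.null(best) || score > best$score + 1e-12 ||
      (abs(score - best$score) <= 1e-12 &&
         (m$specificity > best$spec + 1e-12 ||
            (abs(m$specificity - best$spec) <= 1e-12 && t > best$t)))
    if (better) best <- list(t = t, score = score, spec = m$specificity)
  }
  below <- probs_val[probs_val < best$t]
  if (length(below)) (best$t + max(below)) / 2 else best$t
}

#' Exact (Clopper-Pearson) confidence interval for a proportion
#'
#' @param k Number of successes.
#' @param n Number of trials.
#' @param conf Confidence level.
#' @return Length-2 vector `(lower, upper)`.
#' @export
proportion_ci <- function(k, n, conf = 0.95) {
  if (n <= 0) stop("n must be positive")
  if (k < 0 || k > n) stop("k must lie in [0, n]")
  as.numeric(stats::binom.test(k, n, conf.level = conf)$conf.int)
}

#' DeLong confidence interval for the ROC AUC
#'
#' @inheritParams roc_auc
#' @param conf Confidence level.
#' @return Length-2 vector `(lower, upper)`.
#' @export
auc_ci <- function(probs, labels, conf = 0.95) {
  labels <- .as_binary_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes are required")
  r <- pROC::roc(response = labels, predictor = probs,
                 levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)
  ci <- pROC::ci.auc(r, conf.level = conf, method = "delong")
  c(as.numeric(ci[1]), as.numeric(ci[3]))
}

#' Full performance report at an operating threshold
#'
#' Confusion counts, the four proportion metrics with exact 95% intervals,
#' ROC AUC with its DeLong interval, and the precision-recall average
#' precision.
#'
#' @inheritParams roc_auc
#' @param threshold Operating threshold (typically from
#'   [select_threshold()] on the validation split).
#' @return An object of class `metrics_report`.
#' @export
evaluate_model <- function(probs, labels, threshold) {
  labels <- .as_binary_labels(labels)
  cc <- confusion_at_threshold(probs, labels, threshold)
  m <- metrics_from_confusion(cc)
  pr <- pr_curve(probs, labels)
  ci <- list(
    sensitivity = proportion_ci(cc$tp, cc$tp + cc$fn),
    specificity = proportion_ci(cc$tn, cc$tn + cc$fp),
    ppv = if (cc$tp + cc$fp > 0) proportion_ci(cc$tp, cc$tp + cc$fp) else c(NA, NA),
    accuracy = proportion_ci(cc$tp + cc$tn, length(labels)),
    auc = auc_ci(probs, labels)
  )
  structure(
    list(confusion = cc, metrics = m, auc = roc_auc(probs, labels),
         average_precision = pr$average_precision, pr_curve = pr$curve,
         roc_curve = roc_curve(probs, labels), threshold = threshold,
         confidence_intervals = ci),
    class = "metrics_report"
  )
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> threshold %.4f\n", x$threshold))
  print(x$confusion)
  ml <- x$metrics
  for (k in names(ml)) {
    ci <- x$confidence_intervals[[k]]
    cat(sprintf("  %-12s %6.2f%%  (95%% CI %.2f-%.2f%%)\n", k,
                100 * ml[[k]], 100 * ci[1], 100 * ci[2]))
  }
  cat(sprintf("  %-12s %6.4f  (95%% CI %.4f-%.4f)\n", "auc", x$auc,
              x$confidence_intervals$auc[1], x$confidence_intervals$auc[2]))
  cat(sprintf("  %-12s %6.4f\n", "avg precision", x$average_precision))
  invisible(x)
}

#' Write a metrics report and its curves to CSV
#'
#' @param report A [evaluate_model()] result.
#' @param dir Output directory.
#' @return Invisible vector of written paths.
#' @export
write_metrics_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  summary_path <- file.path(dir, "metrics.csv")
  m <- report$metrics
  ci <- report$confidence_intervals
  df <- data.frame(
    metric = c(names(m), "auc", "average_precision"),
    value = c(unlist(m, use.names = FALSE), report$auc,
              report$average_precision),
    ci_lower = c(vapply(names(m), function(k) ci[[k]][1], 0), ci$auc[1], NA),
    ci_upper = c(vapply(names(m), function(k) ci[[k]][2], 0), ci$auc[2], NA)
  )
  utils::write.csv(df, summary_path, row.names = FALSE)
  roc_path <- file.path(dir, "roc_curve.csv")
  utils::write.csv(report$roc_curve, roc_path, row.names = FALSE)
  pr_path <- file.path(dir, "pr_curve.csv")
  utils::write.csv(report$pr_curve, pr_path, row.names = FALSE)
  invisible(c(summary_path, roc_path, pr_path))
}
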