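#' Area under the ROC curve (rank statistic, tie-aware)
#'
#' AUROC via the Mann-Whitney identity: the mid-rank sum of positive-class
#' scores, which equals the probability that a random positive outranks a
#' random negative with ties counted half.
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 vector.
#' @return AUROC in `[0, 1]`; `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (step interpolation)
#'
#' Sweeps thresholds over distinct score values (highest first, tied scores
#' grouped) and accumulates `sum((R_i - R_{i-1}) * P_i)` — the average
#' precision estimator.
#'
#' @inheritParams auroc
#' @return AUPRC in `[0, 1]`; `NA` without positives.
#' @export
auprc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  n_pos <- sum(labels == 1)
  if (n_pos == 0) return(NA_real_)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- c(which(diff(s) != 0), length(s))  # last index of each tied block
  tp <- cumsum(y)[grp_end]
  fp <- (grp_end) - tp
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  sum(diff(c(0, rec)) * prec)
}

#' Threshold-free and thresholded classification metric panel
#'
#' The cross-validation metric columns: AUROC, AUPRC, accuracy, F score,
#' precision, recall (sensitivity), and specificity, the last five at a
#' fixed decision threshold.
#'
#' @param scores numeric scores in `[0, 1]`.
#' @param labels 0/1 vector (1 = disability class).
#' @param threshold decision threshold for the confusion metrics.
#' @return named numeric vector with entries `auroc`, `auprc`, `accuracy`,
#'   `f_score`, `precision`, `recall`, `specificity`. Undefined ratios
#'   (e.g. precision with no positive prediction) are `NA`.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  stopifnot(length(scores) == length(labels), all(labels %in% c(0, 1)))
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  prec <- if (tp + fp > 0) tp / (tp + fp) else NA_real_
  rec <- if (tp + fn > 0) tp / (tp + fn) else NA_real_
  spec <- if (tn + fp > 0) tn / (tn + fp) else NA_real_
  f1 <- if (is.finite(prec) && is.finite(rec) && prec + rec > 0)
    2 * prec * rec / (prec + rec) else NA_real_
  c(auroc = auroc(scores, labels), auprc = auprc(scores, labels),
    accuracy = (tp + tn) / length(labels),
    f_score = f1, precision = prec, recall = rec, specificity = spec)
}

#' ROC and PR curve points for plotting
#'
#' @inheritParams auroc
#' @return list of two data.frames: `roc` (`fpr`, `tpr`, `threshold`) and
#'   `pr` (`recall`, `precision`, `threshold`).
#' @export
curve_points <- function(scores, labels) {
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; y <- labels[ord]
  grp_end <- c(which(diff(s) != 0), length(s))
  tp <- cumsum(y)[grp_end]; fp <- grp_end - tp
  n1 <- sum(y); n0 <- length(y) - n1
  roc <- data.frame(fpr = c(0, fp / max(n0, 1)), tpr = c(0, tp / max(n1, 1)),
                    threshold = c(Inf, s[grp_end]))
  pr <- data.frame(recall = tp / max(n1, 1), precision = tp / (tp + fp),
                   threshold = s[grp_end])
  list(roc = roc, pr = pr)
}
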