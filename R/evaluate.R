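#' Area under the ROC curve (Mann-Whitney estimator)
#'
#' AUC = probability that a randomly chosen case outscores a randomly chosen
#' control, with half credit for ties:
#' \deqn{AUC = \frac{\#\{score_{case} > score_{ctrl}\} +
#'   \tfrac12 \#\{ties\}}{n_1 n_0}}
#' computed exactly via mid-ranks. Invariant under any strictly increasing
#' transform of the scores.
#'
#' @param scores numeric decision values.
#' @param labels 0/1 status (both classes required).
#' @return AUC in [0, 1].
#' @export
compute_auc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")
  r <- rank(scores, ties.method = "average")
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve coordinates
#'
#' True- and false-positive rates at every distinct score threshold
#' (predict case when score > threshold), plus the Mann-Whitney AUC.
#'
#' @param scores numeric decision values.
#' @param labels 0/1 status.
#' @return List of class \code{roc_curve}: thresholds (decreasing), tpr,
#'   fpr (both nondecreasing), auc.
#' @export
roc_curve <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("need at least one case and one control")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores > t & labels == 1) / n1, 0)
  fpr <- vapply(thr, function(t) sum(scores > t & labels == 0) / n0, 0)
  structure(list(thresholds = thr, tpr = tpr, fpr = fpr,
                 auc = compute_auc(scores, labels)), class = "roc_curve")
}

#' Classification metrics at a fixed decision cut
#'
#' Confusion-matrix summaries at \code{score > cut}: accuracy,
#' true-positive rate, false-positive rate, positive predictive value,
#' negative predictive value. A ratio with a zero denominator (e.g. PPV
#' with no predicted positives) is returned as NA with the
#' \code{"degenerate"} attribute naming it.
#'
#' @param scores numeric decision values.
#' @param labels 0/1 status (both classes required).
#' @param cut decision threshold (default 0, the SVM convention).
#' @return Named list: accuracy, tpr, fpr, ppv, npv.
#' @export
compute_metrics <- function(scores, labels, cut = 0) {
  labels <- as.integer(labels)
  if (!any(labels == 1) || !any(labels == 0))
    stop("need at least one case and one control")
  pred <- as.integer(scores > cut)
  tp <- sum(pred == 1 & labels == 1); fp <- sum(pred == 1 & labels == 0)
  fn <- sum(pred == 0 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  div <- function(a, b) if (b == 0) NA_real_ else a / b
  out <- list(accuracy = (tp + tn) / length(labels),
              tpr = div(tp, tp + fn), fpr = div(fp, fp + tn),
              ppv = div(tp, tp + fp), npv = div(tn, tn + fn))
  deg <- names(out)[vapply(out, is.na, TRUE)]
  if (length(deg)) attr(out, "degenerate") <- deg
  out
}

#' Paired replicate-level comparison of two models' AUCs
#'
#' Given per-replicate AUCs of the with-rare and without-rare models on the
#' same validation replicates, computes the paired differences d_i, their
#' mean, a t-based 95\% confidence interval
#' (mean +/- t_{0.975, n-1} sd/sqrt(n)), and the two-sided paired t-test.
#' Zero variance of the differences (e.g. identical AUC vectors) is flagged
#' \code{degenerate}: the mean difference is still reported, t and p are NA.
#'
#' @param auc_with per-replicate AUC, model with rare variants.
#' @param auc_without per-replicate AUC, model without rare variants.
#' @param conf_level confidence level (default 0.95).
#' @return Object of class \code{replicate_comparison}: auc_with,
#'   auc_without, mean_with, mean_without, mean_diff, ci (lo, hi), t_stat,
#'   p_paired_t, n_replicates, degenerate.
#' @export
compare_paired_auc <- function(auc_with, auc_without, conf_level = 0.95) {
  stopifnot(length(auc_with) == length(auc_without), length(auc_with) >= 2)
  d <- auc_with - auc_without
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  if (s == 0) {
    return(structure(list(auc_with = auc_with, auc_without = auc_without,
                          mean_with = mean(auc_with),
                          mean_without = mean(auc_without),
                          mean_diff = m, ci = c(m, m), t_stat = NA_real_,
                          p_paired_t = NA_real_, n_replicates = n,
                          degenerate = TRUE),
                     class = "replicate_comparison"))
  }
  se <- s / sqrt(n)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  t_stat <- m / se
  structure(list(auc_with = auc_with, auc_without = auc_without,
                 mean_with = mean(auc_with), mean_without = mean(auc_without),
                 mean_diff = m, ci = c(m - tq * se, m + tq * se),
                 t_stat = t_stat,
                 p_paired_t = 2 * stats::pt(-abs(t_stat), df = n - 1),
                 n_replicates = n, degenerate = FALSE),
            class = "replicate_comparison")
}

#' @export
print.replicate_comparison <- function(x, ...) {
  cat(sprintf("paired AUC comparison over %d replicates\n", x$n_replicates))
  cat(sprintf("  mean AUC without rare: %.4f; with rare: %.4f\n",
              x$mean_without, x$mean_with))
  if (x$degenerate)
    cat(sprintf("  difference %.4f (zero variance; t undefined)\n",
                x$mean_diff))
  else
    cat(sprintf("  difference %.4f (95%% CI %.4f, %.4f), paired t p = %.3g\n",
                x$mean_diff, x$ci[1], x$ci[2], x$p_paired_t))
  invisible(x)
}
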