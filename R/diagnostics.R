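# ROC construction and AUC inference.
#
# Convention throughout: higher score = more disease-like, and a subject
# tests positive iff score >= cutoff (inclusive, matching the segmentation
# thresholds' ">=" style).

check_labels <- function(labels) {
  if (is.logical(labels)) labels <- as.integer(labels)
  if (is.factor(labels)) labels <- as.integer(labels) - 1L
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L)))
    stop("labels must be binary (0/1, logical, or two-level factor)",
         call. = FALSE)
  if (length(unique(labels)) < 2L)
    stop("both classes must be present", call. = FALSE)
  labels
}

#' Empirical ROC curve
#'
#' Operating points are computed at every distinct score value (test
#' positive iff score >= cutoff) plus the two trivial endpoints: cutoff
#' `Inf` (sensitivity 0, specificity 1) and cutoff `-Inf` (sensitivity 1,
#' specificity 0). Cutoffs are returned in descending order, so sensitivity
#' is non-decreasing along the curve.
#'
#' @param scores Numeric vector of finite scores.
#' @param labels Binary labels (1 = diseased), same length as `scores`.
#' @return Object of class `roc_curve`: `cutoffs`, `sens`, `spec`,
#'   `n_pos`, `n_neg`.
#' @export
roc_curve <- function(scores, labels) {
  scores <- as.numeric(scores)
  if (!all(is.finite(scores))) stop("scores must be finite", call. = FALSE)
  labels <- check_labels(labels)
  stopifnot(length(scores) == length(labels))
  pos <- scores[labels == 1L]
  neg <- scores[labels == 0L]
  cutoffs <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  sens <- vapply(cutoffs, function(t) mean(pos >= t), numeric(1))
  spec <- vapply(cutoffs, function(t) mean(neg < t), numeric(1))
  structure(list(cutoffs = cutoffs, sens = sens, spec = spec,
                 n_pos = length(pos), n_neg = length(neg)),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("<roc_curve> %d operating points, n_pos=%d, n_neg=%d, AUC=%.4f\n",
              length(x$cutoffs), x$n_pos, x$n_neg, roc_auc(x)))
  invisible(x)
}

#' Area under the ROC curve
#'
#' Trapezoidal area under the empirical curve. By construction this equals
#' the tie-corrected two-sample rank statistic
#' `sum(1(x > y) + 0.5 * 1(x == y)) / (n_pos * n_neg)` to machine precision,
#' a property the test-suite asserts to 1e-12.
#'
#' @param x A `roc_curve`, or a numeric score vector (then `labels` is
#'   required).
#' @param labels Binary labels when `x` is a score vector.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(x, labels = NULL) {
  if (!inherits(x, "roc_curve")) x <- roc_curve(x, labels)
  fpr <- 1 - x$spec
  tpr <- x$sens
  sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
}

#' Youden-optimal cutoff
#'
#' Maximizes Youden's J = sensitivity + specificity - 1 over the curve's
#' finite cutoffs (the observed score values). Ties are broken toward
#' higher sensitivity, then toward the higher cutoff.
#'
#' @param curve A `roc_curve`.
#' @return List with `cutoff_star`, `sens_star`, `spec_star`, `youden_j`.
#' @export
youden_cutoff <- function(curve) {
  stopifnot(inherits(curve, "roc_curve"))
  fin <- is.finite(curve$cutoffs)
  if (!any(fin)) stop("degenerate ROC curve: no finite cutoffs", call. = FALSE)
  cut <- curve$cutoffs[fin]
  sens <- curve$sens[fin]
  spec <- curve$spec[fin]
  j <- sens + spec - 1
  best <- order(-j, -sens, -cut)[1L]
  list(cutoff_star = cut[best], sens_star = sens[best],
       spec_star = spec[best], youden_j = j[best])
}

# DeLong structural components: V10[i] = placement of positive i among the
# negatives, V01[j] = placement of negative j among the positives; their
# means both equal the AUC.
delong_components <- function(scores, labels) {
  labels <- check_labels(labels)
  x <- scores[labels == 1L]
  y <- scores[labels == 0L]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong confidence interval for the AUC
#'
#' Normal-approximation interval using the DeLong structural-components
#' variance, truncated to \[0, 1\]. A degenerate AUC of exactly 0 or 1 has
#' zero estimated variance; a point interval is returned with a warning.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels; each class needs at least 2 members.
#' @param level Confidence level (default 0.95).
#' @return List with `auc`, `lo`, `hi`, `se`, `level`.
#' @export
auc_ci <- function(scores, labels, level = 0.95) {
  labels <- check_labels(labels)
  if (sum(labels == 1L) < 2L || sum(labels == 0L) < 2L)
    stop("each class needs at least 2 members for a CI", call. = FALSE)
  dc <- delong_components(scores, labels)
  v <- stats::var(dc$v10) / length(dc$v10) + stats::var(dc$v01) / length(dc$v01)
  se <- sqrt(v)
  if (dc$auc %in% c(0, 1) || se == 0) {
    if (dc$auc %in% c(0, 1))
      warning("degenerate AUC of ", dc$auc, "; returning a point interval",
              call. = FALSE)
    return(list(auc = dc$auc, lo = dc$auc, hi = dc$auc, se = se, level = level))
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(auc = dc$auc, lo = max(0, dc$auc - z * se),
       hi = min(1, dc$auc + z * se), se = se, level = level)
}

#' Paired DeLong comparison of two AUCs
#'
#' Compares the AUCs of two markers measured on the same subjects using the
#' DeLong structural-components covariance; the p-value comes from the
#' standard normal. Comparing a marker with itself (or any strictly
#' increasing transform of itself) gives a difference of exactly 0 and
#' p = 1.
#'
#' @param scores_a,scores_b Paired numeric scores on identical subjects.
#' @param labels Binary labels shared by both markers.
#' @return List with `auc_a`, `auc_b`, `delta_auc`, `z`, `p`.
#' @export
delong_compare <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b))
    stop("scores are not paired: lengths differ", call. = FALSE)
  labels <- check_labels(labels)
  stopifnot(length(scores_a) == length(labels))
  da <- delong_components(scores_a, labels)
  db <- delong_components(scores_b, labels)
  d10 <- da$v10 - db$v10
  d01 <- da$v01 - db$v01
  v <- stats::var(d10) / length(d10) + stats::var(d01) / length(d01)
  delta <- da$auc - db$auc
  z <- if (v > 0) delta / sqrt(v) else if (delta == 0) 0 else sign(delta) * Inf
  list(auc_a = da$auc, auc_b = db$auc, delta_auc = delta, z = z,
       p = 2 * stats::pnorm(-abs(z)))
}

#' Prevalence-adjusted predictive values and accuracy
#'
#' Bayes-rule predictive values at an assumed disease prevalence, as used
#' when the study sample's class mix does not reflect the clinical
#' population (here the working assumption is a device-specific infection
#' prevalence of 60%):
#' \deqn{PPV = \frac{se \pi}{se \pi + (1-sp)(1-\pi)}, \quad
#'       NPV = \frac{sp (1-\pi)}{sp (1-\pi) + (1-se) \pi},}
#' and prevalence-weighted accuracy \eqn{se \pi + sp (1-\pi)}.
#' A zero denominator yields `NA` for that predictive value, never an error.
#'
#' @param sens,spec Sensitivity and specificity in \[0, 1\].
#' @param prevalence Assumed prevalence in (0, 1); default 0.6.
#' @return List with `prevalence`, `ppv`, `npv`, `accuracy`.
#' @export
prevalence_metrics <- function(sens, spec, prevalence = 0.6) {
  stopifnot(sens >= 0, sens <= 1, spec >= 0, spec <= 1,
            prevalence > 0, prevalence < 1)
  pi <- prevalence
  den_p <- sens * pi + (1 - spec) * (1 - pi)
  den_n <- spec * (1 - pi) + (1 - sens) * pi
  list(prevalence = pi,
       ppv = if (den_p > 0) sens * pi / den_p else NA_real_,
       npv = if (den_n > 0) spec * (1 - pi) / den_n else NA_real_,
       accuracy = sens * pi + spec * (1 - pi))
}

#' Empirical confusion metrics at a cutoff
#'
#' Raw-count sensitivity, specificity, predictive values and accuracy with
#' test-positive defined as score >= cutoff. Predictive values here reflect
#' the sample's own class mix; see [prevalence_metrics()] for the
#' prevalence-adjusted versions.
#'
#' @param scores Numeric scores.
#' @param labels Binary labels.
#' @param cutoff Decision threshold.
#' @return List with `sens`, `spec`, `ppv`, `npv`, `accuracy` (NA where a
#'   denominator is zero).
#' @export
empirical_confusion <- function(scores, labels, cutoff) {
  labels <- check_labels(labels)
  pred <- as.integer(scores >= cutoff)
  tp <- sum(pred == 1L & labels == 1L)
  fp <- sum(pred == 1L & labels == 0L)
  tn <- sum(pred == 0L & labels == 0L)
  fn <- sum(pred == 0L & labels == 1L)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  list(sens = rate(tp, tp + fn), spec = rate(tn, tn + fp),
       ppv = rate(tp, tp + fp), npv = rate(tn, tn + fn),
       accuracy = (tp + tn) / length(labels))
}

#' Full diagnostic evaluation of cohort metrics
#'
#' For each metric column: empirical ROC, DeLong AUC confidence interval,
#' Youden-optimal cutoff with its sensitivity/specificity, and
#' prevalence-adjusted PPV/NPV/accuracy at that cutoff.
#'
#' @param cohort Data frame with one row per observation.
#' @param metrics Character vector of metric column names.
#' @param label_col Name of the binary label column (1 = infected).
#' @param prevalence Assumed prevalence for predictive values (default 0.6).
#' @param level Confidence level for the AUC interval (default 0.95).
#' @return Data frame with one row per metric: `metric`, `auc`, `ci_lo`,
#'   `ci_hi`, `cutoff`, `sens`, `spec`, `ppv`, `npv`, `accuracy`,
#'   `youden_j`.
#' @export
evaluate_metrics <- function(cohort, metrics, label_col = "label",
                             prevalence = 0.6, level = 0.95) {
  stopifnot(is.data.frame(cohort), label_col %in% names(cohort),
            all(metrics %in% names(cohort)))
  labels <- check_labels(cohort[[label_col]])
  rows <- lapply(metrics, function(m) {
    sc <- cohort[[m]]
    curve <- roc_curve(sc, labels)
    ci <- auc_ci(sc, labels, level = level)
    yc <- youden_cutoff(curve)
    pm <- prevalence_metrics(yc$sens_star, yc$spec_star, prevalence)
    data.frame(metric = m, auc = ci$auc, ci_lo = ci$lo, ci_hi = ci$hi,
               cutoff = yc$cutoff_star, sens = yc$sens_star,
               spec = yc$spec_star, ppv = pm$ppv, npv = pm$npv,
               accuracy = pm$accuracy, youden_j = yc$youden_j)
  })
  do.call(rbind, rows)
}

#' Pairwise DeLong comparison matrix
#'
#' Two-sided DeLong p-values for every pair of metric columns, measured on
#' the same subjects.
#'
#' @inheritParams evaluate_metrics
#' @return Square numeric matrix of p-values (diagonal 1).
#' @export
delong_matrix <- function(cohort, metrics, label_col = "label") {
  labels <- check_labels(cohort[[label_col]])
  k <- length(metrics)
  p <- matrix(1, k, k, dimnames = list(metrics, metrics))
  if (k >= 2) {
    for (i in 1:(k - 1)) for (j in (i + 1):k) {
      cmp <- delong_compare(cohort[[metrics[i]]], cohort[[metrics[j]]], labels)
      p[i, j] <- p[j, i] <- cmp$p
    }
  }
  p
}
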