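# Two-group comparison and descriptive summaries for lesion-metric cohorts.

#' Descriptive summary of a metric
#'
#' Sample mean, sample standard deviation (n - 1 denominator; `NA` for a
#' single observation), median and quartiles. Quartiles use linear
#' interpolation of order statistics (R's type-7 convention), pinned so
#' reported IQRs are reproducible.
#'
#' @param x Numeric vector with at least one finite value.
#' @return List with `n`, `mean`, `sd`, `median`, `q1`, `q3`.
#' @export
summarize_values <- function(x) {
  x <- as.numeric(x)
  x <- x[is.finite(x)]
  if (length(x) == 0L) stop("no finite values to summarize", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  list(n = length(x), mean = mean(x),
       sd = if (length(x) >= 2L) stats::sd(x) else NA_real_,
       median = q[2L], q1 = q[1L], q3 = q[3L])
}

# Two-sided exact Mann-Whitney p by full enumeration of the permutation
# distribution of U over all assignments of the pooled values to group A.
# Symmetric two-sided rule: p = P(|U - mn/2| >= |u_obs - mn/2|). Handles
# ties naturally because the enumeration is over the pooled values.
mw_exact <- function(a, b) {
  m <- length(a); n <- length(b)
  pooled <- c(a, b)
  u_of <- function(idx) {
    x <- pooled[idx]; y <- pooled[-idx]
    sum(outer(x, y, function(p, q) (p > q) + 0.5 * (p == q)))
  }
  u_obs <- u_of(seq_len(m))
  combos <- utils::combn(m + n, m)
  u_all <- apply(combos, 2, u_of)
  center <- m * n / 2
  mean(abs(u_all - center) >= abs(u_obs - center) - 1e-9)
}

# Normal approximation with tie correction and continuity correction.
mw_normal <- function(a, b) {
  m <- length(a); n <- length(b)
  N <- m + n
  r <- rank(c(a, b))
  u <- sum(r[seq_len(m)]) - m * (m + 1) / 2
  mu <- m * n / 2
  ties <- table(c(a, b))
  sigma2 <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sigma2 <= 0) return(list(u = u, p = 1))  # all values tied
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sigma2)
  list(u = u, p = 2 * stats::pnorm(-abs(z)))
}

#' Compare a lesion metric between two groups
#'
#' Welch's unequal-variance t-test, or the Mann-Whitney U-test: exact by
#' full permutation enumeration when the combined sample size is at most
#' `exact_limit` (default 12), otherwise a normal approximation with tie
#' and continuity corrections. `method = "auto"` picks Mann-Whitney when
#' either group fails a Shapiro-Wilk normality check at the 0.05 level,
#' Welch's t otherwise; the choice is recorded in the result.
#'
#' @param a,b Numeric vectors, each with at least 2 observations.
#' @param method `"auto"`, `"welch_t"` or `"mann_whitney"`.
#' @param exact_limit Combined-n bound for the exact Mann-Whitney path.
#' @return Object of class `group_comparison`: `method`, `statistic`
#'   (t or U), `p`, `summary_a`, `summary_b`, and for `auto` the per-group
#'   Shapiro-Wilk p-values in `normality_p`.
#' @export
compare_groups <- function(a, b, method = c("auto", "welch_t", "mann_whitney"),
                           exact_limit = 12L) {
  method <- match.arg(method)
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L) stop("group A needs at least 2 observations", call. = FALSE)
  if (length(b) < 2L) stop("group B needs at least 2 observations", call. = FALSE)
  normality_p <- NULL
  if (method == "auto") {
    # shapiro.test needs n in [3, 5000] and non-constant data
    sw <- function(x) {
      if (length(x) < 3L || stats::sd(x) == 0) return(0)  # treat as non-normal
      stats::shapiro.test(if (length(x) > 5000L) x[seq_len(5000L)] else x)$p.value
    }
    normality_p <- c(a = sw(a), b = sw(b))
    method <- if (any(normality_p < 0.05)) "mann_whitney" else "welch_t"
  }
  if (method == "welch_t") {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    statistic <- unname(tt$statistic)
    p <- tt$p.value
    if (is.nan(statistic)) { statistic <- 0; p <- 1 }  # zero-variance groups
  } else {
    if (length(a) + length(b) <= exact_limit) {
      p <- mw_exact(a, b)
      statistic <- sum(outer(a, b, function(x, y) (x > y) + 0.5 * (x == y)))
    } else {
      mw <- mw_normal(a, b)
      statistic <- mw$u
      p <- mw$p
    }
  }
  structure(list(method = method, statistic = statistic, p = min(p, 1),
                 summary_a = summarize_values(a), summary_b = summarize_values(b),
                 normality_p = normality_p),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic %.4g, p = %.4g\n",
              x$method, x$statistic, x$p))
  cat(sprintf("  A: n=%d median %.3g (%.3g - %.3g), mean %.3g\n",
              x$summary_a$n, x$summary_a$median, x$summary_a$q1,
              x$summary_a$q3, x$summary_a$mean))
  cat(sprintf("  B: n=%d median %.3g (%.3g - %.3g), mean %.3g\n",
              x$summary_b$n, x$summary_b$median, x$summary_b$q1,
              x$summary_b$q3, x$summary_b$mean))
  invisible(x)
}

#' Group-comparison table over cohort metrics
#'
#' One row per metric: descriptive summaries per group (infected = label 1)
#' and the two-group test, in the layout of a clinical comparison table
#' (median and IQR alongside mean and SD, the test used, and its p-value).
#'
#' @param cohort Data frame of per-observation metrics plus a label column.
#' @param metrics Character vector of metric columns to compare.
#' @param label_col Binary label column name (1 = infected).
#' @param method Passed to [compare_groups()].
#' @return Data frame with per-group summary columns, `method` and `p`.
#' @export
compare_cohort <- function(cohort, metrics, label_col = "label",
                           method = "auto") {
  labels <- check_labels(cohort[[label_col]])
  rows <- lapply(metrics, function(m) {
    inf <- cohort[[m]][labels == 1L]
    non <- cohort[[m]][labels == 0L]
    gc <- compare_groups(inf, non, method = method)
    si <- gc$summary_a; sn <- gc$summary_b
    data.frame(metric = m,
               infected_median = si$median, infected_q1 = si$q1,
               infected_q3 = si$q3, infected_mean = si$mean, infected_sd = si$sd,
               noninfected_median = sn$median, noninfected_q1 = sn$q1,
               noninfected_q3 = sn$q3, noninfected_mean = sn$mean,
               noninfected_sd = sn$sd,
               method = gc$method, statistic = gc$statistic, p = gc$p)
  })
  do.call(rbind, rows)
}
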