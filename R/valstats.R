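# Method-comparison statistics for validating simulated vFFR against an
# invasive reference: exact-binomial diagnostic metrics, chi-square
# contingency tests, quantile-regression Bland-Altman agreement,
# Passing-Bablok regression, ROC/AUC, and the exact noncentral-t paired
# sample-size calculation.

#' Diagnostic contingency counts
#'
#' @param tp,tn,fp,fn non-negative integer counts.
#' @return An object of class `diagnostic_counts`.
#' @export
diagnostic_counts <- function(tp, tn, fp, fn) {
  v <- c(tp = tp, tn = tn, fp = fp, fn = fn)
  if (any(v < 0) || any(v != round(v))) {
    stop_domain("counts must be non-negative integers")
  }
  if (sum(v) == 0) stop_domain("at least one count must be positive")
  structure(as.list(v), class = "diagnostic_counts")
}

# exact (Clopper-Pearson) binomial interval via beta quantiles
clopper_pearson <- function(k, n, level = 0.95) {
  a <- (1 - level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = lower, upper = upper)
}

#' Diagnostic performance metrics with exact binomial intervals
#'
#' Accuracy, sensitivity, specificity, PPV and NPV as percentages, each
#' with a Clopper-Pearson exact confidence interval. A metric whose
#' denominator is zero is reported as `NA` (undefined), not 0.
#'
#' @param counts a [diagnostic_counts].
#' @param level confidence level (default 0.95).
#' @return A data.frame with columns `metric`, `estimate`, `lower`,
#'   `upper` (percent).
#' @examples
#' diagnostic_metrics(diagnostic_counts(tp = 30, tn = 37, fp = 18, fn = 16))
#' @export
diagnostic_metrics <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "diagnostic_counts"))
  with(counts, {
    one <- function(metric, k, n) {
      if (n == 0) {
        return(data.frame(metric = metric, estimate = NA_real_,
                          lower = NA_real_, upper = NA_real_))
      }
      ci <- 100 * clopper_pearson(k, n, level)
      data.frame(metric = metric, estimate = 100 * k / n,
                 lower = ci[["lower"]], upper = ci[["upper"]])
    }
    rbind(
      one("accuracy", tp + tn, tp + tn + fp + fn),
      one("sensitivity", tp, tp + fn),
      one("specificity", tn, tn + fp),
      one("ppv", tp, tp + fp),
      one("npv", tn, tn + fn)
    )
  })
}

#' Pearson chi-square test of independence
#'
#' The Pearson statistic `sum((O - E)^2 / E)` with expected counts from
#' the row/column margins and `(r - 1)(c - 1)` degrees of freedom, without
#' continuity correction.
#'
#' @param table a counts matrix (at least 2x2).
#' @return List with `statistic`, `dof`, `p_value`.
#' @examples
#' succ <- c(101, 102, 102, 99, 88)
#' chi_square_independence(cbind(succ, 104 - succ))
#' @export
chi_square_independence <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) stop_domain("counts must be non-negative")
  rs <- rowSums(table)
  cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) stop_domain("zero row or column margin")
  expected <- outer(rs, cs) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  dof <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, dof = dof,
       p_value = stats::pchisq(stat, dof, lower.tail = FALSE))
}

# quantile regression on a general design matrix by minimising the check
# loss sum(rho_tau(y - X b)) with asymmetric IRLS (Schlossmacher-style).
rq_irls <- function(X, y, tau, iters = 200) {
  b <- stats::lm.fit(X, y)$coefficients
  b[is.na(b)] <- 0
  eps <- 1e-6 * max(stats::sd(y), 1e-12)
  for (it in seq_len(iters)) {
    r <- y - drop(X %*% b)
    w <- ifelse(r >= 0, tau, 1 - tau) / pmax(abs(r), eps)
    b_new <- stats::lm.wfit(X, y, w)$coefficients
    b_new[is.na(b_new)] <- 0
    if (max(abs(b_new - b)) < 1e-12 * (1 + max(abs(b)))) {
      b <- b_new
      break
    }
    b <- b_new
  }
  unname(b)
}

# linear quantile regression: IRLS followed by a Nelder-Mead polish on the
# exact check loss. Coefficients (intercept, slope).
rq_line <- function(x, y, tau) {
  check_loss <- function(b) {
    r <- y - b[1] - b[2] * x
    sum(r * (tau - (r < 0)))
  }
  b <- rq_irls(cbind(1, x), y, tau)
  polish <- stats::optim(b, check_loss, method = "Nelder-Mead",
                         control = list(maxit = 2000, reltol = 1e-12))
  if (polish$value <= check_loss(b)) b <- polish$par
  c(intercept = b[1], slope = b[2])
}

#' Quantile-regression Bland-Altman agreement
#'
#' When differences between two methods are neither normal nor constant
#' across the measurement range, median bias and 95% limits of agreement
#' are estimated by linear quantile regression of the difference
#' (test - reference) on the pair mean, at the 50th, 2.5th and 97.5th
#' centiles, and reported at a reference mean (default 0.80, the
#' diagnostic threshold).
#'
#' @param reference,test paired measurements.
#' @param ref_mean pair-mean value at which the three lines are evaluated.
#' @return An object of class `agreement_result`: list with `bias_line`,
#'   `lo_line`, `hi_line` (intercept/slope pairs), `bias_at_ref`,
#'   `loa_at_ref` (length-2), `ref_mean`, `n`, `flags`.
#' @export
bland_altman_quantile <- function(reference, test, ref_mean = 0.80) {
  ok <- stats::complete.cases(reference, test)
  reference <- reference[ok]; test <- test[ok]
  n <- length(reference)
  if (n < 3) stop_domain("need at least 3 complete pairs")
  if (n < 20) warning("fewer than 20 pairs; agreement estimates are unstable")
  d <- test - reference
  m <- (test + reference) / 2
  flags <- character()
  taus <- c(lo = 0.025, bias = 0.5, hi = 0.975)
  if (stats::sd(m) < 1e-12 * (1 + mean(abs(m)))) {
    # degenerate mean spread: fall back to unconditional quantiles
    flags <- "degenerate x-spread: unconditional quantiles"
    lines <- lapply(taus, function(tt)
      c(intercept = unname(stats::quantile(d, tt)), slope = 0))
  } else if (all(abs(d - d[1]) < 1e-14 * (1 + abs(d[1])))) {
    lines <- lapply(taus, function(tt) c(intercept = d[1], slope = 0))
  } else {
    lines <- lapply(taus, function(tt) rq_line(m, d, tt))
  }
  at_ref <- vapply(lines, function(b) b[1] + b[2] * ref_mean, 0)
  structure(
    list(bias_line = lines$bias, lo_line = lines$lo, hi_line = lines$hi,
         bias_at_ref = unname(at_ref["bias"]),
         loa_at_ref = unname(at_ref[c("lo", "hi")]),
         ref_mean = ref_mean, n = n, flags = flags),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf(
    "<agreement_result> n=%d: median bias %.3f, 95%% LOA [%.3f, %.3f] at mean %.2f\n",
    x$n, x$bias_at_ref, x$loa_at_ref[1], x$loa_at_ref[2], x$ref_mean))
  invisible(x)
}

#' Passing-Bablok regression
#'
#' Non-parametric method-comparison regression: the slope is the shifted
#' median of all pairwise slopes (slopes of exactly -1 are excluded; the
#' median index is offset by the number of slopes below -1, which makes
#' the estimator invariant to swapping the methods), and the intercept is
#' the median of `y - slope * x`.
#'
#' @param x,y paired measurements (reference and test).
#' @return List with `slope` and `intercept`.
#' @export
passing_bablok <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 10) warning("fewer than 10 pairs; Passing-Bablok is unstable")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  keep <- dx != 0 | dy != 0
  dx <- dx[keep]; dy <- dy[keep]
  slopes <- ifelse(dx == 0, ifelse(dy > 0, Inf, -Inf), dy / dx)
  slopes <- slopes[slopes != -1]          # ties at -1 excluded by convention
  if (length(slopes) == 0) {
    stop(errorCondition("all pairwise slopes undefined",
                        class = c("degenerate_input", "vffr1d_error")))
  }
  slopes <- sort(slopes)
  n_s <- length(slopes)
  k <- sum(slopes < -1)
  if (n_s %% 2 == 1) {
    b <- slopes[(n_s + 1) / 2 + k]
  } else {
    b <- (slopes[n_s / 2 + k] + slopes[n_s / 2 + 1 + k]) / 2
  }
  list(slope = b, intercept = stats::median(y - b * x))
}

#' ROC curve and AUC for a "lower score is diseased" test
#'
#' Orientation follows vFFR semantics: lower simulated vFFR indicates
#' more severe disease, so "test positive" means score at or below the
#' threshold. The AUC is computed by the trapezoidal rule over all
#' thresholds, which with tie-averaging equals the Mann-Whitney rank
#' statistic `P(score_pos < score_neg) + P(tie)/2`.
#'
#' @param scores numeric test scores (e.g. vFFR).
#' @param labels logical or 0/1 disease labels (`TRUE` = diseased).
#' @return List with `auc` and `curve` (data.frame `threshold`, `fpr`,
#'   `tpr`).
#' @export
roc_auc <- function(scores, labels) {
  labels <- as.logical(labels)
  ok <- stats::complete.cases(scores, labels)
  scores <- scores[ok]; labels <- labels[ok]
  n_pos <- sum(labels); n_neg <- sum(!labels)
  if (n_pos == 0 || n_neg == 0) stop_domain("both classes must be present")
  th <- sort(unique(scores))
  tpr <- vapply(th, function(t) mean(scores[labels] <= t), 0)
  fpr <- vapply(th, function(t) mean(scores[!labels] <= t), 0)
  curve <- data.frame(threshold = c(th, Inf), fpr = c(fpr, 1), tpr = c(tpr, 1))
  curve <- rbind(data.frame(threshold = -Inf, fpr = 0, tpr = 0), curve)
  auc <- sum(diff(curve$fpr) * (curve$tpr[-1] + curve$tpr[-nrow(curve)]) / 2)
  list(auc = auc, curve = curve)
}

#' Minimum sample size for a two-tailed paired t-test
#'
#' Smallest `n` such that the exact noncentral-t power of the two-tailed
#' one-sample test on paired differences (degrees of freedom `n - 1`,
#' noncentrality `d * sqrt(n)`) reaches the requested power.
#'
#' @param effect_size Cohen's d_z for the paired differences.
#' @param alpha two-tailed type-I error rate.
#' @param power required power.
#' @return Minimum integer sample size.
#' @examples
#' paired_t_sample_size(0.29, alpha = 0.05, power = 0.80)
#' @export
paired_t_sample_size <- function(effect_size, alpha = 0.05, power = 0.80) {
  if (effect_size <= 0) stop_domain("effect size must be positive")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop_domain("alpha and power must lie in (0, 1)")
  }
  pow <- function(n) {
    crit <- stats::qt(1 - alpha / 2, df = n - 1)
    ncp <- effect_size * sqrt(n)
    stats::pt(-crit, df = n - 1, ncp = ncp) +
      stats::pt(crit, df = n - 1, ncp = ncp, lower.tail = FALSE)
  }
  n <- 2
  while (pow(n) < power && n < 1e7) n <- n + 1
  n
}
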