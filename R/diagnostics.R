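# orient scores so that larger oriented score = more abnormal
orient_scores <- function(scores, direction) {
  direction <- match.arg(direction, c("lower_is_abnormal",
                                      "higher_is_abnormal"))
  if (direction == "lower_is_abnormal") -scores else scores
}

check_two_classes <- function(labels) {
  labels <- as.logical(labels)
  if (any(is.na(labels)))
    abort("labels must be binary with no missing values",
          class = "ctperf_input_error")
  if (!any(labels) || all(labels))
    abort("both classes must be present", class = "ctperf_input_error")
  labels
}

# DeLong placement values: for each positive, the fraction of negatives it
# beats (ties count half), and symmetrically for negatives
delong_placements <- function(x, labels) {
  pos <- x[labels]
  neg <- x[!labels]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  v10 <- (r_all[seq_len(m)] - rank(pos, ties.method = "average")) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - rank(neg, ties.method = "average")) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' Empirical ROC analysis with DeLong variance
#'
#' Computes the empirical (trapezoidal / Mann-Whitney) AUC with midrank tie
#' handling, oriented so that lower parameter values indicate abnormality by
#' default, a DeLong-variance confidence interval on the AUC (normal
#' approximation), the full ROC curve over candidate thresholds (midpoints
#' between adjacent distinct values), and the Youden-index cutoff.
#'
#' @param data A data frame, or a numeric score vector.
#' @param scores,labels Columns of `data` (tidy-eval), or a numeric vector
#'   and a logical/binary vector when `data` is numeric. `TRUE`/1 marks
#'   reference-positive (abnormal) observations.
#' @param direction `"lower_is_abnormal"` (default) or
#'   `"higher_is_abnormal"`.
#' @param level Confidence level for the AUC interval.
#' @return A `ctp_roc` object; see [tidy.ctp_roc()] and [glance.ctp_roc()].
#' @examples
#' empirical_auc(c(0.5, 0.6, 0.9, 1.1), c(TRUE, TRUE, FALSE, FALSE))
#' @export
empirical_auc <- function(data, scores, labels,
                          direction = "lower_is_abnormal", level = 0.95) {
  if (is.data.frame(data)) {
    sc <- dplyr::pull(data, {{ scores }})
    lb <- dplyr::pull(data, {{ labels }})
  } else {
    sc <- data
    lb <- scores
  }
  lb <- check_two_classes(lb)
  x <- orient_scores(sc, direction)
  pl <- delong_placements(x, lb)
  s10 <- if (pl$m > 1) stats::var(pl$v10) else 0
  s01 <- if (pl$n > 1) stats::var(pl$v01) else 0
  v <- s10 / pl$m + s01 / pl$n
  z <- qnorm(1 - (1 - level) / 2)
  ci <- pmin(1, pmax(0, pl$auc + c(-1, 1) * z * sqrt(v)))
  curve <- roc_curve_table(sc, lb, direction)
  yd <- youden_from_curve(curve)
  structure(list(auc = pl$auc, auc_var = v, auc_ci = ci, level = level,
                 curve = curve, youden = yd, direction = direction,
                 n_pos = pl$m, n_neg = pl$n),
            class = "ctp_roc")
}

# candidate cutoffs: midpoints between adjacent distinct values plus the
# open ends; sens/spec follow the "abnormal iff value < cutoff" convention
roc_curve_table <- function(scores, labels, direction) {
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  if (direction == "higher_is_abnormal") {
    pos_call <- function(c) scores > c
  } else {
    pos_call <- function(c) scores < c
  }
  sens <- vapply(cand, function(c) mean(pos_call(c)[labels]), numeric(1))
  spec <- vapply(cand, function(c) mean(!pos_call(c)[!labels]), numeric(1))
  tibble(threshold = cand, sensitivity = sens, specificity = spec,
         j = sens + spec - 1)
}

youden_from_curve <- function(curve) {
  ord <- order(-curve$j, -curve$specificity, curve$threshold)
  best <- curve[ord[1], ]
  list(cutoff = best$threshold, j = best$j,
       sensitivity = best$sensitivity, specificity = best$specificity)
}

#' @export
print.ctp_roc <- function(x, ...) {
  cat(sprintf("<ctp_roc> AUC %.3f (%d%% CI %.3f-%.3f), %d pos / %d neg\n",
              x$auc, round(100 * x$level), x$auc_ci[1], x$auc_ci[2],
              x$n_pos, x$n_neg))
  cat(sprintf("  Youden cutoff %.4g (J = %.3f, sens %.2f, spec %.2f)\n",
              x$youden$cutoff, x$youden$j, x$youden$sensitivity,
              x$youden$specificity))
  invisible(x)
}

#' Tidy and summarise ROC results
#'
#' `tidy()` returns the ROC curve (one row per candidate threshold);
#' `glance()` a one-row summary with the AUC, its confidence interval and
#' the Youden cutoff.
#'
#' @param x A `ctp_roc`.
#' @param ... Ignored.
#' @export
tidy.ctp_roc <- function(x, ...) x$curve

#' @rdname tidy.ctp_roc
#' @export
glance.ctp_roc <- function(x, ...) {
  tibble(auc = x$auc, auc_low = x$auc_ci[1], auc_high = x$auc_ci[2],
         youden_cutoff = x$youden$cutoff, youden_j = x$youden$j,
         sensitivity = x$youden$sensitivity,
         specificity = x$youden$specificity,
         n_pos = x$n_pos, n_neg = x$n_neg)
}

#' @rdname tidy.ctp_roc
#' @param object A `ctp_roc` for `autoplot`.
#' @export
autoplot.ctp_roc <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(1 - .data$specificity, .data$sensitivity)) +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  subtitle = sprintf("AUC %.3f", object$auc)) +
    ggplot2::theme_minimal()
}

#' Youden-index optimal cutoff
#'
#' Maximises `sensitivity + specificity - 1` over candidate thresholds
#' (midpoints between adjacent distinct observed values); ties are broken
#' toward higher specificity.
#'
#' @inheritParams empirical_auc
#' @return A one-row tibble: `cutoff`, `j`, `sensitivity`, `specificity`.
#' @export
youden_cutoff <- function(data, scores, labels,
                          direction = "lower_is_abnormal") {
  roc <- empirical_auc(data, {{ scores }}, {{ labels }},
                       direction = direction)
  as_tibble(roc$youden[c("cutoff", "j", "sensitivity", "specificity")])
}

#' DeLong test for two paired (correlated) AUCs
#'
#' Compares the AUCs of two markers measured on the same observations via
#' the structural-components estimator of the covariance of the two
#' empirical AUCs; the two-sided p-value uses the normal distribution.
#'
#' @param scores_a,scores_b Two score vectors on the same observations.
#' @param labels Binary reference labels (TRUE = abnormal).
#' @param direction Orientation shared by both markers.
#' @return A one-row tibble: `auc_a`, `auc_b`, `difference`, `statistic`
#'   (z), `p.value`.
#' @export
delong_paired_test <- function(scores_a, scores_b, labels,
                               direction = "lower_is_abnormal") {
  if (length(scores_a) != length(scores_b) ||
      length(scores_a) != length(labels))
    abort("scores_a, scores_b and labels must have equal length",
          class = "ctperf_input_error")
  lb <- check_two_classes(labels)
  pa <- delong_placements(orient_scores(scores_a, direction), lb)
  pb <- delong_placements(orient_scores(scores_b, direction), lb)
  s10 <- stats::cov(cbind(pa$v10, pb$v10))
  s01 <- stats::cov(cbind(pa$v01, pb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / pa$m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / pa$n
  diff <- pa$auc - pb$auc
  if (var_diff <= .Machine$double.eps) {
    if (abs(diff) > 1e-12)
      abort("degenerate variance with unequal AUCs in the DeLong test",
            class = "ctperf_degenerate_error")
    z <- 0
    p <- 1
  } else {
    z <- diff / sqrt(var_diff)
    p <- 2 * pnorm(-abs(z))
  }
  tibble(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
         statistic = z, p.value = p)
}

#' Wilson score confidence interval for a binomial proportion
#'
#' @param successes,trials Counts with `0 <= successes <= trials`,
#'   `trials >= 1`.
#' @param level Confidence level.
#' @return A one-row tibble: `estimate`, `lower`, `upper`, `n`.
#' @examples
#' wilson_ci(49, 63) # sensitivity 78% (66-86%)
#' @export
wilson_ci <- function(successes, trials, level = 0.95) {
  if (trials < 1 || successes < 0 || successes > trials)
    abort("need 0 <= successes <= trials and trials >= 1",
          class = "ctperf_input_error")
  z <- qnorm(1 - (1 - level) / 2)
  p <- successes / trials
  den <- 1 + z^2 / trials
  centre <- p + z^2 / (2 * trials)
  half <- z * sqrt(p * (1 - p) / trials + z^2 / (4 * trials^2))
  tibble(estimate = p, lower = (centre - half) / den,
         upper = (centre + half) / den, n = trials)
}

#' Sensitivity, specificity and predictive values with Wilson intervals
#'
#' @param tp,fp,fn,tn Confusion-matrix counts (or pass a single list /
#'   one-row data frame with those fields as `tp`).
#' @param level Confidence level for the Wilson intervals.
#' @return A tibble with one row per metric (`sensitivity`, `specificity`,
#'   `ppv`, `npv`): `estimate`, `lower`, `upper`, `successes`, `trials`,
#'   and `defined` (FALSE when the denominator is zero; such rows carry
#'   `NA` estimates).
#' @examples
#' confusion_metrics(tp = 49, fp = 54, fn = 14, tn = 283)
#' @export
confusion_metrics <- function(tp, fp = NULL, fn = NULL, tn = NULL,
                              level = 0.95) {
  if (is.list(tp) || is.data.frame(tp)) {
    cm <- tp
    tp <- cm$tp
    fp <- cm$fp
    fn <- cm$fn
    tn <- cm$tn
  }
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts)))
    abort("confusion counts must be nonnegative integers",
          class = "ctperf_input_error")
  one <- function(metric, succ, tot) {
    if (tot == 0)
      return(tibble(metric = metric, estimate = NA_real_, lower = NA_real_,
                    upper = NA_real_, successes = succ, trials = tot,
                    defined = FALSE))
    ci <- wilson_ci(succ, tot, level)
    tibble(metric = metric, estimate = ci$estimate, lower = ci$lower,
           upper = ci$upper, successes = succ, trials = tot, defined = TRUE)
  }
  bind_rows(one("sensitivity", tp, tp + fn),
            one("specificity", tn, tn + fp),
            one("ppv", tp, tp + fp),
            one("npv", tn, tn + fn))
}

#' Reconstruct a confusion matrix from printed sensitivity and specificity
#'
#' Given published sensitivity/specificity percentages and the class totals,
#' recovers the integer confusion matrix by round-half-up: `tp` is the
#' nearest integer to `sens_pct/100 * n_pos`, `tn` to
#' `spec_pct/100 * n_neg`, with `fn`/`fp` by complement.
#'
#' @param sens_pct,spec_pct Percentages in `[0, 100]`.
#' @param n_pos,n_neg Class totals (>= 1).
#' @return A one-row tibble: `tp`, `fp`, `fn`, `tn`.
#' @examples
#' reconstruct_confusion(78, 84, 63, 337)
#' @export
reconstruct_confusion <- function(sens_pct, spec_pct, n_pos, n_neg) {
  stopifnot(sens_pct >= 0, sens_pct <= 100, spec_pct >= 0, spec_pct <= 100,
            n_pos >= 1, n_neg >= 1)
  round_half_up <- function(x) floor(x + 0.5)
  tp <- round_half_up(sens_pct / 100 * n_pos)
  tn <- round_half_up(spec_pct / 100 * n_neg)
  tibble(tp = tp, fp = n_neg - tn, fn = n_pos - tp, tn = tn)
}

#' Mann-Whitney U test with midranks
#'
#' U statistic computed with midranks, with a normal-approximation two-sided
#' p-value using the tie-corrected variance and a continuity correction.
#'
#' @param group_a,group_b Numeric samples.
#' @return A one-row tibble: `u` (for `group_a`), `statistic` (z),
#'   `p.value`, `n_a`, `n_b`.
#' @export
mann_whitney_u <- function(group_a, group_b) {
  if (length(group_a) == 0 || length(group_b) == 0)
    abort("both groups must be nonempty", class = "ctperf_input_error")
  na <- length(group_a)
  nb <- length(group_b)
  nn <- na + nb
  r <- rank(c(group_a, group_b), ties.method = "average")
  u <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  tie_sizes <- table(c(group_a, group_b))
  tie_term <- sum(tie_sizes^3 - tie_sizes)
  v <- na * nb / 12 * ((nn + 1) - tie_term / (nn * (nn - 1)))
  mu <- na * nb / 2
  if (v <= 0) {
    z <- 0
    p <- 1
  } else {
    z <- (u - mu - sign(u - mu) * 0.5) / sqrt(v)
    p <- min(1, 2 * pnorm(-abs(z)))
  }
  tibble(u = u, statistic = z, p.value = p, n_a = na, n_b = nb)
}

#' Cohen's kappa for two binary raters
#'
#' Chance-corrected agreement `(p_o - p_e) / (1 - p_e)` from the 2x2
#' agreement table, with an asymptotic normal confidence interval.
#'
#' @param calls_a,calls_b Logical/binary vectors of equal length >= 2.
#' @param level Confidence level.
#' @return A one-row tibble: `statistic_name`, `value`, `lower`, `upper`,
#'   `defined` (`FALSE`, with `NA` value, when both raters are constant and
#'   identical so chance agreement is 1).
#' @export
cohen_kappa <- function(calls_a, calls_b, level = 0.95) {
  if (length(calls_a) != length(calls_b) || length(calls_a) < 2)
    abort("call vectors must have equal length >= 2",
          class = "ctperf_input_error")
  a <- as.logical(calls_a)
  b <- as.logical(calls_b)
  n <- length(a)
  po <- mean(a == b)
  pe <- mean(a) * mean(b) + mean(!a) * mean(!b)
  if (abs(1 - pe) < .Machine$double.eps)
    return(tibble(statistic_name = "kappa", value = NA_real_,
                  lower = NA_real_, upper = NA_real_, defined = FALSE))
  k <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / (n * (1 - pe)^2))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(statistic_name = "kappa", value = k,
         lower = max(-1, k - z * se), upper = min(1, k + z * se),
         defined = TRUE)
}

#' Intraclass correlation, two-way random, absolute agreement, single measure
#'
#' ICC(2,1) from the two-way ANOVA mean squares of an n x k ratings matrix
#' (targets x raters), with the F-distribution confidence bounds of McGraw
#' and Wong.
#'
#' @param ratings Numeric matrix or data frame, one row per target, one
#'   column per rater; >= 5 targets, >= 2 raters, no missing cells.
#' @param level Confidence level.
#' @return A one-row tibble: `statistic_name`, `value`, `lower`, `upper`,
#'   `defined`.
#' @export
icc_absolute_agreement <- function(ratings, level = 0.95) {
  m <- as.matrix(ratings)
  if (any(is.na(m)))
    abort("ratings must have no missing cells", class = "ctperf_input_error")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 5 || k < 2)
    abort("need at least 5 targets and 2 raters",
          class = "ctperf_input_error")
  grand <- mean(m)
  row_m <- rowMeans(m)
  col_m <- colMeans(m)
  ss_total <- sum((m - grand)^2)
  if (ss_total <= .Machine$double.eps)
    return(tibble(statistic_name = "icc", value = NA_real_,
                  lower = NA_real_, upper = NA_real_, defined = FALSE))
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_err <- ss_total - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - level
  a <- k * icc / (n * (1 - icc))
  b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  fl <- qf(1 - alpha / 2, n - 1, v)
  fu <- qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - fl * mse) /
    (fl * (k * msc + (k * n - n - k) * mse) + n * msr)
  upper <- n * (fu * msr - mse) /
    (k * msc + (k * n - n - k) * mse + n * fu * msr)
  tibble(statistic_name = "icc", value = icc, lower = lower, upper = upper,
         defined = TRUE)
}

#' Paired t-test
#'
#' Standard paired statistic with a two-sided p-value, used to compare
#' rest and stress heart rates.
#'
#' @param a,b Paired numeric vectors of equal length >= 2.
#' @return A one-row tibble: `estimate` (mean difference), `statistic`,
#'   `parameter` (df), `p.value`.
#' @export
paired_t_test <- function(a, b) {
  if (length(a) != length(b) || length(a) < 2)
    abort("paired samples must have equal length >= 2",
          class = "ctperf_input_error")
  d <- a - b
  s <- sd(d)
  n <- length(d)
  if (s == 0) {
    if (mean(d) == 0)
      return(tibble(estimate = 0, statistic = 0, parameter = n - 1,
                    p.value = 1))
    abort("zero variance of differences with nonzero mean difference",
          class = "ctperf_degenerate_error")
  }
  t <- mean(d) / (s / sqrt(n))
  tibble(estimate = mean(d), statistic = t, parameter = n - 1,
         p.value = 2 * pt(-abs(t), df = n - 1))
}

#' Effective dose from the dose-length product
#'
#' Chest conversion: effective dose (mSv) = DLP (mGy.cm) x 0.014.
#'
#' @param dlp Dose-length product, mGy.cm, nonnegative.
#' @param conversion_factor mSv per mGy.cm.
#' @return Effective dose in mSv.
#' @examples
#' effective_dose(754.4)
#' @export
effective_dose <- function(dlp, conversion_factor = 0.014) {
  if (any(dlp < 0))
    abort("DLP must be nonnegative", class = "ctperf_input_error")
  dlp * conversion_factor
}
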