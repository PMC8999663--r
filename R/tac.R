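tac_values <- function(data) {
  if (is.numeric(data)) return(as.numeric(data))
  if (is.data.frame(data)) {
    if (!"value_hu" %in% names(data))
      abort("a time-attenuation curve needs a `value_hu` column",
            class = "ctperf_input_error")
    return(as.numeric(data$value_hu))
  }
  abort("time-attenuation curve must be a numeric vector or a data frame",
        class = "ctperf_input_error")
}

tac_times <- function(data) {
  if (is.data.frame(data) && "frame_time_s" %in% names(data))
    return(as.numeric(data$frame_time_s))
  seq_along(tac_values(data))
}

new_tac <- function(frame_time_s, value_hu, roi_label) {
  structure(tibble(frame = seq_along(frame_time_s),
                   frame_time_s = frame_time_s,
                   value_hu = value_hu,
                   roi_label = roi_label),
            class = c("ctp_tac", class(tibble())))
}

#' Peak enhancement of a time-attenuation curve
#'
#' Peak enhancement (PE) is the difference between the baseline and the peak
#' CT attenuation of a curve: the baseline is the mean of the first
#' `n_baseline_frames` values and the peak is the maximum of the remaining
#' values. For the aorta, PE in the timing-bolus scan is the denominator of
#' the myocardial perfusion ratio.
#'
#' @param data A numeric vector of HU values, or a data frame with a
#'   `value_hu` column (and optionally `frame_time_s`).
#' @param n_baseline_frames Number of leading pre-contrast frames averaged
#'   into the baseline (default 2, the timing-bolus convention; dynamic
#'   series use 1 since their first frame is pre-contrast).
#' @return A `ctp_pe` object with fields `baseline`, `peak`, `pe`
#'   (`peak - baseline`, HU) and `peak_frame` (index into the full curve).
#' @examples
#' compute_peak_enhancement(c(50, 50, 130.8, 90), n_baseline_frames = 2)$pe
#' @export
compute_peak_enhancement <- function(data, n_baseline_frames = 2) {
  v <- tac_values(data)
  if (length(v) < 3)
    abort("time-attenuation curve needs at least 3 frames",
          class = "ctperf_input_error")
  if (n_baseline_frames < 1 || n_baseline_frames >= length(v))
    abort("n_baseline_frames must be >= 1 and smaller than the frame count",
          class = "ctperf_input_error")
  baseline <- mean(v[seq_len(n_baseline_frames)])
  rest <- v[-seq_len(n_baseline_frames)]
  peak_rel <- which.max(rest)
  structure(list(baseline = baseline,
                 peak = rest[peak_rel],
                 pe = rest[peak_rel] - baseline,
                 peak_frame = n_baseline_frames + peak_rel),
            class = "ctp_pe")
}

#' @export
print.ctp_pe <- function(x, ...) {
  cat(sprintf("<ctp_pe> PE %.1f HU (baseline %.1f, peak %.1f at frame %d)\n",
              x$pe, x$baseline, x$peak, x$peak_frame))
  invisible(x)
}

#' @export
tidy.ctp_pe <- function(x, ...) {
  tibble(baseline = x$baseline, peak = x$peak, pe = x$pe,
         peak_frame = x$peak_frame)
}

#' Select the static phase from a dynamic perfusion series
#'
#' The static CTP image is one frame of the dynamic series, chosen late
#' enough for myocardial enhancement but past the aortic first pass. The
#' default rule returns the first frame, at or after the aortic peak frame,
#' at which the mean myocardial curve attains its maximum over the remaining
#' frames. Alternatively a fixed frame offset after the aortic peak can be
#' requested.
#'
#' @param aorta,myocardium_mean Aortic and mean-myocardial curves sharing
#'   one frame grid (numeric vectors or data frames with `value_hu` /
#'   `frame_time_s`).
#' @param rule `"myocardial_peak"` (default) or `"fixed_offset"`.
#' @param offset Frame offset after the aortic peak for the
#'   `"fixed_offset"` rule (clipped to the series length).
#' @param n_baseline_frames Baseline frames for the aortic peak search.
#' @return The selected frame index (never earlier than the aortic peak
#'   frame).
#' @export
select_static_phase <- function(aorta, myocardium_mean,
                                rule = c("myocardial_peak", "fixed_offset"),
                                offset = 3, n_baseline_frames = 1) {
  rule <- match.arg(rule)
  ta <- tac_times(aorta)
  tm <- tac_times(myocardium_mean)
  if (length(ta) != length(tm) || any(abs(ta - tm) > 1e-8))
    abort("aortic and myocardial curves must share one frame grid",
          class = "ctperf_input_error")
  apf <- compute_peak_enhancement(aorta, n_baseline_frames)$peak_frame
  if (rule == "fixed_offset") return(min(apf + offset, length(ta)))
  myo <- tac_values(myocardium_mean)
  tail_vals <- myo[apf:length(myo)]
  apf + which.max(tail_vals) - 1L
}

#' Pearson correlation between timing-bolus and dynamic peak enhancement
#'
#' Product-moment correlation of per-patient (timing PE, dynamic PE) pairs,
#' with a two-sided p-value from the t transform.
#'
#' @param data A data frame of per-patient values, or a numeric vector.
#' @param timing,dynamic Columns of `data` (tidy-eval), or two numeric
#'   vectors when `data` is numeric.
#' @return A one-row tibble with `estimate`, `statistic`, `p.value` and `n`.
#' @examples
#' pe_correlation(tibble::tibble(t = c(1, 2, 3), d = c(2, 4, 6)), t, d)
#' @export
pe_correlation <- function(data, timing, dynamic) {
  if (is.numeric(data)) {
    x <- data
    y <- timing
  } else {
    x <- dplyr::pull(data, {{ timing }})
    y <- dplyr::pull(data, {{ dynamic }})
  }
  if (length(x) != length(y) || length(x) < 3)
    abort("correlation needs at least 3 complete pairs",
          class = "ctperf_input_error")
  if (sd(x) == 0 || sd(y) == 0)
    abort("correlation undefined: a coordinate has zero variance",
          class = "ctperf_degenerate_error")
  n <- length(x)
  r <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  if (abs(r) >= 1) {
    stat <- Inf * sign(r)
    p <- 0
  } else {
    stat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * pt(-abs(stat), df = n - 2)
  }
  tibble(estimate = r, statistic = stat, p.value = p, n = n)
}

#' @describeIn compute_peak_enhancement Plot a time-attenuation curve.
#' @param object,... For `autoplot`, a `ctp_tac` and ignored arguments.
#' @export
autoplot.ctp_tac <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frame_time_s, .data$value_hu,
                                       colour = .data$roi_label)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "time (s)", y = "attenuation (HU)", colour = "ROI") +
    ggplot2::theme_minimal()
}
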