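#' Myocardial perfusion ratio (MPR)
#'
#' MPR normalises a segment's subendocardial enhancement (baseline-subtracted
#' endocardial HU in the static image) by the aortic peak enhancement of the
#' diluted timing-bolus scan, removing patient-level variability in contrast
#' delivery. Normally perfused myocardium sits near 1.
#'
#' @param endo_enhancement Subendocardial enhancement (HU), vectorised.
#' @param aortic_pe_timing_bolus Aortic timing-bolus peak enhancement (HU),
#'   scalar or vector; must be positive.
#' @return `endo_enhancement / aortic_pe_timing_bolus`.
#' @examples
#' compute_mpr(80.8, 80.8)
#' compute_mpr(48, 80) # below the reported 0.81 cutoff -> abnormal
#' @export
compute_mpr <- function(endo_enhancement, aortic_pe_timing_bolus) {
  if (any(!is.finite(aortic_pe_timing_bolus)) ||
      any(aortic_pe_timing_bolus <= 0))
    abort("aortic timing-bolus PE must be positive (bolus detection failed?)",
          class = "ctperf_degenerate_error")
  endo_enhancement / aortic_pe_timing_bolus
}

#' Transmural perfusion ratio (TPR)
#'
#' TPR is a segment's endocardial CT attenuation divided by the mean
#' epicardial CT attenuation over all 16 segments of the same patient.
#' Subendocardial hypoperfusion lowers it; balanced transmural defects,
#' which depress the epicardial mean as well, can falsely normalise it.
#'
#' @param segment_endo_attenuation Endocardial attenuation (HU) of one or
#'   more segments.
#' @param all_epi_attenuations Epicardial attenuation (HU) of all 16
#'   segments of the patient.
#' @return `segment_endo_attenuation / mean(all_epi_attenuations)`.
#' @examples
#' compute_tpr(110.4, rep(115, 16))
#' @export
compute_tpr <- function(segment_endo_attenuation, all_epi_attenuations) {
  if (length(all_epi_attenuations) != 16)
    abort("TPR needs the epicardial attenuation of exactly 16 segments",
          class = "ctperf_input_error")
  denom <- mean(all_epi_attenuations)
  if (!is.finite(denom) || denom <= 0)
    abort("mean epicardial attenuation must be positive",
          class = "ctperf_degenerate_error")
  segment_endo_attenuation / denom
}

#' Classify a perfusion parameter value against a cutoff
#'
#' All three quantitative parameters (MPR, TPR, endocardial attenuation)
#' decrease with hypoperfusion, so a segment is called abnormal when its
#' value falls strictly below the cutoff; a value equal to the cutoff is
#' called normal.
#'
#' @param value Parameter values.
#' @param cutoff Finite cutoff in the same units.
#' @param direction Only `"lower_is_abnormal"` is defined.
#' @return Logical vector, `TRUE` = abnormal.
#' @examples
#' classify_segment(c(0.69, 0.81, 0.9), cutoff = 0.81)
#' @export
classify_segment <- function(value, cutoff,
                             direction = "lower_is_abnormal") {
  direction <- match.arg(direction, "lower_is_abnormal")
  if (!is.finite(cutoff))
    abort("cutoff must be finite", class = "ctperf_input_error")
  value < cutoff
}

#' Add perfusion parameters to a per-segment measurement table
#'
#' Computes MPR and TPR for every patient x segment row. The table must
#' carry `patient_id`, `segment_id`, `endo_hu`, `epi_hu`, `endo_enh_hu` and
#' a per-row `aortic_pe_timing` column; TPR is computed within each
#' patient's 16 segments.
#'
#' @param data A measurement tibble (one row per patient x segment).
#' @return `data` with `mpr` and `tpr` columns appended.
#' @export
add_parameters <- function(data) {
  need <- c("patient_id", "segment_id", "endo_hu", "epi_hu", "endo_enh_hu",
            "aortic_pe_timing")
  miss <- setdiff(need, names(data))
  if (length(miss) > 0)
    abort(paste0("missing columns: ", paste(miss, collapse = ", ")),
          class = "ctperf_input_error")
  data |>
    group_by(.data$patient_id) |>
    mutate(mpr = compute_mpr(.data$endo_enh_hu, .data$aortic_pe_timing),
           tpr = compute_tpr(.data$endo_hu, .data$epi_hu)) |>
    ungroup()
}

#' Apply cutoffs to a parameter table
#'
#' @param data Output of [add_parameters()].
#' @param cutoffs Named list with elements `mpr`, `tpr`, `endo_hu`.
#' @return `data` with logical `call_mpr`, `call_tpr`, `call_hu` columns.
#' @export
classify_parameters <- function(data, cutoffs) {
  mutate(data,
         call_mpr = classify_segment(.data$mpr, cutoffs$mpr),
         call_tpr = classify_segment(.data$tpr, cutoffs$tpr),
         call_hu = classify_segment(.data$endo_hu, cutoffs$endo_hu))
}
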