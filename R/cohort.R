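# lognormal decomposition of the two aortic peak enhancements into a shared
# patient factor (cardiac output) plus scan-specific residuals, solved so the
# marginal means/SDs and the between-scan correlation match the configuration
pe_lognormal_params <- function(cfg) {
  cv_t <- cfg$aortic_pe_timing_mean_sd[2] / cfg$aortic_pe_timing_mean_sd[1]
  cv_d <- cfg$aortic_pe_dynamic_mean_sd[2] / cfg$aortic_pe_dynamic_mean_sd[1]
  s_t <- sqrt(log(1 + cv_t^2))
  s_d <- sqrt(log(1 + cv_d^2))
  s_c2 <- cfg$pe_correlation_target * s_t * s_d
  if (s_c2 > min(s_t^2, s_d^2))
    config_error("pe_correlation_target",
                 "not attainable with the configured PE coefficients of variation")
  list(
    s_c = sqrt(s_c2),
    s_t = sqrt(s_t^2 - s_c2),
    s_d = sqrt(s_d^2 - s_c2),
    mu_t = log(cfg$aortic_pe_timing_mean_sd[1]) - s_t^2 / 2,
    mu_d = log(cfg$aortic_pe_dynamic_mean_sd[1]) - s_d^2 / 2
  )
}

#' Assign SPECT-like stress/rest perfusion scores to segments
#'
#' Maps a perfusion class and a severity in `[0, 1]` onto the 5-point
#' perfusion scale (0 normal, 1 mildly reduced, 2 moderately reduced,
#' 3 severely reduced, 4 absent). A segment is reference-positive
#' (abnormal) when its stress score is >= 2. Reversible abnormalities
#' (present under stress, resolved at rest) are ischaemic; fixed
#' abnormalities (present in both states) are infarcted.
#'
#' @param perfusion_class Character vector with values `"normal"`,
#'   `"ischemic"` or `"infarcted"`.
#' @param severity Numeric vector in `[0, 1]`; higher is worse.
#' @return A tibble with columns `perfusion_class`, `stress_score`,
#'   `rest_score` and logical `abnormal`.
#' @examples
#' assign_spect_scores(c("normal", "ischemic", "infarcted"), c(0.1, 0.9, 0.5))
#' @export
assign_spect_scores <- function(perfusion_class, severity) {
  if (length(severity) == 1) severity <- rep(severity, length(perfusion_class))
  if (length(perfusion_class) != length(severity))
    abort("perfusion_class and severity must have the same length",
          class = "ctperf_input_error")
  ok <- perfusion_class %in% c("normal", "ischemic", "infarcted")
  if (!all(ok))
    abort(sprintf("unknown perfusion class: %s",
                  paste(unique(perfusion_class[!ok]), collapse = ", ")),
          class = "ctperf_input_error")
  if (any(!is.finite(severity)) || any(severity < 0 | severity > 1))
    abort("severity must lie in [0, 1]", class = "ctperf_input_error")
  stress <- ifelse(perfusion_class == "normal",
                   as.integer(severity > 0.7),
                   2L + pmin(2L, as.integer(floor(severity * 3))))
  rest <- dplyr::case_when(
    perfusion_class == "normal"    ~ 0L,
    perfusion_class == "ischemic"  ~ as.integer(stress == 4L),
    perfusion_class == "infarcted" ~ as.integer(stress)
  )
  tibble(perfusion_class = perfusion_class,
         stress_score = as.integer(stress),
         rest_score = rest,
         abnormal = stress >= 2L)
}

# all truth-level draws for one patient, in a fixed order under one substream
generate_patient <- function(i, cfg, pe_par, adjacency) {
  withr::with_seed(substream_seed(cfg$master_seed, i, "truth"), {
    z_c <- rnorm(1)
    cof <- exp(pe_par$s_c * z_c)
    pe_timing <- exp(pe_par$mu_t + pe_par$s_c * z_c + pe_par$s_t * rnorm(1))
    pe_dynamic <- exp(pe_par$mu_d + pe_par$s_c * z_c + pe_par$s_d * rnorm(1))
    hr_rest <- rnorm(1, cfg$hr_rest_mean_sd[1], cfg$hr_rest_mean_sd[2])
    z_hr <- rnorm(1)
    hr_stress <- cfg$hr_stress_mean_sd[1] +
      0.6 * cfg$hr_stress_mean_sd[2] / cfg$hr_rest_mean_sd[2] *
        (hr_rest - cfg$hr_rest_mean_sd[1]) +
      sqrt(1 - 0.36) * cfg$hr_stress_mean_sd[2] * z_hr
    hr_rest <- max(35, hr_rest)
    hr_stress <- max(hr_rest + 2, hr_stress)
    groove_angle <- runif(1, 0, 2 * pi)

    diseased <- runif(1) < cfg$patient_disease_prob &&
      cfg$expected_abnormal_fraction > 0
    region <- integer(0)
    infarcted_region <- FALSE
    balanced <- FALSE
    if (diseased) {
      extent <- 1L + rbinom(1, 15L, defect_growth_prob(cfg))
      region <- grow_defect_region(extent, adjacency)
      infarcted_region <- runif(1) < cfg$infarct_fraction_of_abnormal
      balanced <- runif(1) < cfg$balanced_transmural_prob
    }
    cls <- rep("normal", 16)
    cls[region] <- if (infarcted_region) "infarcted" else "ischemic"
    abnormal <- cls != "normal"

    u_mpr <- runif(16)
    z_att <- cfg$attenuation_pe_coupling * z_c +
      sqrt(1 - cfg$attenuation_pe_coupling^2) * rnorm(16)
    z_epi <- cfg$attenuation_pe_coupling * z_c +
      sqrt(1 - cfg$attenuation_pe_coupling^2) * rnorm(16)
    grad <- pmax(0.5, rnorm(16, cfg$epi_gradient_mean_sd[1],
                            cfg$epi_gradient_mean_sd[2]))

    mpr_true <- ifelse(abnormal,
                       qsplitnorm(u_mpr, cfg$mpr_quartiles_abnormal, lower = 0),
                       qsplitnorm(u_mpr, cfg$mpr_quartiles_normal, lower = 0))
    endo_attn <- ifelse(abnormal,
                        qsplitnorm(pnorm(z_att),
                                   cfg$endo_attn_quartiles_abnormal, lower = 0),
                        qsplitnorm(pnorm(z_att),
                                   cfg$endo_attn_quartiles_normal, lower = 0))
    # epicardial attenuation follows the endocardium in normal tissue and in
    # balanced-transmural defects; in subendocardial-only defects it keeps a
    # normally perfused appearance (this is what falsely normalises TPR in
    # extensive balanced defects)
    epi_normal_look <- qsplitnorm(pnorm(z_epi),
                                  cfg$endo_attn_quartiles_normal, lower = 0) / grad
    epi_attn <- ifelse(!abnormal | balanced, endo_attn / grad, epi_normal_look)

    severity <- 1 - u_mpr
    scores <- assign_spect_scores(cls, severity)

    endo_enh <- mpr_true * pe_timing
    epi_baseline <- pmin(cfg$epi_baseline_hu, epi_attn)
    segs <- tibble(
      segment_id = 1:16,
      level = aha_segments()$level,
      perfusion_class = cls,
      stress_score = scores$stress_score,
      rest_score = scores$rest_score,
      abnormal = scores$abnormal,
      severity = severity,
      mpr_true = mpr_true,
      endo_attn_true = endo_attn,
      epi_attn_true = epi_attn,
      endo_enh_true = endo_enh,
      epi_enh_true = epi_attn - epi_baseline,
      endo_baseline_hu = endo_attn - endo_enh,
      epi_baseline_hu = epi_baseline,
      balanced_defect = abnormal & balanced
    )
    list(
      patient_id = sprintf("P%03d", i),
      patient_index = i,
      cardiac_output_factor = cof,
      pe_timing_true = pe_timing,
      pe_dynamic_true = pe_dynamic,
      hr_rest = hr_rest,
      hr_stress = hr_stress,
      groove_angle = groove_angle,
      segments = segs
    )
  })
}

#' Generate a synthetic CT-perfusion phantom cohort
#'
#' Draws a seeded cohort of patient phantoms. Each patient carries a shared
#' cardiac-output factor (inducing the configured correlation between
#' timing-bolus and dynamic aortic peak enhancement), gamma-variate contrast
#' kinetics, rest/stress heart rates, a contiguous perfusion defect in a
#' random subset of patients, and 16 AHA segments with true MPR, endocardial
#' and epicardial attenuation, enhancement targets and SPECT-like stress/rest
#' truth scores. Per-class MPR and attenuation marginals are two-piece
#' normals hitting the configured quartile triples exactly.
#'
#' @param config A [cohort_config()].
#' @param n_patients Optional override of `config$n_patients`.
#' @return An object of class `ctp_cohort`: a list with elements `config`,
#'   `patients` (list of phantoms) and the tibbles returned by
#'   [segment_truth()] and [patient_table()].
#' @examples
#' coh <- generate_cohort(cohort_config(n_patients = 2, master_seed = 42))
#' segment_truth(coh)
#' @export
generate_cohort <- function(config = cohort_config(), n_patients = NULL) {
  if (!inherits(config, "ctp_config")) config <- validate_config(config)
  if (!is.null(n_patients)) {
    config$n_patients <- n_patients
    config <- validate_config(unclass(config))
  }
  pe_par <- pe_lognormal_params(config)
  adjacency <- aha_adjacency()
  patients <- lapply(seq_len(config$n_patients), generate_patient,
                     cfg = config, pe_par = pe_par, adjacency = adjacency)
  structure(list(config = config, patients = patients), class = "ctp_cohort")
}

#' Per-segment truth table of a cohort
#'
#' @param cohort A `ctp_cohort`.
#' @return A tibble with one row per patient x segment.
#' @export
segment_truth <- function(cohort) {
  stopifnot(inherits(cohort, "ctp_cohort"))
  bind_rows(lapply(cohort$patients, function(p) {
    mutate(p$segments, patient_id = p$patient_id, .before = 1)
  }))
}

#' Per-patient table of a cohort
#'
#' @param cohort A `ctp_cohort`.
#' @return A tibble with one row per patient.
#' @export
patient_table <- function(cohort) {
  stopifnot(inherits(cohort, "ctp_cohort"))
  bind_rows(lapply(cohort$patients, function(p) {
    tibble(patient_id = p$patient_id,
           cardiac_output_factor = p$cardiac_output_factor,
           pe_timing_true = p$pe_timing_true,
           pe_dynamic_true = p$pe_dynamic_true,
           hr_rest = p$hr_rest,
           hr_stress = p$hr_stress,
           groove_angle = p$groove_angle,
           n_abnormal = sum(p$segments$abnormal))
  }))
}

#' @export
print.ctp_cohort <- function(x, ...) {
  st <- segment_truth(x)
  cat(sprintf("<ctp_cohort> %d patients, %d segments (%d abnormal: %d ischemic, %d infarcted)\n",
              length(x$patients), nrow(st), sum(st$abnormal),
              sum(st$perfusion_class == "ischemic"),
              sum(st$perfusion_class == "infarcted")))
  invisible(x)
}

#' @describeIn generate_cohort Class-wise distribution plot of true MPR and
#'   endocardial attenuation across the cohort.
#' @param object,... An autoplot `ctp_cohort` and ignored arguments.
#' @export
autoplot.ctp_cohort <- function(object, ...) {
  st <- segment_truth(object)
  long <- tidyr::pivot_longer(
    select(st, "abnormal", "mpr_true", "endo_attn_true"),
    c("mpr_true", "endo_attn_true"),
    names_to = "parameter", values_to = "value")
  long$parameter <- ifelse(long$parameter == "mpr_true", "MPR",
                           "endocardial attenuation (HU)")
  ggplot2::ggplot(long, ggplot2::aes(
    x = ifelse(.data$abnormal, "abnormal", "normal"),
    y = .data$value, fill = .data$abnormal)) +
    ggplot2::geom_violin(show.legend = FALSE) +
    ggplot2::geom_boxplot(width = 0.15, fill = "white", outlier.shape = NA) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}
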