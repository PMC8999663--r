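#' Configuration for a synthetic CT-perfusion phantom cohort
#'
#' Builds and validates the full set of parameters controlling the synthetic
#' cohort generator: cohort composition, per-class distributions of the
#' quantitative perfusion parameters, aortic contrast kinetics, haemodynamics,
#' and short-axis image geometry. Defaults are calibrated to the printed
#' summary statistics of a 25-patient static-CTP study cohort: segment-level
#' abnormality prevalence 63/400 with 49/63 of abnormal segments infarcted,
#' timing-bolus aortic peak enhancement 80.8 (SD 18.1) HU, dynamic-scan aortic
#' peak enhancement 393.8 (SD 91.7) HU with patient-level correlation 0.84
#' between the two, and per-class median (IQR) targets of 1.0 (0.9-1.1) /
#' 0.7 (0.5-0.8) for MPR and 128 (112-144) / 106 (95-124) HU for endocardial
#' attenuation.
#'
#' Per-class values are drawn from a two-piece (split) normal parameterised to
#' hit the configured quartile triple exactly (see [qsplitnorm()]), truncated
#' at zero.
#'
#' @param n_patients Number of patients in the cohort.
#' @param n_segments_per_patient Segments per patient; must be 16 (AHA model).
#' @param expected_abnormal_fraction Expected fraction of reference-positive
#'   (stress score >= 2) segments.
#' @param infarct_fraction_of_abnormal Expected fraction of abnormal segments
#'   whose defect is fixed (infarct) rather than reversible (ischaemia).
#' @param patient_disease_prob Probability that a patient carries any
#'   perfusion defect; together with `expected_abnormal_fraction` this sets
#'   the mean defect extent of diseased patients (defects are contiguous in
#'   the 16-segment adjacency graph).
#' @param balanced_transmural_prob Probability that a diseased patient's
#'   defect is balanced-transmural (epicardial attenuation reduced together
#'   with endocardial), the mechanism that falsely normalises TPR.
#' @param mpr_quartiles_normal,mpr_quartiles_abnormal Quartile triples
#'   (25th, 50th, 75th) of true segment MPR per class.
#' @param endo_attn_quartiles_normal,endo_attn_quartiles_abnormal Quartile
#'   triples of endocardial attenuation (HU) per class.
#' @param aortic_pe_timing_mean_sd,aortic_pe_dynamic_mean_sd Mean and SD (HU)
#'   of aortic peak enhancement in the diluted timing-bolus scan and the
#'   full-strength dynamic scan.
#' @param pe_correlation_target Target patient-level Pearson correlation
#'   between timing-bolus and dynamic aortic peak enhancement.
#' @param attenuation_pe_coupling Copula correlation (0-1) between a
#'   segment's latent attenuation score and the patient's shared cardiac
#'   output factor; routes patient-level aortic-enhancement variability into
#'   the attenuation parameter while leaving the ratio parameters untouched
#'   and the per-class attenuation marginals exact.
#' @param hr_rest_mean_sd,hr_stress_mean_sd Heart-rate mean and SD pairs
#'   (beats/min) at rest and under stress.
#' @param contrast_dilution Timing-bolus contrast dilution relative to full
#'   strength (0.2 = a 20 percent solution).
#' @param kinetics Gamma-variate bolus parameters: `t0` arrival time (s),
#'   `alpha` shape, `beta` scale (s), plus myocardial `delay` (s) and added
#'   `dispersion` (s, widens beta for the myocardial curve).
#' @param aortic_baseline_hu Pre-contrast blood-pool attenuation (HU).
#' @param epi_baseline_hu Pre-contrast epicardial-layer attenuation (HU).
#' @param epi_gradient_mean_sd Mean and SD of the per-segment endo/epi
#'   attenuation ratio in normally perfused myocardium.
#' @param timing_frames,timing_frame_interval_s Timing-bolus sampling.
#' @param n_dynamic_frames Frames in the dynamic series (one per cardiac
#'   cycle under stress).
#' @param image_geometry List: `matrix_size`, `n_slices` (multiple of 3),
#'   `slice_thickness_mm`, `endo_radius`, `epi_radius` (voxels).
#' @param noise_sd Additive Gaussian image noise (HU).
#' @param observer_sd Named list of second-reader measurement noise SDs
#'   (`endo_hu`, `mpr`, `tpr`) used to emulate inter-observer agreement.
#' @param master_seed Integer master seed; all stage and patient substreams
#'   are derived from it.
#'
#' @return An object of class `ctp_config` (a validated named list).
#' @examples
#' cfg <- cohort_config(n_patients = 4, master_seed = 7)
#' cfg$expected_abnormal_fraction
#' @export
cohort_config <- function(n_patients = 25,
                          n_segments_per_patient = 16,
                          expected_abnormal_fraction = 63 / 400,
                          infarct_fraction_of_abnormal = 49 / 63,
                          patient_disease_prob = 0.6,
                          balanced_transmural_prob = 0.5,
                          mpr_quartiles_normal = c(0.9, 1.0, 1.1),
                          mpr_quartiles_abnormal = c(0.5, 0.7, 0.8),
                          endo_attn_quartiles_normal = c(112, 128, 144),
                          endo_attn_quartiles_abnormal = c(95, 106, 124),
                          aortic_pe_timing_mean_sd = c(80.8, 18.1),
                          aortic_pe_dynamic_mean_sd = c(393.8, 91.7),
                          pe_correlation_target = 0.84,
                          attenuation_pe_coupling = 0.5,
                          hr_rest_mean_sd = c(65.4, 10.2),
                          hr_stress_mean_sd = c(80.0, 8.0),
                          contrast_dilution = 0.2,
                          kinetics = list(t0 = 8, alpha = 3, beta = 3.5,
                                          delay = 4, dispersion = 1.5),
                          aortic_baseline_hu = 45,
                          epi_baseline_hu = 48,
                          epi_gradient_mean_sd = c(1.0, 0.03),
                          timing_frames = 30,
                          timing_frame_interval_s = 1,
                          n_dynamic_frames = 30,
                          image_geometry = list(matrix_size = 128,
                                                n_slices = 12,
                                                slice_thickness_mm = 5,
                                                endo_radius = 20,
                                                epi_radius = 32),
                          noise_sd = 10,
                          observer_sd = list(endo_hu = 5.3, mpr = 0.053,
                                             tpr = 0.052),
                          master_seed = 1L) {
  cfg <- list(
    n_patients = n_patients,
    n_segments_per_patient = n_segments_per_patient,
    expected_abnormal_fraction = expected_abnormal_fraction,
    infarct_fraction_of_abnormal = infarct_fraction_of_abnormal,
    patient_disease_prob = patient_disease_prob,
    balanced_transmural_prob = balanced_transmural_prob,
    mpr_quartiles_normal = mpr_quartiles_normal,
    mpr_quartiles_abnormal = mpr_quartiles_abnormal,
    endo_attn_quartiles_normal = endo_attn_quartiles_normal,
    endo_attn_quartiles_abnormal = endo_attn_quartiles_abnormal,
    aortic_pe_timing_mean_sd = aortic_pe_timing_mean_sd,
    aortic_pe_dynamic_mean_sd = aortic_pe_dynamic_mean_sd,
    pe_correlation_target = pe_correlation_target,
    attenuation_pe_coupling = attenuation_pe_coupling,
    hr_rest_mean_sd = hr_rest_mean_sd,
    hr_stress_mean_sd = hr_stress_mean_sd,
    contrast_dilution = contrast_dilution,
    kinetics = kinetics,
    aortic_baseline_hu = aortic_baseline_hu,
    epi_baseline_hu = epi_baseline_hu,
    epi_gradient_mean_sd = epi_gradient_mean_sd,
    timing_frames = timing_frames,
    timing_frame_interval_s = timing_frame_interval_s,
    n_dynamic_frames = n_dynamic_frames,
    image_geometry = image_geometry,
    noise_sd = noise_sd,
    observer_sd = observer_sd,
    master_seed = as.integer(master_seed)
  )
  validate_config(cfg)
}

config_error <- function(field, msg) {
  abort(sprintf("invalid configuration field `%s`: %s", field, msg),
        class = "ctperf_config_error", field = field)
}

validate_config <- function(cfg) {
  chk_count <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 1 || x != floor(x))
      config_error(field, "must be a positive integer")
  }
  chk_prop <- function(x, field) {
    if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1)
      config_error(field, "must be a proportion in [0, 1]")
  }
  chk_quartiles <- function(x, field) {
    if (!is.numeric(x) || length(x) != 3 || any(is.na(x)) || any(diff(x) <= 0))
      config_error(field, "must be a strictly increasing (q25, q50, q75) triple")
  }
  chk_mean_sd <- function(x, field) {
    if (!is.numeric(x) || length(x) != 2 || any(is.na(x)) || x[2] <= 0)
      config_error(field, "must be a (mean, sd) pair with sd > 0")
  }
  chk_count(cfg$n_patients, "n_patients")
  if (!identical(as.integer(cfg$n_segments_per_patient), 16L))
    config_error("n_segments_per_patient", "must be 16 (AHA 16-segment model)")
  chk_prop(cfg$expected_abnormal_fraction, "expected_abnormal_fraction")
  chk_prop(cfg$infarct_fraction_of_abnormal, "infarct_fraction_of_abnormal")
  chk_prop(cfg$patient_disease_prob, "patient_disease_prob")
  chk_prop(cfg$balanced_transmural_prob, "balanced_transmural_prob")
  chk_prop(cfg$attenuation_pe_coupling, "attenuation_pe_coupling")
  for (f in c("mpr_quartiles_normal", "mpr_quartiles_abnormal",
              "endo_attn_quartiles_normal", "endo_attn_quartiles_abnormal"))
    chk_quartiles(cfg[[f]], f)
  for (f in c("aortic_pe_timing_mean_sd", "aortic_pe_dynamic_mean_sd",
              "hr_rest_mean_sd", "hr_stress_mean_sd", "epi_gradient_mean_sd"))
    chk_mean_sd(cfg[[f]], f)
  if (cfg$pe_correlation_target <= 0 || cfg$pe_correlation_target >= 1)
    config_error("pe_correlation_target", "must lie in (0, 1)")
  if (cfg$contrast_dilution <= 0 || cfg$contrast_dilution > 1)
    config_error("contrast_dilution", "must lie in (0, 1]")
  if (cfg$expected_abnormal_fraction > 0) {
    if (cfg$patient_disease_prob <= 0)
      config_error("patient_disease_prob",
                   "must be positive when abnormal segments are expected")
    q <- defect_growth_prob(cfg)
    if (q < 0 || q > 1)
      config_error("expected_abnormal_fraction",
                   "unreachable with this patient_disease_prob (mean extent outside 1..16)")
  }
  geom <- cfg$image_geometry
  for (f in c("matrix_size", "n_slices", "slice_thickness_mm",
              "endo_radius", "epi_radius"))
    if (is.null(geom[[f]]) || !is.numeric(geom[[f]]) || geom[[f]] <= 0)
      config_error(paste0("image_geometry$", f), "must be a positive number")
  if (geom$epi_radius <= geom$endo_radius)
    config_error("image_geometry$epi_radius",
                 "epicardial radius must exceed endocardial radius")
  if (geom$n_slices %% 3 != 0)
    config_error("image_geometry$n_slices",
                 "must be a multiple of 3 (basal/mid/apical thirds)")
  if (cfg$noise_sd < 0) config_error("noise_sd", "must be nonnegative")
  if (cfg$n_dynamic_frames < 3)
    config_error("n_dynamic_frames", "must be at least 3")
  if (cfg$timing_frames < 3) config_error("timing_frames", "must be at least 3")
  if (!is.finite(cfg$master_seed))
    config_error("master_seed", "must be a finite integer")
  structure(cfg, class = "ctp_config")
}

# binomial growth probability for defect extent: extent ~ 1 + Binom(15, q) for
# diseased patients, so that p_dis * (1 + 15 q) = 16 * expected fraction
defect_growth_prob <- function(cfg) {
  (16 * cfg$expected_abnormal_fraction / cfg$patient_disease_prob - 1) / 15
}

#' Read a cohort configuration from a YAML or JSON file
#'
#' Any subset of [cohort_config()] arguments may be given in the file;
#' unspecified fields keep their calibrated defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `ctp_config`.
#' @export
read_cohort_config <- function(path) {
  if (!file.exists(path))
    abort(paste0("config file not found: ", path), class = "ctperf_config_error")
  vals <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  unknown <- setdiff(names(vals), names(formals(cohort_config)))
  if (length(unknown) > 0)
    config_error(unknown[1], "not a recognised configuration field")
  do.call(cohort_config, vals)
}

#' @export
print.ctp_config <- function(x, ...) {
  cat("<ctp_config>\n")
  cat(sprintf("  patients: %d x %d segments (expected abnormal fraction %.3f)\n",
              x$n_patients, x$n_segments_per_patient,
              x$expected_abnormal_fraction))
  cat(sprintf("  aortic PE: timing %.1f (%.1f) HU, dynamic %.1f (%.1f) HU, r target %.2f\n",
              x$aortic_pe_timing_mean_sd[1], x$aortic_pe_timing_mean_sd[2],
              x$aortic_pe_dynamic_mean_sd[1], x$aortic_pe_dynamic_mean_sd[2],
              x$pe_correlation_target))
  cat(sprintf("  MPR quartiles: normal %s / abnormal %s\n",
              paste(x$mpr_quartiles_normal, collapse = "/"),
              paste(x$mpr_quartiles_abnormal, collapse = "/")))
  cat(sprintf("  geometry: %dx%d, %d slices @ %g mm, radii %g-%g vox, noise %g HU\n",
              x$image_geometry$matrix_size, x$image_geometry$matrix_size,
              x$image_geometry$n_slices, x$image_geometry$slice_thickness_mm,
              x$image_geometry$endo_radius, x$image_geometry$epi_radius,
              x$noise_sd))
  cat(sprintf("  master seed: %d\n", x$master_seed))
  invisible(x)
}

# deterministic substream seed below 2^31 derived from master seed,
# patient index and a stage label
substream_seed <- function(master_seed, patient = 0L, stage = "cohort") {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  s <- (as.double(master_seed) * 48271 + as.double(patient) * 7919 + h * 104729)
  as.integer(s %% 2147483629)
}
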