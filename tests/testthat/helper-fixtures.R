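# small, fast geometry for image-level tests
small_config <- function(n_patients = 2, noise_sd = 0, master_seed = 101, ...) {
  cohort_config(
    n_patients = n_patients,
    noise_sd = noise_sd,
    master_seed = master_seed,
    image_geometry = list(matrix_size = 48, n_slices = 6,
                          slice_thickness_mm = 5,
                          endo_radius = 8, epi_radius = 14),
    ...
  )
}

# hand-built phantom with prescribed per-segment layer values, for
# render-then-measure round trips
fake_patient <- function(endo_baseline = rep(50, 16),
                         endo_enh = rep(80, 16),
                         epi_baseline = rep(50, 16),
                         epi_enh = rep(80, 16),
                         groove_angle = 0, hr_stress = 80,
                         pe_dynamic_true = 390, patient_index = 1L) {
  list(
    patient_id = "FAKE",
    patient_index = patient_index,
    pe_timing_true = 80,
    pe_dynamic_true = pe_dynamic_true,
    hr_stress = hr_stress,
    hr_rest = 65,
    groove_angle = groove_angle,
    segments = tibble::tibble(
      segment_id = 1:16,
      endo_baseline_hu = endo_baseline,
      endo_enh_true = endo_enh,
      epi_baseline_hu = epi_baseline,
      epi_enh_true = epi_enh
    )
  )
}

# frame at which the myocardial bolus shape attains its grid maximum
myo_peak_frame <- function(patient, config) {
  rr <- 60 / patient$hr_stress
  times <- (seq_len(config$n_dynamic_frames) - 1) * rr
  which.max(ctperf:::myocardial_shape(times, config$kinetics))
}

# exhaustive pairwise AUC oracle (wins + half-ties over all pos x neg pairs)
auc_brute <- function(scores, labels, direction = "lower_is_abnormal") {
  x <- if (direction == "lower_is_abnormal") -scores else scores
  pos <- x[as.logical(labels)]
  neg <- x[!as.logical(labels)]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# exhaustive Youden scan over candidate thresholds (lower_is_abnormal)
youden_brute <- function(scores, labels) {
  labels <- as.logical(labels)
  u <- sort(unique(scores))
  cand <- c(-Inf, if (length(u) > 1) (head(u, -1) + tail(u, -1)) / 2, Inf)
  best <- -Inf
  for (c in cand) {
    sens <- mean(scores[labels] < c)
    spec <- mean(scores[!labels] >= c)
    best <- max(best, sens + spec - 1)
  }
  best
}

# all-pairs Mann-Whitney U oracle for group_a
u_brute <- function(a, b) {
  total <- 0
  for (x in a) for (y in b) total <- total + (x > y) + 0.5 * (x == y)
  total
}

# truth-level parameter table of a cohort (no imaging), for replicate studies
truth_parameters <- function(cohort) {
  segment_truth(cohort) |>
    dplyr::group_by(patient_id) |>
    dplyr::mutate(tpr = endo_attn_true / mean(epi_attn_true)) |>
    dplyr::ungroup() |>
    dplyr::transmute(patient_id, segment_id, abnormal,
                     mpr = mpr_true, endo_hu = endo_attn_true, tpr)
}
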