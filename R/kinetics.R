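# first-pass gamma-variate bolus shape, zero before arrival time t0
gamma_variate <- function(t, t0, alpha, beta) {
  dt <- pmax(t - t0, 0)
  ifelse(dt > 0, dt^alpha * exp(-dt / beta), 0)
}

# bolus shape normalised to a maximum of 1 on the sampled frame grid, so a
# noise-free curve attains its configured peak enhancement exactly at the
# grid argmax
grid_bolus_shape <- function(times, t0, alpha, beta) {
  h <- gamma_variate(times, t0, alpha, beta)
  m <- max(h)
  if (m > 0) h / m else h
}

# myocardial copy of the aortic bolus: delayed and dispersed
myocardial_shape <- function(times, kin) {
  grid_bolus_shape(times, kin$t0 + kin$delay, kin$alpha,
                   kin$beta + kin$dispersion)
}

# ROI-mean noise is image noise shrunk by ROI averaging
tac_noise_sd <- function(cfg) cfg$noise_sd / 5

#' Simulate the timing-bolus aortic scan of a phantom patient
#'
#' Produces the aortic time-attenuation curve of a low-dose test injection
#' of contrast diluted to `contrast_dilution` (default a 20 percent
#' solution), sampled at the ascending aorta. The curve is a baseline
#' plateau plus a gamma-variate bolus whose full-strength amplitude is set
#' by the patient's true aortic enhancement (itself scaled by the shared
#' cardiac-output factor), multiplied by the dilution, plus ROI noise.
#'
#' @param patient A phantom from [generate_cohort()]`$patients`.
#' @param config The cohort's [cohort_config()].
#' @param amplitude_scale Multiplier on the bolus amplitude (0 gives a flat
#'   pre-contrast curve).
#' @return A `ctp_tac` tibble (`frame`, `frame_time_s`, `value_hu`,
#'   `roi_label = "aorta"`).
#' @export
simulate_timing_bolus <- function(patient, config, amplitude_scale = 1) {
  times <- (seq_len(config$timing_frames) - 1) * config$timing_frame_interval_s
  kin <- config$kinetics
  shape <- grid_bolus_shape(times, kin$t0, kin$alpha, kin$beta)
  amplitude_full <- patient$pe_timing_true / config$contrast_dilution
  peak_enh <- config$contrast_dilution * amplitude_full * amplitude_scale
  noise <- withr::with_seed(
    substream_seed(config$master_seed, patient$patient_index, "timing"),
    rnorm(length(times), 0, tac_noise_sd(config)))
  new_tac(times, config$aortic_baseline_hu + peak_enh * shape + noise, "aorta")
}

#' Simulate the stress dynamic perfusion series of a phantom patient
#'
#' One acquisition per cardiac cycle under stress (frame spacing = the
#' stress RR interval), with a full-strength aortic bolus and per-segment
#' endocardial and epicardial myocardial curves that lag and disperse the
#' aortic input. The first frame is pre-contrast.
#'
#' @inheritParams simulate_timing_bolus
#' @return A `ctp_series`: list with `aorta` (a `ctp_tac`), `myocardium`
#'   (long tibble: `frame`, `frame_time_s`, `segment_id`, `layer`,
#'   `value_hu`), `frame_times`, and `patient_id`.
#' @export
simulate_dynamic_series <- function(patient, config, amplitude_scale = 1) {
  rr <- 60 / patient$hr_stress
  times <- (seq_len(config$n_dynamic_frames) - 1) * rr
  kin <- config$kinetics
  a_shape <- grid_bolus_shape(times, kin$t0, kin$alpha, kin$beta)
  m_shape <- myocardial_shape(times, kin)
  seed <- substream_seed(config$master_seed, patient$patient_index, "dynamic")
  nf <- length(times)
  withr::with_seed(seed, {
    aorta <- new_tac(
      times,
      config$aortic_baseline_hu +
        patient$pe_dynamic_true * amplitude_scale * a_shape +
        rnorm(nf, 0, tac_noise_sd(config)),
      "aorta")
    segs <- patient$segments
    myo <- tidyr::expand_grid(segment_id = segs$segment_id,
                              layer = c("endo", "epi")) |>
      mutate(rows = purrr::map2(.data$segment_id, .data$layer, function(s, l) {
        base <- if (l == "endo") segs$endo_baseline_hu[s] else segs$epi_baseline_hu[s]
        enh <- if (l == "endo") segs$endo_enh_true[s] else segs$epi_enh_true[s]
        tibble(frame = seq_len(nf), frame_time_s = times,
               value_hu = base + enh * amplitude_scale * m_shape +
                 rnorm(nf, 0, tac_noise_sd(config)))
      })) |>
      tidyr::unnest("rows") |>
      select("frame", "frame_time_s", "segment_id", "layer", "value_hu")
  })
  structure(list(aorta = aorta, myocardium = myo, frame_times = times,
                 patient_id = patient$patient_id),
            class = "ctp_series")
}

#' Mean myocardial curve of a dynamic series
#'
#' Averages the endocardial-layer curves of all 16 segments frame by frame;
#' this is the curve used to pick the static phase.
#'
#' @param series A `ctp_series`.
#' @return A `ctp_tac` with `roi_label = "myocardium"`.
#' @export
myocardial_mean_tac <- function(series) {
  stopifnot(inherits(series, "ctp_series"))
  m <- series$myocardium |>
    filter(.data$layer == "endo") |>
    group_by(.data$frame, .data$frame_time_s) |>
    summarise(value_hu = mean(.data$value_hu), .groups = "drop") |>
    arrange(.data$frame)
  new_tac(m$frame_time_s, m$value_hu, "myocardium")
}

#' @export
print.ctp_series <- function(x, ...) {
  cat(sprintf("<ctp_series> %s: %d frames over %.1f s, 16 segments x 2 layers\n",
              x$patient_id, length(x$frame_times), max(x$frame_times)))
  invisible(x)
}
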