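#' Run the full synthetic static-CTP analysis pipeline
#'
#' Orchestrates generate -> simulate -> render -> measure -> parameterise ->
#' evaluate: draws a seeded phantom cohort, simulates each patient's
#' timing-bolus and dynamic scans, selects the static phase, renders the
#' pre-contrast and static short-axis stacks, measures the 16 AHA segments
#' in endocardial/epicardial layers, computes MPR/TPR/attenuation, emulates
#' a second reader, and evaluates diagnostic accuracy against the SPECT-like
#' segment truth. With `skip_render = TRUE` the per-segment measurements are
#' taken directly from the phantom truth values (the noise-free fast path;
#' identical to the rendered path when `noise_sd = 0`).
#'
#' @param config A [cohort_config()], or a path to a YAML/JSON config file.
#' @param output_dir Directory for artifacts (created if needed); `NULL`
#'   writes nothing.
#' @param seed Optional override of the config's master seed.
#' @param skip_render Skip image rendering and measure truth directly.
#' @param write_images Also write per-patient NIfTI stacks and segment maps
#'   (only meaningful when rendering).
#' @param cutoffs Optional named list (`mpr`, `tpr`, `endo_hu`) of fixed
#'   cutoffs; by default Youden-derived cutoffs from this cohort are used.
#' @return A `ctp_run`: list with `manifest`, `cohort`, `segments` (the
#'   per-segment parameter table), `patients`, and `report`.
#' @export
run_pipeline <- function(config = cohort_config(), output_dir = NULL,
                         seed = NULL, skip_render = FALSE,
                         write_images = FALSE, cutoffs = NULL) {
  if (is.character(config)) config <- read_cohort_config(config)
  if (!inherits(config, "ctp_config")) config <- validate_config(config)
  if (!is.null(seed)) {
    config$master_seed <- as.integer(seed)
    config <- validate_config(unclass(config))
  }
  t_start <- Sys.time()
  stage <- function(what, pid, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("pipeline stage `%s` failed for %s: %s",
                    what, pid, conditionMessage(e)),
            class = "ctperf_pipeline_error", parent = e)
    })
  }

  cohort <- stage("generate", "cohort", generate_cohort(config))
  if (!is.null(output_dir) &&
      !dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)

  per_patient <- lapply(cohort$patients, function(p) {
    tac <- stage("timing_bolus", p$patient_id,
                 simulate_timing_bolus(p, config))
    pe_timing <- compute_peak_enhancement(tac, n_baseline_frames = 2)$pe
    if (skip_render) {
      meas <- tibble(segment_id = p$segments$segment_id,
                     endo_hu = p$segments$endo_attn_true,
                     epi_hu = p$segments$epi_attn_true,
                     endo_enh_hu = p$segments$endo_enh_true,
                     n_endo = NA_integer_, n_epi = NA_integer_,
                     static_frame = NA_integer_)
    } else {
      series <- stage("dynamic_series", p$patient_id,
                      simulate_dynamic_series(p, config))
      frame <- stage("phase_selection", p$patient_id,
                     select_static_phase(series$aorta,
                                         myocardial_mean_tac(series)))
      baseline <- stage("render", p$patient_id,
                        render_short_axis_stack(p, 1L, config))
      static <- stage("render", p$patient_id,
                      render_short_axis_stack(p, frame, config))
      segmap <- stage("segment_map", p$patient_id,
                      build_segment_map(static))
      layers <- stage("layer_split", p$patient_id, split_layers(static))
      meas <- stage("measure", p$patient_id,
                    measure_segments(static, baseline, segmap, layers))
      meas$static_frame <- frame
      if (!is.null(output_dir) && write_images) {
        write_stack_nifti(static, file.path(
          output_dir, paste0(p$patient_id, "_static.nii.gz")))
        write_stack_nifti(baseline, file.path(
          output_dir, paste0(p$patient_id, "_baseline.nii.gz")))
        write_segment_map_nifti(segmap, file.path(
          output_dir, paste0(p$patient_id, "_segments.nii.gz")),
          config$image_geometry$slice_thickness_mm)
      }
    }
    mutate(meas, patient_id = p$patient_id, aortic_pe_timing = pe_timing,
           .before = 1)
  })

  segments <- bind_rows(per_patient) |>
    add_parameters() |>
    left_join(select(segment_truth(cohort), "patient_id", "segment_id",
                     "perfusion_class", "stress_score", "rest_score",
                     "abnormal"),
              by = c("patient_id", "segment_id"))

  # second-reader emulation: independent measurement noise on each parameter
  segments <- withr::with_seed(
    substream_seed(config$master_seed, 0L, "observer"), {
      n <- nrow(segments)
      mutate(segments,
             endo_hu_obs = .data$endo_hu +
               rnorm(n, 0, config$observer_sd$endo_hu),
             mpr_obs = .data$mpr + rnorm(n, 0, config$observer_sd$mpr),
             tpr_obs = .data$tpr + rnorm(n, 0, config$observer_sd$tpr))
    })

  # cohort-derived Youden cutoffs need both classes; degenerate cohorts fall
  # back to the published cutoffs (MPR 0.81, TPR 0.92, attenuation 106 HU)
  both_classes <- any(segments$abnormal) && !all(segments$abnormal)
  report <- if (both_classes) {
    stage("evaluate", "cohort", diagnostic_report(segments))
  }
  if (is.null(cutoffs)) {
    cutoffs <- if (both_classes) {
      list(mpr = report$parameters$mpr$cutoff,
           tpr = report$parameters$tpr$cutoff,
           endo_hu = report$parameters$attenuation$cutoff)
    } else {
      list(mpr = 0.81, tpr = 0.92, endo_hu = 106)
    }
  }
  segments <- classify_parameters(segments, cutoffs)

  patients <- patient_table(cohort) |>
    left_join(segments |> group_by(.data$patient_id) |>
                summarise(aortic_pe_timing = .data$aortic_pe_timing[1]),
              by = "patient_id")
  hr_test <- paired_t_test(patients$hr_stress, patients$hr_rest)

  manifest <- list(
    package_version = as.character(utils::packageVersion("ctperf")),
    master_seed = config$master_seed,
    skip_render = skip_render,
    config = unclass(config),
    n_patients = length(cohort$patients),
    n_segments = nrow(segments),
    hr_paired_t = as.data.frame(hr_test),
    elapsed_s = as.numeric(difftime(Sys.time(), t_start, units = "secs")),
    outputs = character(0)
  )

  if (!is.null(output_dir)) {
    paths <- c(segments = file.path(output_dir, "segments.csv"),
               patients = file.path(output_dir, "patients.csv"),
               report = file.path(output_dir, "report.json"),
               accuracy = file.path(output_dir, "accuracy_table.csv"))
    write.csv(segments, paths["segments"], row.names = FALSE)
    write.csv(patients, paths["patients"], row.names = FALSE)
    if (!is.null(report)) {
      jsonlite::write_json(report_to_list(report), paths["report"],
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      write.csv(tidy(report), paths["accuracy"], row.names = FALSE)
    } else {
      paths <- paths[c("segments", "patients")]
    }
    manifest$outputs <- as.list(paths)
    manifest$checksums <- as.list(tools::md5sum(unname(unlist(paths))))
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  structure(list(manifest = manifest, cohort = cohort, segments = segments,
                 patients = patients, report = report),
            class = "ctp_run")
}

#' @export
print.ctp_run <- function(x, ...) {
  cat(sprintf("<ctp_run> %d patients, %d segments (seed %d, %s)\n",
              x$manifest$n_patients, x$manifest$n_segments,
              x$manifest$master_seed,
              if (x$manifest$skip_render) "truth fast path" else "rendered"))
  if (!is.null(x$report)) print(x$report)
  invisible(x)
}

#' Recompute a published diagnostic-accuracy table from its printed cells
#'
#' Reconstructs each parameter's confusion matrix from the printed
#' sensitivity/specificity percentages and the segment totals, then
#' recomputes all four metrics with Wilson intervals. The default printed
#' values ship with the package (`table2_printed.csv`): segment-level
#' accuracy of MPR, TPR, endocardial attenuation and visual assessment
#' against 63 abnormal / 337 normal segments.
#'
#' @param printed Data frame with columns `parameter`, `sens_pct`,
#'   `spec_pct`; default reads the shipped fixture.
#' @param n_pos,n_neg Reference-positive and -negative totals.
#' @param level Confidence level.
#' @return A tibble, one row per parameter: reconstructed counts, each
#'   metric as a rounded integer percentage with rounded CI bounds.
#' @examples
#' reproduce_table2()
#' @export
reproduce_table2 <- function(printed = NULL, n_pos = 63, n_neg = 337,
                             level = 0.95) {
  if (is.null(printed))
    printed <- read.csv(system.file("extdata", "table2_printed.csv",
                                    package = "ctperf"))
  round_half_up <- function(x) floor(x + 0.5)
  bind_rows(lapply(seq_len(nrow(printed)), function(i) {
    cm <- reconstruct_confusion(printed$sens_pct[i], printed$spec_pct[i],
                                n_pos, n_neg)
    m <- confusion_metrics(cm, level = level)
    row <- tibble(parameter = printed$parameter[i],
                  tp = cm$tp, fp = cm$fp, fn = cm$fn, tn = cm$tn)
    for (j in seq_len(nrow(m))) {
      nm <- m$metric[j]
      row[[paste0(nm, "_pct")]] <- round_half_up(100 * m$estimate[j])
      row[[paste0(nm, "_low")]] <- round_half_up(100 * m$lower[j])
      row[[paste0(nm, "_high")]] <- round_half_up(100 * m$upper[j])
    }
    row
  }))
}
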