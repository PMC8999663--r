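# per-slice polar coordinate grids for an annular LV wall phantom
slice_polar_grid <- function(matrix_size) {
  centre <- (matrix_size + 1) / 2
  x <- matrix(rep(seq_len(matrix_size), each = matrix_size) - centre,
              nrow = matrix_size)
  y <- matrix(rep(seq_len(matrix_size), times = matrix_size) - centre,
              nrow = matrix_size)
  list(r = sqrt(x^2 + y^2), theta = atan2(y, x) %% (2 * pi), centre = centre)
}

slice_levels <- function(n_slices) {
  rep(c("basal", "mid", "apical"), each = n_slices / 3)
}

new_stack <- function(voxels, wall_mask, lv_center, slice_thickness_mm,
                      levels, groove_angle, geometry) {
  structure(list(voxels = voxels, wall_mask = wall_mask,
                 lv_center = lv_center,
                 slice_thickness_mm = slice_thickness_mm,
                 levels = levels, groove_angle = groove_angle,
                 geometry = geometry),
            class = "ctp_stack")
}

#' Render a short-axis image stack of a phantom patient at one frame
#'
#' Builds the short-axis left-ventricular volume at a given frame of the
#' dynamic series: an annular myocardial wall per slice whose voxels carry
#' that segment's layer attenuation at the frame (baseline plus enhancement
#' scaled by the myocardial bolus shape), an LV cavity carrying the aortic
#' blood-pool curve, and additive Gaussian HU noise. Frame 1 is
#' pre-contrast.
#'
#' @inheritParams simulate_timing_bolus
#' @param frame_index Frame of the dynamic series (1-based).
#' @return A `ctp_stack`: HU voxel array `(row, col, slice)`, wall mask,
#'   per-slice LV centre, slice thickness (mm), per-slice level labels, the
#'   phantom's anterior-groove angle, and the geometry used.
#' @export
render_short_axis_stack <- function(patient, frame_index, config) {
  geom <- config$image_geometry
  if (geom$endo_radius <= 0 || geom$epi_radius <= geom$endo_radius)
    abort("invalid geometry: radii must be positive with epi > endo",
          class = "ctperf_geometry_error")
  nf <- config$n_dynamic_frames
  if (frame_index < 1 || frame_index > nf)
    abort(sprintf("frame_index %d outside the dynamic series (1..%d)",
                  frame_index, nf),
          class = "ctperf_input_error")
  rr <- 60 / patient$hr_stress
  times <- (seq_len(nf) - 1) * rr
  kin <- config$kinetics
  h_myo <- myocardial_shape(times, kin)[frame_index]
  h_ao <- grid_bolus_shape(times, kin$t0, kin$alpha, kin$beta)[frame_index]
  cavity_hu <- config$aortic_baseline_hu + patient$pe_dynamic_true * h_ao

  n <- geom$matrix_size
  ns <- geom$n_slices
  grid <- slice_polar_grid(n)
  wall2d <- grid$r >= geom$endo_radius & grid$r < geom$epi_radius
  cavity2d <- grid$r < geom$endo_radius
  mid_r <- (geom$endo_radius + geom$epi_radius) / 2
  endo2d <- wall2d & grid$r < mid_r
  phi <- (grid$theta - patient$groove_angle) %% (2 * pi)

  levels <- slice_levels(ns)
  segs <- patient$segments
  voxels <- array(0, dim = c(n, n, ns))
  wall_mask <- array(FALSE, dim = c(n, n, ns))
  seed <- substream_seed(config$master_seed, patient$patient_index,
                         paste0("render", frame_index))
  noise <- withr::with_seed(seed, rnorm(n * n * ns, 0, config$noise_sd))
  dim(noise) <- c(n, n, ns)
  seg_tbl <- aha_segments()
  for (s in seq_len(ns)) {
    nsec <- if (levels[s] == "apical") 4L else 6L
    sector <- pmin(floor(phi / (2 * pi / nsec)) + 1L, nsec)
    offset <- c(basal = 0L, mid = 6L, apical = 12L)[[levels[s]]]
    seg_id <- sector + offset
    sl <- matrix(0, n, n)
    sl[cavity2d] <- cavity_hu
    endo_val <- segs$endo_baseline_hu + segs$endo_enh_true * h_myo
    epi_val <- segs$epi_baseline_hu + segs$epi_enh_true * h_myo
    vals <- ifelse(endo2d, endo_val[seg_id], epi_val[seg_id])
    sl[wall2d] <- vals[wall2d]
    voxels[, , s] <- sl + noise[, , s]
    wall_mask[, , s] <- wall2d
  }
  new_stack(voxels, wall_mask,
            lv_center = matrix(grid$centre, nrow = ns, ncol = 2),
            slice_thickness_mm = geom$slice_thickness_mm,
            levels = levels, groove_angle = patient$groove_angle,
            geometry = geom)
}

#' @export
print.ctp_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("<ctp_stack> %dx%d x %d slices @ %g mm (%d wall voxels)\n",
              d[1], d[2], d[3], x$slice_thickness_mm, sum(x$wall_mask)))
  invisible(x)
}

#' Write / read a short-axis stack as NIfTI
#'
#' The HU volume is written as `.nii.gz` with in-plane voxel size 1 mm and
#' the slice thickness in the third pixdim; the wall mask, centre, level
#' labels and groove angle travel in a sidecar JSON next to the image.
#'
#' @param stack A `ctp_stack`.
#' @param path Output path ending in `.nii` or `.nii.gz`.
#' @return `write_stack_nifti` returns `path` invisibly; `read_stack_nifti`
#'   returns a `ctp_stack`.
#' @export
write_stack_nifti <- function(stack, path) {
  img <- RNifti::asNifti(stack$voxels)
  RNifti::pixdim(img) <- c(1, 1, stack$slice_thickness_mm)
  RNifti::writeNifti(img, path)
  side <- sub("\\.nii(\\.gz)?$", ".json", path)
  jsonlite::write_json(
    list(levels = stack$levels,
         groove_angle = stack$groove_angle,
         lv_center = stack$lv_center,
         geometry = stack$geometry),
    side, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_nifti
#' @export
read_stack_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  side <- jsonlite::read_json(sub("\\.nii(\\.gz)?$", ".json", path),
                              simplifyVector = TRUE)
  vox <- array(as.numeric(img), dim = dim(img))
  geom <- as.list(side$geometry)
  grid <- slice_polar_grid(geom$matrix_size)
  wall2d <- grid$r >= geom$endo_radius & grid$r < geom$epi_radius
  wall <- array(wall2d, dim = dim(vox))
  new_stack(vox, wall, lv_center = matrix(side$lv_center, ncol = 2),
            slice_thickness_mm = RNifti::pixdim(img)[3],
            levels = side$levels, groove_angle = side$groove_angle,
            geometry = geom)
}

#' @describeIn render_short_axis_stack Raster plot of selected slices.
#' @param object,... For `autoplot`, a `ctp_stack`, then optionally
#'   `slices` (indices to show).
#' @param slices Slice indices to display.
#' @export
autoplot.ctp_stack <- function(object, slices = NULL, ...) {
  d <- dim(object$voxels)
  slices <- slices %||% unique(round(seq(1, d[3], length.out = 4)))
  df <- bind_rows(lapply(slices, function(s) {
    tibble(row = rep(seq_len(d[1]), times = d[2]),
           col = rep(seq_len(d[2]), each = d[1]),
           hu = as.vector(object$voxels[, , s]),
           slice = paste0("slice ", s, " (", object$levels[s], ")"))
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row, fill = .data$hu)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::facet_wrap(~slice) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "HU") +
    ggplot2::theme_minimal()
}
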