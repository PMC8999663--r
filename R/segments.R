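#' Map short-axis wall voxels to the AHA 16-segment model
#'
#' Bins each slice's wall voxels by polar angle about the LV centre into 6
#' equal sectors (basal and mid levels) or 4 (apical), measured
#' counterclockwise from the stack's anterior-groove angle. The nonzero
#' labels partition the wall mask: every wall voxel receives exactly one
#' segment, basal slices only labels 1-6, mid 7-12, apical 13-16.
#'
#' @param stack A `ctp_stack`.
#' @return A `ctp_segment_map`: integer label array (0 = background) plus
#'   the level labels.
#' @export
build_segment_map <- function(stack) {
  stopifnot(inherits(stack, "ctp_stack"))
  d <- dim(stack$voxels)
  labels <- array(0L, dim = d)
  for (s in seq_len(d[3])) {
    wall <- stack$wall_mask[, , s]
    if (!any(wall))
      abort(sprintf("slice %d has an empty wall mask", s),
            class = "ctperf_geometry_error")
    cy <- stack$lv_center[s, 1]
    cx <- stack$lv_center[s, 2]
    x <- matrix(rep(seq_len(d[2]), each = d[1]) - cx, nrow = d[1])
    y <- matrix(rep(seq_len(d[1]), times = d[2]) - cy, nrow = d[1])
    theta <- atan2(y, x) %% (2 * pi)
    phi <- (theta - stack$groove_angle) %% (2 * pi)
    nsec <- if (stack$levels[s] == "apical") 4L else 6L
    offset <- c(basal = 0L, mid = 6L, apical = 12L)[[stack$levels[s]]]
    sector <- pmin(floor(phi / (2 * pi / nsec)) + 1L, nsec)
    lab <- matrix(0L, d[1], d[2])
    lab[wall] <- sector[wall] + offset
    labels[, , s] <- lab
  }
  structure(list(labels = labels, levels = stack$levels),
            class = "ctp_segment_map")
}

#' @export
print.ctp_segment_map <- function(x, ...) {
  ids <- sort(unique(x$labels[x$labels > 0]))
  cat(sprintf("<ctp_segment_map> %d labelled voxels, segments %s\n",
              sum(x$labels > 0), paste(range(ids), collapse = "-")))
  invisible(x)
}

#' Write a segment map as a NIfTI label volume
#'
#' @param map A `ctp_segment_map`.
#' @param path Output `.nii`/`.nii.gz` path.
#' @param slice_thickness_mm Slice thickness recorded in the header.
#' @export
write_segment_map_nifti <- function(map, path, slice_thickness_mm = 5) {
  img <- RNifti::asNifti(map$labels)
  RNifti::pixdim(img) <- c(1, 1, slice_thickness_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Split the myocardial wall into endocardial and epicardial layers
#'
#' Per slice, a wall voxel belongs to the endocardial layer when its
#' normalised transmural depth - its radial position between the
#' endocardial and epicardial borders - is below `endo_fraction`; the rest
#' of the wall is epicardial. The two masks partition the wall.
#'
#' @param stack A `ctp_stack`.
#' @param map A `ctp_segment_map` for the same stack (unused by the radial
#'   rule but kept in the signature so layer definitions that depend on the
#'   segment can drop in).
#' @param endo_fraction Transmural depth cut, in (0, 1); default 0.5.
#' @return A list with logical arrays `endo` and `epi`.
#' @export
split_layers <- function(stack, map = NULL, endo_fraction = 0.5) {
  stopifnot(inherits(stack, "ctp_stack"))
  if (endo_fraction <= 0 || endo_fraction >= 1)
    abort("endo_fraction must lie strictly between 0 and 1",
          class = "ctperf_input_error")
  d <- dim(stack$voxels)
  endo <- array(FALSE, dim = d)
  for (s in seq_len(d[3])) {
    wall <- stack$wall_mask[, , s]
    if (!any(wall))
      abort(sprintf("slice %d has an empty wall mask", s),
            class = "ctperf_geometry_error")
    cy <- stack$lv_center[s, 1]
    cx <- stack$lv_center[s, 2]
    x <- matrix(rep(seq_len(d[2]), each = d[1]) - cx, nrow = d[1])
    y <- matrix(rep(seq_len(d[1]), times = d[2]) - cy, nrow = d[1])
    r <- sqrt(x^2 + y^2)
    # prefer the stack's analytic annulus radii; fall back to the mask extent
    if (!is.null(stack$geometry)) {
      r_in <- stack$geometry$endo_radius
      r_out <- stack$geometry$epi_radius
    } else {
      r_in <- min(r[wall])
      r_out <- max(r[wall])
    }
    if (r_out - r_in < 1)
      abort(sprintf("slice %d wall is thinner than 2 voxels", s),
            class = "ctperf_geometry_error")
    depth <- (r - r_in) / (r_out - r_in)
    e <- matrix(FALSE, d[1], d[2])
    e[wall] <- depth[wall] < endo_fraction
    endo[, , s] <- e
  }
  list(endo = endo, epi = stack$wall_mask & !endo)
}

#' Per-segment layer measurements from a static and a baseline stack
#'
#' For each of the 16 segments, the endocardial and epicardial attenuation
#' are the mean HU over the segment's layer voxels in the static
#' (contrast-enhanced) stack; the endocardial enhancement subtracts the mean
#' over the same voxels in the pre-contrast baseline stack.
#'
#' @param static_stack,baseline_stack `ctp_stack`s sharing one geometry.
#' @param map A `ctp_segment_map` built on that geometry.
#' @param layers Layer masks from [split_layers()].
#' @return A tibble with one row per segment: `segment_id`, `endo_hu`,
#'   `epi_hu`, `endo_enh_hu`, `n_endo`, `n_epi`.
#' @export
measure_segments <- function(static_stack, baseline_stack, map, layers) {
  stopifnot(inherits(static_stack, "ctp_stack"),
            inherits(baseline_stack, "ctp_stack"))
  if (!identical(dim(static_stack$voxels), dim(baseline_stack$voxels)) ||
      !identical(dim(static_stack$voxels), dim(map$labels)))
    abort("static stack, baseline stack and segment map must share geometry",
          class = "ctperf_input_error")
  sv <- static_stack$voxels
  bv <- baseline_stack$voxels
  lab <- map$labels
  out <- lapply(1:16, function(id) {
    me <- lab == id & layers$endo
    mp <- lab == id & layers$epi
    if (!any(me) || !any(mp))
      abort(sprintf("segment %d has no voxels in one of the layers", id),
            class = "ctperf_geometry_error")
    tibble(segment_id = id,
           endo_hu = mean(sv[me]),
           epi_hu = mean(sv[mp]),
           endo_enh_hu = mean(sv[me]) - mean(bv[me]),
           n_endo = sum(me),
           n_epi = sum(mp))
  })
  bind_rows(out)
}
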