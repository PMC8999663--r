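cfg <- small_config(noise_sd = 0)

test_that("segment map covers the wall with all 16 labels, by level", {
  stack <- render_short_axis_stack(fake_patient(), 1L, cfg)
  map <- build_segment_map(stack)
  expect_setequal(unique(map$labels[map$labels > 0]), 1:16)
  # labels partition the wall
  expect_true(all((map$labels > 0) == stack$wall_mask))
  lev <- slice_lab <- ctperf:::slice_levels(cfg$image_geometry$n_slices)
  for (s in seq_along(lev)) {
    ids <- unique(map$labels[, , s][map$labels[, , s] > 0])
    rng <- switch(lev[s], basal = 1:6, mid = 7:12, apical = 13:16)
    expect_true(all(ids %in% rng))
  }
})

test_that("a uniform annulus splits into near-equal basal sectors", {
  stack <- render_short_axis_stack(fake_patient(groove_angle = 0), 1L, cfg)
  map <- build_segment_map(stack)
  counts <- table(map$labels[, , 1][map$labels[, , 1] > 0])
  expect_equal(length(counts), 6)
  expect_lte(diff(range(counts)), 4)  # discretisation only
})

test_that("rotating the phantom by 60 degrees permutes basal labels cyclically", {
  s0 <- render_short_axis_stack(fake_patient(groove_angle = 0.3), 1L, cfg)
  s1 <- render_short_axis_stack(fake_patient(groove_angle = 0.3 + pi / 3),
                                1L, cfg)
  m0 <- build_segment_map(s0)$labels[, , 1]
  m1 <- build_segment_map(s1)$labels[, , 1]
  # voxel counts are preserved as a multiset and every voxel's label shifts
  # back by exactly one sector
  expect_equal(sort(as.integer(table(m0[m0 > 0]))),
               sort(as.integer(table(m1[m1 > 0]))))
  w <- m0 > 0
  expect_true(all(m1[w] == (m0[w] - 2) %% 6 + 1))
})

test_that("layer split partitions the wall at the transmural midpoint", {
  stack <- render_short_axis_stack(fake_patient(), 1L, cfg)
  layers <- split_layers(stack, endo_fraction = 0.5)
  expect_true(all((layers$endo | layers$epi) == stack$wall_mask))
  expect_false(any(layers$endo & layers$epi))
  # radial rule: endo voxels are closer to the cavity
  d <- dim(stack$voxels)
  cy <- stack$lv_center[1, 1]
  cx <- stack$lv_center[1, 2]
  x <- matrix(rep(seq_len(d[2]), each = d[1]) - cx, nrow = d[1])
  y <- matrix(rep(seq_len(d[1]), times = d[2]) - cy, nrow = d[1])
  r <- sqrt(x^2 + y^2)
  expect_lt(max(r[layers$endo[, , 1]]), min(r[layers$epi[, , 1]]) + 1e-9)
  expect_error(split_layers(stack, endo_fraction = 1.2),
               class = "ctperf_input_error")
})

test_that("render-then-measure recovers prescribed layer values exactly", {
  enh <- rep(80, 16)
  enh[4] <- 40
  pat <- fake_patient(endo_enh = enh, epi_enh = enh)
  frame <- myo_peak_frame(pat, cfg)
  static <- render_short_axis_stack(pat, frame, cfg)
  baseline <- render_short_axis_stack(pat, 1L, cfg)
  map <- build_segment_map(static)
  layers <- split_layers(static)
  rec <- measure_segments(static, baseline, map, layers)
  expect_equal(rec$endo_enh_hu[rec$segment_id == 4], 40)
  expect_equal(rec$endo_enh_hu[rec$segment_id != 4], rep(80, 15))
  expect_equal(rec$endo_hu, 50 + enh)
  expect_true(all(rec$n_endo > 0 & rec$n_epi > 0))
  # static = baseline implies zero enhancement everywhere
  same <- measure_segments(baseline, baseline, map, layers)
  expect_true(all(same$endo_enh_hu == 0))
})

test_that("segment means equal an independent voxel-loop oracle", {
  cfgN <- small_config(noise_sd = 10, master_seed = 55)
  pat <- generate_cohort(cfgN)$patients[[1]]
  static <- render_short_axis_stack(pat, 20L, cfgN)
  baseline <- render_short_axis_stack(pat, 1L, cfgN)
  map <- build_segment_map(static)
  layers <- split_layers(static)
  rec <- measure_segments(static, baseline, map, layers)
  for (id in c(1, 7, 13, 16)) {
    acc <- c()
    d <- dim(static$voxels)
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) for (s in seq_len(d[3]))
      if (map$labels[i, j, s] == id && layers$endo[i, j, s])
        acc <- c(acc, static$voxels[i, j, s])
    expect_equal(rec$endo_hu[rec$segment_id == id], mean(acc))
  }
})

test_that("measurement ignores background voxels", {
  pat <- fake_patient()
  frame <- myo_peak_frame(pat, cfg)
  static <- render_short_axis_stack(pat, frame, cfg)
  baseline <- render_short_axis_stack(pat, 1L, cfg)
  map <- build_segment_map(static)
  layers <- split_layers(static)
  ref <- measure_segments(static, baseline, map, layers)
  scrambled <- static
  withr::with_seed(3, {
    bg <- !scrambled$wall_mask
    scrambled$voxels[bg] <- rnorm(sum(bg), 500, 300)
  })
  expect_equal(measure_segments(scrambled, baseline, map, layers), ref)
})

test_that("geometry mismatches and empty masks raise geometry errors", {
  stack <- render_short_axis_stack(fake_patient(), 1L, cfg)
  broken <- stack
  broken$wall_mask[, , 2] <- FALSE
  expect_error(build_segment_map(broken), class = "ctperf_geometry_error")
  other <- render_short_axis_stack(fake_patient(), 1L, small_config(
    master_seed = 1))
  other$voxels <- other$voxels[1:24, 1:24, , drop = FALSE]
  map <- build_segment_map(stack)
  layers <- split_layers(stack)
  expect_error(measure_segments(other, stack, map, layers),
               class = "ctperf_input_error")
})

test_that("NIfTI round trip preserves the stack", {
  stack <- render_short_axis_stack(fake_patient(), 1L, cfg)
  path <- file.path(tempdir(), "stack_test.nii.gz")
  write_stack_nifti(stack, path)
  back <- read_stack_nifti(path)
  expect_equal(back$voxels, stack$voxels, tolerance = 1e-6)
  expect_equal(back$slice_thickness_mm, stack$slice_thickness_mm)
  expect_equal(back$levels, stack$levels)
  expect_equal(back$groove_angle, stack$groove_angle)
  expect_equal(measure_segments(back, back, build_segment_map(back),
                                split_layers(back)),
               measure_segments(stack, stack, build_segment_map(stack),
                                split_layers(stack)),
               tolerance = 1e-6)
  unlink(c(path, sub("\\.nii\\.gz$", ".json", path)))
})
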