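test_that("MPR is the enhancement-to-aortic-PE ratio", {
  expect_equal(compute_mpr(80.8, 80.8), 1.0)
  mpr <- compute_mpr(48.0, 80.0)
  expect_equal(mpr, 0.60)
  expect_true(classify_segment(mpr, cutoff = 0.81))
  # ratio invariance under joint scaling
  expect_equal(compute_mpr(48 * 3.7, 80 * 3.7), mpr)
  expect_error(compute_mpr(50, 0), class = "ctperf_degenerate_error")
  expect_error(compute_mpr(50, -5), class = "ctperf_degenerate_error")
})

test_that("TPR divides a segment's endocardium by the global epicardial mean", {
  expect_equal(compute_tpr(100, rep(100, 16)), 1.0)
  tpr <- compute_tpr(110.4, rep(115, 16))
  expect_equal(tpr, 0.96)
  # the balanced-transmural false negative: truly abnormal yet above cutoff
  expect_false(classify_segment(tpr, cutoff = 0.92))
  expect_equal(compute_tpr(110.4 * 2, rep(115 * 2, 16)), tpr)
  expect_error(compute_tpr(100, rep(100, 15)), class = "ctperf_input_error")
  expect_error(compute_tpr(100, rep(0, 16)),
               class = "ctperf_degenerate_error")
})

test_that("classification is strict-below with the boundary called normal", {
  expect_true(classify_segment(0.69, 0.81))
  expect_false(classify_segment(0.81, 0.81))
  expect_false(classify_segment(128, 106))
  expect_error(classify_segment(1, Inf), class = "ctperf_input_error")
})

test_that("ratio parameters are HU-scale invariant but attenuation is not", {
  coh <- generate_cohort(small_config(n_patients = 2, master_seed = 12))
  segs <- coh$patients[[1]]$segments
  pe <- coh$patients[[1]]$pe_timing_true
  c_scale <- 1.37
  mpr0 <- compute_mpr(segs$endo_enh_true, pe)
  tpr0 <- compute_tpr(segs$endo_attn_true, segs$epi_attn_true)
  expect_equal(compute_mpr(segs$endo_enh_true * c_scale, pe * c_scale), mpr0)
  expect_equal(compute_tpr(segs$endo_attn_true * c_scale,
                           segs$epi_attn_true * c_scale), tpr0)
  expect_false(isTRUE(all.equal(segs$endo_attn_true * c_scale,
                                segs$endo_attn_true)))
})

test_that("add_parameters computes per-patient MPR and TPR columns", {
  df <- tibble::tibble(
    patient_id = rep(c("A", "B"), each = 16),
    segment_id = rep(1:16, 2),
    endo_hu = rep(c(120, 100), each = 16),
    epi_hu = rep(c(120, 125), each = 16),
    endo_enh_hu = rep(c(80, 40), each = 16),
    aortic_pe_timing = rep(c(80, 80), each = 16))
  out <- add_parameters(df)
  expect_equal(out$mpr, rep(c(1.0, 0.5), each = 16))
  expect_equal(out$tpr, rep(c(1.0, 0.8), each = 16))
  called <- classify_parameters(out, list(mpr = 0.81, tpr = 0.92,
                                          endo_hu = 106))
  expect_equal(called$call_mpr, rep(c(FALSE, TRUE), each = 16))
  expect_error(add_parameters(df[, -3]), class = "ctperf_input_error")
})

test_that("abnormal segments sit below normal ones in MPR (Mann-Whitney)", {
  hits <- 0
  reps <- 20
  for (i in seq_len(reps)) {
    coh <- generate_cohort(cohort_config(n_patients = 25, master_seed = 400 + i))
    st <- segment_truth(coh)
    if (sum(st$abnormal) < 2) next
    p <- mann_whitney_u(st$mpr_true[st$abnormal],
                        st$mpr_true[!st$abnormal])$p.value
    hits <- hits + (p < 0.05)
  }
  expect_gte(hits / reps, 0.95)
})
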