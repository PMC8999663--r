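test_that("cohort has the right shape and is seed-deterministic", {
  coh <- generate_cohort(cohort_config(n_patients = 25, master_seed = 3))
  st <- segment_truth(coh)
  expect_equal(nrow(st), 400)
  expect_equal(length(coh$patients), 25)
  for (p in coh$patients)
    expect_equal(sort(p$segments$segment_id), 1:16)

  coh2 <- generate_cohort(cohort_config(n_patients = 25, master_seed = 3))
  expect_identical(segment_truth(coh2), st)
  expect_identical(patient_table(coh2), patient_table(coh))

  coh3 <- generate_cohort(cohort_config(n_patients = 25, master_seed = 4))
  expect_false(identical(segment_truth(coh3), st))
})

test_that("truth scores satisfy the perfusion-class invariants", {
  st <- segment_truth(generate_cohort(cohort_config(n_patients = 60,
                                                    master_seed = 8)))
  expect_true(all(st$abnormal == (st$stress_score >= 2)))
  isc <- st[st$perfusion_class == "ischemic", ]
  inf <- st[st$perfusion_class == "infarcted", ]
  nrm <- st[st$perfusion_class == "normal", ]
  expect_true(all(isc$stress_score >= 2 & isc$rest_score < 2))
  expect_true(all(inf$stress_score >= 2 & inf$rest_score >= 2))
  expect_true(all(nrm$stress_score < 2))
  expect_true(all(st$endo_enh_true >= 0))
  expect_true(all(st$stress_score %in% 0:4 & st$rest_score %in% 0:4))
})

test_that("assign_spect_scores maps classes onto the 5-point scale", {
  s <- assign_spect_scores(c("normal", "ischemic", "infarcted"),
                           c(0.1, 0.9, 0.5))
  expect_equal(s$abnormal, c(FALSE, TRUE, TRUE))
  expect_true(s$stress_score[1] < 2)
  expect_true(s$stress_score[2] >= 2 && s$rest_score[2] < 2)
  expect_true(s$stress_score[3] >= 2 && s$rest_score[3] >= 2)
  # severe ischaemia scores high under stress but resolves at rest
  sev <- assign_spect_scores("ischemic", 0.95)
  expect_equal(sev$stress_score, 4L)
  expect_lt(sev$rest_score, 2L)
  expect_error(assign_spect_scores("scarred", 0.5),
               class = "ctperf_input_error")
})

test_that("defects are contiguous in the 16-segment adjacency graph", {
  adj <- ctperf:::aha_adjacency()
  coh <- generate_cohort(cohort_config(n_patients = 40, master_seed = 21))
  for (p in coh$patients) {
    region <- p$segments$segment_id[p$segments$abnormal]
    if (length(region) < 2) next
    # breadth-first reachability within the region
    seen <- region[1]
    repeat {
      grow <- intersect(unique(unlist(adj[seen])), setdiff(region, seen))
      if (length(grow) == 0) break
      seen <- c(seen, grow)
    }
    expect_setequal(seen, region)
  }
})

test_that("abnormal prevalence and infarct share converge to configuration", {
  coh <- generate_cohort(cohort_config(n_patients = 500, master_seed = 13))
  st <- segment_truth(coh)
  expect_equal(mean(st$abnormal), 63 / 400, tolerance = 0.15)
  expect_equal(mean(st$perfusion_class[st$abnormal] == "infarcted"),
               49 / 63, tolerance = 0.15)
})

test_that("invalid configurations fail naming the offending field", {
  expect_error(cohort_config(n_segments_per_patient = 17),
               "n_segments_per_patient", class = "ctperf_config_error")
  expect_error(cohort_config(mpr_quartiles_abnormal = c(0.8, 0.7, 0.5)),
               "mpr_quartiles_abnormal", class = "ctperf_config_error")
  expect_error(cohort_config(expected_abnormal_fraction = 1.4),
               "expected_abnormal_fraction", class = "ctperf_config_error")
  expect_error(
    cohort_config(image_geometry = list(matrix_size = 64, n_slices = 6,
                                        slice_thickness_mm = 5,
                                        endo_radius = 12, epi_radius = 10)),
    "epi_radius", class = "ctperf_config_error")
  expect_error(cohort_config(noise_sd = -1), "noise_sd",
               class = "ctperf_config_error")
})

test_that("split-normal quantile function hits its quartiles and truncates", {
  q <- c(0.5, 0.7, 0.8)
  expect_equal(qsplitnorm(c(0.25, 0.5, 0.75), q), q)
  withr::with_seed(1, {
    x <- rsplitnorm(2e5, q, lower = 0)
    expect_true(all(x > 0))
    expect_equal(unname(quantile(x, c(0.25, 0.5, 0.75))), q,
                 tolerance = 0.01)
  })
  # asymmetric tails: the lower scale is wider than the upper here
  expect_lt(qsplitnorm(0.05, q), q[1] - (q[3] - q[2]))
})
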