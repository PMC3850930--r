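test_that("first-pass generator preserves the centroid difference exactly", {
  dt <- 0.13
  for (ptt in c(4, 7, 10)) {
    fp <- gen_first_pass_series(bolus_ground_truth(ptt, noise_sigma = 0),
                                dt = dt)
    # analytic construction: continuous first moments differ by exactly ptt
    expect_equal(fp$truth$centroid_la - fp$truth$centroid_pa, ptt)
    # sampled, noise-free pipeline recovers it to quadrature precision
    expect_equal(ptt_from_bundle(fp), ptt, tolerance = dt / 2)
  }
  # ROIs are spatially disjoint
  fp <- gen_first_pass_series(bolus_ground_truth(7))
  expect_false(any(fp$roi_pa$mask & fp$roi_la$mask))
})

test_that("first-pass generator validates its inputs", {
  expect_error(bolus_ground_truth(0), "ptt_true")
  expect_error(bolus_ground_truth(-3), "ptt_true")
  expect_error(bolus_ground_truth(7, alpha = -1), "positive")
  expect_error(bolus_ground_truth(7, noise_sigma = -0.1), "noise_sigma")
  # a series too short to contain the delayed bolus is an explicit error
  expect_error(
    gen_first_pass_series(bolus_ground_truth(7), n_frames = 30),
    "too short")
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- gen_first_pass_series(bolus_ground_truth(6, noise_sigma = 0.02, seed = 5))
  b <- gen_first_pass_series(bolus_ground_truth(6, noise_sigma = 0.02, seed = 5))
  expect_identical(a$series$data, b$series$data)

  fa <- gen_flow_set(flow_ground_truth(70, pbvv_true = 32, noise_sigma = 2,
                                       seed = 5))
  fb <- gen_flow_set(flow_ground_truth(70, pbvv_true = 32, noise_sigma = 2,
                                       seed = 5))
  expect_identical(fa$arterial$flow, fb$arterial$flow)
  expect_identical(fa$venous[[2]]$flow, fb$venous[[2]]$flow)

  ca <- gen_cohort(cohort_spec(seed = 5))
  cb <- gen_cohort(cohort_spec(seed = 5))
  expect_identical(ca, cb)
})

test_that("flow generator conserves volume and hits the PBVV target", {
  # arterial cycle volume equals summed venous cycle volume, always
  for (nv in 1:5) {
    fl <- gen_flow_set(flow_ground_truth(70, hr = 75, pbvv_true = 28,
                                         n_veins = nv))
    sv_a <- cycle_volume(fl$arterial)
    sv_v <- sum(vapply(fl$venous, cycle_volume, numeric(1)))
    expect_equal(sv_a, sv_v, tolerance = 1e-12)
  }
  # sv_true = 70, hr = 60: arterial cycle volume is 70 mL (noise-free)
  fl <- gen_flow_set(flow_ground_truth(70, hr = 60, pbvv_true = 32))
  expect_equal(cycle_volume(fl$arterial), 70, tolerance = 0.005 * 70)

  # noisy recovery within 5%
  fl <- gen_flow_set(flow_ground_truth(70, hr = 70, pbvv_true = 32,
                                       noise_sigma = 2, seed = 3))
  pbvv <- compute_pbvv(cumulative_volume(net_flow(fl$arterial, fl$venous)))
  expect_equal(pbvv, 32, tolerance = 0.05 * 32)

  # a target at the stroke-volume ceiling is still solvable
  fl_hi <- gen_flow_set(flow_ground_truth(70, hr = 60, pbvv_true = 68))
  pbvv_hi <- compute_pbvv(cumulative_volume(
    net_flow(fl_hi$arterial, fl_hi$venous), drift_correct = FALSE))
  expect_equal(pbvv_hi, 68, tolerance = 0.05 * 68)

  expect_error(flow_ground_truth(70, pbvv_true = 75), "infeasible")
  expect_error(flow_ground_truth(-70), "positive")
  expect_error(gen_flow_set(flow_ground_truth(70), n_samples = 4), ">= 8")
})

test_that("mask generator reports exact slab volumes and honest bounds", {
  st <- gen_mask_stack("slab", n_slices = 10, voxels_per_slice = 100,
                       pixel_spacing = 1.4, slice_thickness = 5)
  expect_equal(attr(st, "volume_true_ml"), 9.8)
  expect_equal(attr(st, "discretization_bound_ml"), 0)

  # empty mask: 0 mL
  st0 <- gen_mask_stack("slab", n_slices = 3, voxels_per_slice = 0)
  expect_warning(v <- planimetric_volume(st0))
  expect_equal(v, 0)

  el <- gen_mask_stack("ellipsoid", semi_axes = c(60, 80, 100),
                       pixel_spacing = 2, slice_thickness = 5)
  expect_lt(abs(planimetric_volume(el) - attr(el, "volume_true_ml")),
            attr(el, "discretization_bound_ml"))
})

test_that("cohort generator draws from the specified distributions", {
  # SD = 0: every subject equals the group mean
  spec0 <- cohort_spec(
    metrics = list(pbvv_ml = list(patient = c(32, 0), control = c(33, 0))))
  ch <- gen_cohort(spec0, seed = 2)
  expect_true(all(ch$pbvv_ml[ch$group == "patient"] == 32))
  expect_true(all(ch$pbvv_ml[ch$group == "control"] == 33))

  # n = 200/group, PBVI 16 +/- 4 vs 20 +/- 5: sample means within 3 SEM
  ch <- gen_cohort(cohort_spec(n_patient = 200, n_control = 200), seed = 7)
  expect_lt(abs(mean(ch$pbvi_pct[ch$group == "patient"]) - 16),
            3 * 4 / sqrt(200))
  expect_lt(abs(mean(ch$pbvi_pct[ch$group == "control"]) - 20),
            3 * 5 / sqrt(200))

  # covariates exist only for patients; fibrosis flag is boolean or NA
  ch <- gen_cohort(cohort_spec(), seed = 3)
  expect_true(all(is.na(ch$dlco_pct[ch$group == "control"])))
  expect_true(all(is.na(ch$fibrosis_hrct) | ch$fibrosis_hrct %in% c(TRUE, FALSE)))

  expect_error(cohort_spec(n_patient = 1), "n >= 2")
  expect_error(cohort_spec(metrics = list(x = list(patient = c(1, -1),
                                                   control = c(1, 1)))),
               "sd >= 0")
})

test_that("generator RNG use does not disturb the caller's stream", {
  set.seed(99)
  before <- .Random.seed
  invisible(gen_first_pass_series(bolus_ground_truth(7, noise_sigma = 0.02,
                                                     seed = 1)))
  invisible(gen_cohort(cohort_spec(seed = 4)))
  expect_identical(.Random.seed, before)
})
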