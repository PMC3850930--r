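test_that("cycle volume integrates flow over one cycle", {
  # constant flow: SV = q * T, and CO = SV * HR / 1000
  t <- seq(0, 1, length.out = 33)[1:32]
  cv <- cycle_volume(flow_curve(t, rep(100, 32), cycle_length = 1))
  expect_equal(cv, 100)
  expect_equal(cardiac_output(cv, 60), 6.0)

  # half-sinusoid: peak 300 mL/s over 0.3 s systole -> SV = 2*300*0.3/pi
  t <- seq(0, 1, length.out = 1001)[1:1000]
  q <- ifelse(t < 0.3, 300 * sin(pi * t / 0.3), 0)
  expect_equal(cycle_volume(flow_curve(t, q, cycle_length = 1)),
               2 * 300 * 0.3 / pi, tolerance = 1e-4)

  # generator ground truth at the default 35 samples/cycle
  fl <- gen_flow_set(flow_ground_truth(70, hr = 60, pbvv_true = 32))
  expect_equal(cycle_volume(fl$arterial), 70, tolerance = 0.005 * 70)

  expect_error(cardiac_output(70, 0), "positive")
  expect_error(flow_curve(t, q[1:10], cycle_length = 1), "equal length")
})

test_that("net flow cancels venous return and validates cycle lengths", {
  fl <- gen_flow_set(flow_ground_truth(70, hr = 70, pbvv_true = 32,
                                       n_veins = 1))
  # a single vein identical to the arterial curve: identically zero net flow
  net <- net_flow(fl$arterial, list(fl$arterial))
  expect_equal(net$flow, numeric(length(net$flow)))

  # two identical veins each carrying half: also zero
  half <- fl$arterial
  half$flow <- half$flow / 2
  net2 <- net_flow(fl$arterial, list(half, half))
  expect_equal(max(abs(net2$flow)), 0)

  # noise-free generator output: the net cycle integral vanishes
  fl4 <- gen_flow_set(flow_ground_truth(70, hr = 70, pbvv_true = 32,
                                        n_veins = 4))
  expect_lt(abs(cycle_volume(net_flow(fl4$arterial, fl4$venous))), 1e-9 * 70)

  # mismatched cycle length is an error naming the offending vessel
  bad <- flow_curve(fl$arterial$times * 0.9, fl$arterial$flow,
                    vessel = "pulmonary_vein_9",
                    cycle_length = fl$arterial$cycle_length * 0.9)
  expect_error(net_flow(fl$arterial, list(bad)), "pulmonary_vein_9")
})

test_that("cumulative volume integrates net flow and closes under drift correction", {
  t <- seq(0, 1, length.out = 129)[1:128]
  # zero net flow: identically zero volume curve
  z <- cumulative_volume(flow_curve(t, numeric(128), cycle_length = 1),
                         drift_correct = FALSE)
  expect_equal(z$cumulative_volume, numeric(129))
  expect_equal(compute_pbvv(z), 0)

  # net = 100 sin(2 pi t): cumulative (100/2pi)(1 - cos), max - min = 100/pi
  sine <- flow_curve(t, 100 * sin(2 * pi * t), cycle_length = 1)
  vol <- cumulative_volume(sine, drift_correct = FALSE)
  expect_equal(compute_pbvv(vol), 100 / pi, tolerance = 0.005 * 100 / pi)

  # noisy generated set, drift corrected: exact closure, bounded correction
  fl <- gen_flow_set(flow_ground_truth(70, hr = 70, pbvv_true = 32,
                                       noise_sigma = 2, seed = 3))
  vol2 <- cumulative_volume(net_flow(fl$arterial, fl$venous))
  expect_identical(vol2$cumulative_volume[length(vol2$cumulative_volume)], 0)
  # closure error stems from the sampled noise: |drift| <= 5 sigma * sqrt(n+1) * dt
  T <- fl$arterial$cycle_length
  n <- length(fl$arterial$times)
  expect_lt(abs(vol2$drift_ml), 5 * 2 * sqrt(5 * (n + 1)) * T / n)
})

test_that("PBVV matches ground truth and its invariances", {
  fl <- gen_flow_set(flow_ground_truth(70, hr = 70, pbvv_true = 32,
                                       noise_sigma = 2, seed = 3))
  pbvv <- compute_pbvv(cumulative_volume(net_flow(fl$arterial, fl$venous)))
  expect_equal(pbvv, 32, tolerance = 0.05 * 32)

  # pbvv_true = 0 means venous == arterial: PBVV is 0
  fl0 <- gen_flow_set(flow_ground_truth(70, hr = 70, pbvv_true = 0))
  expect_equal(compute_pbvv(cumulative_volume(
    net_flow(fl0$arterial, fl0$venous), drift_correct = FALSE)), 0,
    tolerance = 1e-9)

  # invariance to the cycle start point (within one sample's quadrature)
  flc <- gen_flow_set(flow_ground_truth(70, hr = 60, pbvv_true = 32))
  ref <- compute_pbvv(cumulative_volume(net_flow(flc$arterial, flc$venous),
                                        drift_correct = FALSE))
  for (k in c(5, 12, 23)) {
    rot <- compute_pbvv(cumulative_volume(
      net_flow(rotate_flow(flc$arterial, k), lapply(flc$venous, rotate_flow, k)),
      drift_correct = FALSE))
    expect_equal(rot, ref, tolerance = 70 / length(flc$arterial$times))
  }

  # invariance to venous partitioning (1-5 veins, fixed sum)
  vals <- vapply(1:5, function(nv) {
    fl <- gen_flow_set(flow_ground_truth(70, hr = 70, pbvv_true = 32,
                                         n_veins = nv))
    compute_pbvv(cumulative_volume(net_flow(fl$arterial, fl$venous),
                                   drift_correct = FALSE))
  }, numeric(1))
  expect_equal(max(vals) - min(vals), 0, tolerance = 1e-9)

  # scaling all flows by k scales SV and PBVV by k; PBVV/SV is unchanged
  k <- 2.5
  scaled <- lapply(c(list(flc$arterial), flc$venous), function(cu) {
    cu$flow <- k * cu$flow
    cu
  })
  sv_s <- cycle_volume(scaled[[1]])
  pbvv_s <- compute_pbvv(cumulative_volume(
    net_flow(scaled[[1]], scaled[-1]), drift_correct = FALSE))
  expect_equal(sv_s, k * cycle_volume(flc$arterial), tolerance = 1e-9)
  expect_equal(pbvv_s, k * ref, tolerance = 1e-9)
  expect_equal(pbvv_sv_ratio(pbvv_s, sv_s),
               pbvv_sv_ratio(ref, cycle_volume(flc$arterial)),
               tolerance = 1e-9)
})

test_that("PBVV/SV ratio is a percentage of pulmonary-trunk stroke volume", {
  expect_equal(pbvv_sv_ratio(32, 70), 100 * 32 / 70)
  expect_equal(pbvv_sv_ratio(0, 70), 0)
  expect_error(pbvv_sv_ratio(32, 0), "positive")
})
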