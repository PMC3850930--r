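test_that("extract_tic returns ROI mean time courses", {
  # constant field: curve is constant at the field value
  data <- array(5, dim = c(8, 12, 4))
  series <- image_series(data, frame_times = 0:3 * 0.5)
  mask <- matrix(FALSE, 8, 12); mask[3:5, 2:4] <- TRUE
  curve <- extract_tic(series, roi_mask(mask))
  expect_equal(curve$intensities, rep(5, 4))
  expect_equal(curve$times, 0:3 * 0.5)

  # one-voxel mask: that voxel's time course exactly
  data <- array(rnorm(8 * 12 * 6), dim = c(8, 12, 6))
  series <- image_series(data, frame_times = seq(0, 1, length.out = 6))
  m1 <- matrix(FALSE, 8, 12); m1[4, 7] <- TRUE
  expect_equal(extract_tic(series, roi_mask(m1))$intensities, data[4, 7, ])

  # noise-free generator output equals the analytic ROI curves
  fp <- gen_first_pass_series(bolus_ground_truth(7, noise_sigma = 0))
  expect_equal(extract_tic(fp$series, fp$roi_pa)$intensities,
               fp$truth$curve_pa)
  expect_equal(extract_tic(fp$series, fp$roi_la)$intensities,
               fp$truth$curve_la)

  # shape mismatch and empty mask are errors
  expect_error(extract_tic(series, roi_mask(matrix(TRUE, 4, 4))),
               "does not match")
  expect_error(roi_mask(matrix(FALSE, 8, 12)), "empty")
})

test_that("baseline correction subtracts the pre-contrast mean", {
  # constant curve: corrected to all zeros
  x <- tic(0:9 * 0.13, rep(100, 10))
  expect_equal(baseline_correct(x, 4)$intensities, rep(0, 10))

  # a common offset does not change the corrected curve
  t <- 0:99 * 0.13
  s <- gamma_variate(t, 1, 2, 3, 1.5)
  a <- baseline_correct(tic(t, s + 100), 5)
  b <- baseline_correct(tic(t, s), 5)
  expect_equal(a$intensities, b$intensities)

  # gamma-variate + baseline: centroid after correction equals the analytic
  # first moment t0 + (alpha + 1) * beta within quadrature tolerance
  dt <- 0.13
  t <- 0:299 * dt
  s <- gamma_variate(t, 50, 2, 3, 1.5) + 100
  corr <- baseline_correct(tic(t, s), 5)
  expect_equal(curve_centroid(corr), 2 + (3 + 1) * 1.5, tolerance = dt / 2)

  expect_error(baseline_correct(x, 10), "n_pre")
  expect_error(baseline_correct(x, 0), "n_pre")
})

test_that("curve centroid is the discrete first moment", {
  # single-point mass
  t <- seq(0, 8, by = 0.4)
  s <- numeric(length(t)); s[t == 3.2] <- 100
  expect_equal(curve_centroid(tic(t, s)), 3.2)

  # symmetric triangle on [2, 8] has its centroid at the apex
  t <- seq(0, 10, by = 0.25)
  s <- pmax(0, 3 - abs(t - 5))
  expect_equal(curve_centroid(tic(t, s)), 5.0)

  # sampled gamma-variate: equals a brute-force discrete sum exactly and
  # converges to the analytic moment t0 + (alpha + 1) * beta as dt -> 0
  for (dt in c(0.13, 0.02)) {
    t <- seq(0, 40, by = dt)
    s <- gamma_variate(t, 1, 2, 3, 1.5)
    got <- curve_centroid(tic(t, s))
    expect_equal(got, centroid_bruteforce(t, s), tolerance = 1e-12)
    expect_equal(got, 2 + 4 * 1.5, tolerance = dt / 2)
  }

  # invariance under positive scaling of intensities
  t <- seq(0, 30, by = 0.13)
  s <- gamma_variate(t, 1, 1, 2.5, 1.2)
  expect_equal(curve_centroid(tic(t, 7.3 * s)), curve_centroid(tic(t, s)))

  # time shift moves the centroid by exactly the shift (up to the tiny
  # gamma-variate tail lost past the end of the grid)
  s2 <- gamma_variate(t, 1, 1 + 2.6, 2.5, 1.2)  # shift by 20 * dt stays on-grid
  expect_equal(curve_centroid(tic(t, s2)) - curve_centroid(tic(t, s)), 2.6,
               tolerance = 1e-4)

  # all-zero window (before bolus arrival) is an undefined centroid
  expect_error(curve_centroid(tic(t, s), window = c(0, 0.9)), "undefined")

  # trapezoid rule agrees with rectangle rule on a uniform grid
  expect_equal(curve_centroid(tic(t, s), rule = "trapezoid"),
               curve_centroid(tic(t, s)), tolerance = 1e-3)
})

test_that("PTT is the centroid difference of the LA and PA curves", {
  t <- seq(0, 40, by = 0.13)
  s <- gamma_variate(t, 1, 2, 3, 1.5)
  # identical curves: zero
  expect_equal(compute_ptt(tic(t, s), tic(t, s))$ptt_s, 0)

  # LA = PA shifted by exactly 6.0 s
  s_la <- gamma_variate(t, 1, 8, 3, 1.5)
  res <- compute_ptt(tic(t, s), tic(t, s_la))
  expect_equal(res$ptt_s, 6.0, tolerance = 0.13 / 2)
  expect_length(res$flags, 0)

  # swapped curves: negative value flagged, not clamped
  expect_warning(res <- compute_ptt(tic(t, s_la), tic(t, s)), "negative")
  expect_equal(res$ptt_s, -6.0, tolerance = 0.13 / 2)
  expect_true("negative_ptt" %in% res$flags)

  # synthetic subject at 2% noise recovers the true PTT within 5%
  fp <- gen_first_pass_series(bolus_ground_truth(7, noise_sigma = 0.02,
                                                 seed = 1))
  expect_equal(ptt_from_bundle(fp, window_mode = "local_min"), 7,
               tolerance = 0.05 * 7)

  # undefined centroid on either curve propagates as an error
  expect_error(compute_ptt(tic(t, numeric(length(t))), tic(t, s)),
               "undefined")
})

test_that("PTT is invariant to common baseline offsets after correction", {
  fp <- gen_first_pass_series(bolus_ground_truth(6.5, noise_sigma = 0))
  base <- ptt_from_bundle(fp)
  shifted <- fp
  shifted$series$data <- shifted$series$data + 42
  expect_equal(ptt_from_bundle(shifted), base, tolerance = 1e-9)
})

test_that("gamma-variate fit recovers curve parameters and centroid", {
  t <- seq(0, 35, by = 0.13)
  s <- gamma_variate(t, 80, 2, 3, 1.5)
  fit <- fit_gamma_variate(tic(t, s))
  expect_equal(fit$alpha, 3, tolerance = 1e-4)
  expect_equal(fit$beta, 1.5, tolerance = 1e-4)
  expect_equal(fit$centroid, 2 + 4 * 1.5, tolerance = 1e-4)

  # fitted centroid is robust to truncating the tail (extrapolation)
  keep <- t <= 8
  fit2 <- fit_gamma_variate(tic(t[keep], s[keep]))
  expect_equal(fit2$centroid, 8, tolerance = 0.05)
})
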