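# Synthetic acquisitions with analytic ground truth. Every generator returns
# the truth it was built from, so downstream stages can be validated without
# clinical data.

# Evaluate `code` under a fixed seed without disturbing the caller's RNG
# stream; a NULL seed leaves the RNG alone.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else suppressWarnings(rm(".Random.seed", envir = globalenv()))
  })
  set.seed(seed)
  force(code)
}

#' Ground truth for a synthetic first-pass bolus acquisition
#'
#' Parameters of a two-ROI first-pass experiment: a gamma-variate bolus
#' arriving in the pulmonary trunk at `t0_pa`, reappearing in the left atrium
#' after a transit delay whose centroid difference is exactly `ptt_true`.
#'
#' @param ptt_true true pulmonary transit time in seconds, > 0.
#' @param t0_pa bolus arrival time in the pulmonary trunk, seconds, >= 0.
#' @param alpha,beta gamma-variate shape (dimensionless) and scale (seconds),
#'   both > 0.
#' @param noise_sigma voxel noise as a fraction of peak intensity, >= 0.
#' @param seed integer RNG seed (NULL for the current RNG stream).
#'
#' @return An object of class `bolus_ground_truth`.
#' @export
bolus_ground_truth <- function(ptt_true, t0_pa = 1.0, alpha = 3, beta = 1.5,
                               noise_sigma = 0, seed = NULL) {
  if (!is.finite(ptt_true) || ptt_true <= 0) stop("ptt_true must be > 0")
  if (t0_pa < 0) stop("t0_pa must be >= 0")
  if (alpha <= 0 || beta <= 0) stop("alpha and beta must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(
    list(ptt_true = ptt_true, t0_pa = t0_pa, alpha = alpha, beta = beta,
         noise_sigma = noise_sigma, seed = seed),
    class = "bolus_ground_truth"
  )
}

#' Generate a synthetic first-pass image series with two ROIs
#'
#' Builds a time-resolved image series in which the mean intensity of the
#' pulmonary-trunk ROI follows `baseline + gamma-variate` and the left-atrial
#' ROI follows a dispersed, delayed copy: the LA curve uses the same shape
#' `alpha` with scale `beta * dispersion` and an arrival time chosen so that
#' the difference of the two curves' analytic first moments equals
#' `ptt_true` exactly (each gamma-variate centroid is `t0 + (alpha+1)*beta`).
#' Dispersion broadens the LA curve, as transit through the pulmonary
#' vascular bed does, while preserving the centroid-difference ground truth.
#'
#' Noise is applied per voxel to the magnitude image: Rician by default
#' (magnitude of a complex Gaussian perturbation, the noise distribution of
#' magnitude MR images), with a plain additive Gaussian fallback.
#'
#' @param gt a [bolus_ground_truth()].
#' @param dt frame interval in seconds (default 0.13, a typical temporal
#'   resolution of saturation-recovery first-pass imaging).
#' @param n_frames number of frames; default covers baseline plus the 99.95%
#'   mass of the delayed bolus. An explicitly short series is an error, not a
#'   silent truncation.
#' @param grid in-plane image size `c(rows, cols)` (default 16 x 16).
#' @param baseline baseline signal as a fraction of bolus peak (default
#'   0.15, the nonzero saturation-recovery baseline).
#' @param dispersion LA/PA gamma-variate scale ratio, >= 1 (default 1.3);
#'   must leave the LA arrival after the PA arrival.
#' @param noise_model `"rician"` (default) or `"gaussian"`.
#'
#' @return List: `series` ([image_series()]), `roi_pa`, `roi_la`
#'   ([roi_mask()]s, spatially disjoint), and `truth` (the ground truth plus
#'   the analytic curve parameters, including `t0_la`, `beta_la` and the
#'   noise-free analytic ROI curves `curve_pa`, `curve_la`).
#' @export
gen_first_pass_series <- function(gt, dt = 0.13, n_frames = NULL,
                                  grid = c(16L, 16L), baseline = 0.15,
                                  dispersion = 1.3,
                                  noise_model = c("rician", "gaussian")) {
  stopifnot(inherits(gt, "bolus_ground_truth"))
  noise_model <- match.arg(noise_model)
  if (dt <= 0) stop("dt must be positive")
  if (dispersion < 1) stop("dispersion must be >= 1")
  beta_la <- gt$beta * dispersion
  # LA arrival chosen so centroid(LA) - centroid(PA) = ptt_true exactly
  t0_la <- gt$t0_pa + gt$ptt_true - (gt$alpha + 1) * (beta_la - gt$beta)
  if (t0_la <= gt$t0_pa)
    stop("dispersion too large for this ptt_true: LA arrival would precede PA")
  # cover 99.95% of the LA bolus mass (gamma-variate mass ~ gamma(alpha+1))
  t_need <- t0_la + qgamma(0.9995, shape = gt$alpha + 1, scale = beta_la)
  n_min <- ceiling(t_need / dt) + 1L
  if (is.null(n_frames)) n_frames <- n_min
  if (n_frames < n_min)
    stop(sprintf(
      "series too short: %d frames x %.3g s does not contain the delayed bolus (need >= %d frames)",
      n_frames, dt, n_min))
  times <- (seq_len(n_frames) - 1L) * dt
  A_pa <- (exp(1) / gt$alpha)^gt$alpha        # unit peak amplitude
  curve_pa <- baseline + gamma_variate(times, A_pa, gt$t0_pa, gt$alpha, gt$beta)
  curve_la <- baseline +
    gamma_variate(times, A_pa / dispersion, t0_la, gt$alpha, beta_la)

  rows <- grid[1]; cols <- grid[2]
  if (rows < 8L || cols < 12L) stop("image grid too small for two disjoint ROIs")
  mask_pa <- matrix(FALSE, rows, cols)
  mask_la <- matrix(FALSE, rows, cols)
  r <- seq(floor(rows / 4) + 1L, rows - floor(rows / 4))
  mask_pa[r, seq(2L, floor(cols / 2) - 1L)] <- TRUE
  mask_la[r, seq(floor(cols / 2) + 2L, cols - 1L)] <- TRUE

  data <- array(baseline, dim = c(rows, cols, n_frames))
  for (f in seq_len(n_frames)) {
    plane <- data[, , f]
    plane[mask_pa] <- curve_pa[f]
    plane[mask_la] <- curve_la[f]
    data[, , f] <- plane
  }
  if (gt$noise_sigma > 0) {
    sigma <- gt$noise_sigma * (baseline + 1)  # fraction of peak signal
    data <- with_seed(gt$seed, {
      n <- length(data)
      if (noise_model == "rician") {
        sqrt((data + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
      } else {
        data + rnorm(n, 0, sigma)
      }
    })
    dim(data) <- c(rows, cols, n_frames)
  }
  truth <- c(unclass(gt),
             list(t0_la = t0_la, beta_la = beta_la, dispersion = dispersion,
                  baseline = baseline, dt = dt, noise_model = noise_model,
                  centroid_pa = gt$t0_pa + (gt$alpha + 1) * gt$beta,
                  centroid_la = t0_la + (gt$alpha + 1) * beta_la,
                  curve_pa = curve_pa, curve_la = curve_la))
  list(
    series = image_series(data, times),
    roi_pa = roi_mask(mask_pa, "pulmonary_trunk"),
    roi_la = roi_mask(mask_la, "left_atrium"),
    truth = truth
  )
}

#' Ground truth for a synthetic pulmonary flow set
#'
#' @param sv_true true pulmonary-trunk stroke volume in mL, > 0.
#' @param hr heart rate in beats/min, > 0.
#' @param pbvv_true true pulmonary blood volume variation in mL,
#'   `0 <= pbvv_true <= sv_true` (the cyclic storage cannot exceed the
#'   stroke volume).
#' @param n_veins number of pulmonary veins, 1-5.
#' @param noise_sigma additive flow noise SD in mL/s, >= 0.
#' @param seed integer RNG seed (NULL for the current stream).
#'
#' @return An object of class `flow_ground_truth`.
#' @export
flow_ground_truth <- function(sv_true, hr = 70, pbvv_true = 32, n_veins = 4L,
                              noise_sigma = 0, seed = NULL) {
  if (sv_true <= 0) stop("sv_true must be positive")
  if (hr <= 0) stop("hr must be positive")
  if (pbvv_true < 0) stop("pbvv_true must be >= 0")
  if (pbvv_true > sv_true)
    stop("infeasible ground truth: pbvv_true exceeds sv_true")
  n_veins <- as.integer(n_veins)
  if (n_veins < 1L || n_veins > 5L) stop("n_veins must be in 1..5")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(
    list(sv_true = sv_true, hr = hr, pbvv_true = pbvv_true,
         n_veins = n_veins, noise_sigma = noise_sigma, seed = seed),
    class = "flow_ground_truth"
  )
}

# Arterial waveform: systolic half-sinusoid plus optional constant diastolic
# throughflow, integrating to `sv` over the cycle. Vectorised in t (cyclic).
arterial_waveform <- function(t, sv, T, systole_frac = 0.3,
                              diastolic_fraction = 0) {
  ts <- systole_frac * T
  qd <- diastolic_fraction * sv / T
  qpeak <- (1 - diastolic_fraction) * sv * pi / (2 * ts)
  tm <- t %% T
  q <- rep(qd, length(t))
  inside <- tm < ts
  q[inside] <- qd + qpeak * sin(pi * tm[inside] / ts)
  q
}

# Peak-to-trough excursion of the cumulative integral of
# qa(t) - qa(t - delta) over one cycle, evaluated on a fine grid. For the
# half-sinusoid this is the maximal sliding-window volume, monotone
# increasing in delta up to the systolic duration (where it reaches sv).
shift_excursion <- function(delta, sv, T, systole_frac, diastolic_fraction,
                            n_grid = 8192L) {
  tg <- seq(0, T, length.out = n_grid + 1L)
  qa <- arterial_waveform(tg, sv, T, systole_frac, diastolic_fraction)
  qs <- arterial_waveform(tg - delta, sv, T, systole_frac, diastolic_fraction)
  dq <- qa - qs
  v <- c(0, cumsum(diff(tg) * (head(dq, -1) + tail(dq, -1)) / 2))
  max(v) - min(v)
}

#' Generate a synthetic pulmonary flow set (trunk + veins)
#'
#' The arterial waveform is a systolic half-sinusoid pulse (plus an optional
#' constant diastolic throughflow) integrating to `sv_true` per cycle. The
#' total venous waveform is a damped, phase-shifted copy,
#' `Qv = (1 - d) * Qa(t) + d * Qa(t - delta)`: the undamped fraction leaves
#' the circulation instantaneously, the damped fraction after a delay, so the
#' cyclic volume stored in the pulmonary bed — the peak-to-trough excursion
#' of the cumulative net inflow — is `d` times the excursion produced by a
#' pure shift. The damping `d` (and, for large targets, the shift `delta`) is
#' solved so this noise-free excursion equals `pbvv_true` exactly; arterial
#' and summed venous cycle volumes are equal by construction. The venous
#' return is partitioned among `n_veins` veins in fixed proportions, which
#' leaves the summed venous flow (and hence PBVV) unchanged.
#'
#' @param gt a [flow_ground_truth()].
#' @param n_samples samples per cycle for each returned curve (default 35,
#'   a typical retrospectively gated reconstruction), >= 8.
#' @param systole_frac systolic fraction of the cycle (default 0.3).
#' @param venous_shift_frac venous phase shift as a fraction of the cycle
#'   (default 0.25); increased automatically when `pbvv_true` is too large to
#'   reach by damping alone.
#' @param diastolic_fraction fraction of the stroke volume carried by a
#'   constant diastolic flow component (default 0).
#' @param vein_weights optional venous partition weights (length `n_veins`,
#'   positive; normalised internally). Default: equal split.
#'
#' @return List: `arterial` ([flow_curve()]), `venous` (list of
#'   [flow_curve()]s), and `truth` (ground truth plus the solved damping `d`
#'   and shift `delta_s`).
#' @export
gen_flow_set <- function(gt, n_samples = 35L, systole_frac = 0.3,
                         venous_shift_frac = 0.25, diastolic_fraction = 0,
                         vein_weights = NULL) {
  stopifnot(inherits(gt, "flow_ground_truth"))
  n_samples <- as.integer(n_samples)
  if (n_samples < 8L) stop("n_samples must be >= 8")
  if (systole_frac <= 0 || systole_frac >= 1)
    stop("systole_frac must be in (0, 1)")
  T <- 60 / gt$hr
  ts <- systole_frac * T
  delta <- venous_shift_frac * T
  E <- shift_excursion(delta, gt$sv_true, T, systole_frac, diastolic_fraction)
  if (gt$pbvv_true <= E) {
    d <- if (E > 0) gt$pbvv_true / E else 0
  } else {
    # damping alone cannot reach the target: lengthen the venous delay
    # (excursion grows with the shift, reaching sv once the shift spans
    # the whole systolic pulse)
    d <- 1
    f <- function(dl) shift_excursion(dl, gt$sv_true, T, systole_frac,
                                      diastolic_fraction) - gt$pbvv_true
    upper <- ts * 1.0001
    if (f(upper) < 0) upper <- T / 2
    delta <- uniroot(f, c(delta, upper), tol = 1e-10)$root
  }
  if (is.null(vein_weights)) vein_weights <- rep(1, gt$n_veins)
  if (length(vein_weights) != gt$n_veins || any(vein_weights <= 0))
    stop("vein_weights must be positive, one per vein")
  w <- vein_weights / sum(vein_weights)

  times <- seq(0, T, length.out = n_samples + 1L)[seq_len(n_samples)]
  qa <- arterial_waveform(times, gt$sv_true, T, systole_frac,
                          diastolic_fraction)
  qv_tot <- (1 - d) * qa +
    d * arterial_waveform(times - delta, gt$sv_true, T, systole_frac,
                          diastolic_fraction)
  # enforce conservation on the sampled curves: the cyclic-trapezoid cycle
  # volumes of arterial and summed venous flow agree to machine precision,
  # not merely in the continuous limit
  cyc_int <- function(q) trapz(c(times, times[1] + T), c(q, q[1]))
  qv_tot <- qv_tot * (cyc_int(qa) / cyc_int(qv_tot))
  noise <- function(n) if (gt$noise_sigma > 0) rnorm(n, 0, gt$noise_sigma) else 0
  out <- with_seed(gt$seed, {
    arterial <- flow_curve(times, qa + noise(n_samples),
                           vessel = "pulmonary_trunk", cycle_length = T)
    venous <- lapply(seq_len(gt$n_veins), function(i) {
      flow_curve(times, w[i] * qv_tot + noise(n_samples),
                 vessel = paste0("pulmonary_vein_", i), cycle_length = T)
    })
    list(arterial = arterial, venous = venous)
  })
  out$truth <- c(unclass(gt),
                 list(d = d, delta_s = delta, cycle_length = T,
                      systole_frac = systole_frac,
                      diastolic_fraction = diastolic_fraction,
                      vein_weights = w,
                      co_true = cardiac_output(gt$sv_true, gt$hr)))
  out
}

#' Generate a binary mask stack of known analytic volume
#'
#' Two geometries:
#' * `"slab"` — `n_slices` slices each containing `voxels_per_slice` masked
#'   voxels; the analytic volume is exactly voxel count x voxel volume
#'   (discretization bound 0).
#' * `"ellipsoid"` — voxel centres inside an ellipsoid with the given
#'   semi-axes (mm); the analytic volume is `(4/3) pi a b c` and the
#'   reported discretization bound is the total volume of the voxels that
#'   straddle the surface.
#'
#' @param shape `"slab"` or `"ellipsoid"`.
#' @param n_slices number of slices (slab geometry).
#' @param voxels_per_slice masked voxels per slice, scalar or per-slice
#'   vector; may be 0 (empty slices allowed).
#' @param semi_axes ellipsoid semi-axes `c(a, b, c)` in mm (rows, cols,
#'   slice axis).
#' @param pixel_spacing in-plane spacing in mm (default 1.4).
#' @param slice_thickness slice thickness in mm (default 5).
#' @param slice_gap slice gap in mm (default 0).
#' @param label stack label (default `"lung"`).
#'
#' @return A [segmentation_stack()] with attributes `volume_true_ml` and
#'   `discretization_bound_ml`.
#' @export
gen_mask_stack <- function(shape = c("slab", "ellipsoid"),
                           n_slices = 10L, voxels_per_slice = 100L,
                           semi_axes = c(60, 80, 100),
                           pixel_spacing = 1.4, slice_thickness = 5,
                           slice_gap = 0, label = "lung") {
  shape <- match.arg(shape)
  pixel_spacing <- rep(as.numeric(pixel_spacing), length.out = 2L)
  if (any(pixel_spacing <= 0) || slice_thickness <= 0 || slice_gap < 0)
    stop("pixel spacing and slice thickness must be positive, gap >= 0")
  voxel_ml <- prod(pixel_spacing) * (slice_thickness + slice_gap) / 1000
  if (shape == "slab") {
    n_slices <- as.integer(n_slices)
    if (n_slices < 1L) stop("n_slices must be >= 1")
    vps <- rep(as.integer(voxels_per_slice), length.out = n_slices)
    if (any(vps < 0)) stop("voxels_per_slice must be >= 0")
    side <- max(ceiling(sqrt(max(vps, 1L))) + 2L, 4L)
    mask <- array(FALSE, dim = c(side, side, n_slices))
    for (k in seq_len(n_slices)) {
      if (vps[k] > 0) {
        plane <- matrix(FALSE, side, side)
        plane[seq_len(vps[k])] <- TRUE
        mask[, , k] <- plane
      }
    }
    vol_true <- sum(vps) * voxel_ml
    bound <- 0
  } else {
    if (length(semi_axes) != 3L || any(semi_axes <= 0))
      stop("semi_axes must be 3 positive lengths in mm")
    a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
    dz <- slice_thickness + slice_gap
    xs <- axis_centers(a, pixel_spacing[1])
    ys <- axis_centers(b, pixel_spacing[2])
    zs <- axis_centers(cc, dz)
    fx <- (xs / a)^2; fy <- (ys / b)^2; fz <- (zs / cc)^2
    f <- outer(outer(fx, fy, `+`), fz, `+`)
    mask <- f <= 1
    # surface voxels: voxel corners disagree about inside/outside
    lo <- function(v, h) pmax(abs(v) - h / 2, 0)
    hi <- function(v, h) abs(v) + h / 2
    fmin <- outer(outer((lo(xs, pixel_spacing[1]) / a)^2,
                        (lo(ys, pixel_spacing[2]) / b)^2, `+`),
                  (lo(zs, dz) / cc)^2, `+`)
    fmax <- outer(outer((hi(xs, pixel_spacing[1]) / a)^2,
                        (hi(ys, pixel_spacing[2]) / b)^2, `+`),
                  (hi(zs, dz) / cc)^2, `+`)
    bound <- sum(fmin <= 1 & fmax > 1) * voxel_ml
    vol_true <- 4 / 3 * pi * a * b * cc / 1000
  }
  stack <- segmentation_stack(mask, pixel_spacing, slice_thickness,
                              slice_gap, label = label)
  attr(stack, "volume_true_ml") <- vol_true
  attr(stack, "discretization_bound_ml") <- bound
  stack
}

# Symmetric voxel-centre coordinates covering [-half-h, half+h]
axis_centers <- function(half, h) {
  n <- ceiling(half / h) + 1L
  seq(-n, n) * h
}

#' Specification of a synthetic two-group cohort
#'
#' Per-group sample sizes and per-metric normal means/SDs for a
#' patient/control study. Defaults reproduce a 27-patient / 10-control
#' systemic-sclerosis study design: PBVI 16 +/- 4 vs 20 +/- 5%, PBV
#' 466 +/- 87 vs 471 +/- 122 mL, PBVV 32 +/- 8 vs 33 +/- 7 mL, PBVV/SV
#' 45 +/- 10 vs 40 +/- 6%, LV SV index 44 +/- 11 vs 54 +/- 7 mL/m^2, heart
#' rate 76 +/- 11 vs 64 +/- 7 bpm, BSA 1.81 +/- 0.16 vs 1.78 +/- 0.21 m^2,
#' age 57 +/- 13 vs 54 +/- 9 y. Clinical covariates (patients only) use
#' plausible values for an early systemic-sclerosis cohort, with per-covariate
#' missingness emulating incomplete clinical workup; the fibrosis flag is
#' Bernoulli with the stated prevalence.
#'
#' @param n_patient,n_control group sizes, each >= 2.
#' @param metrics named list; each element is
#'   `list(patient = c(mean, sd), control = c(mean, sd))` with sd >= 0.
#' @param covariates named list of `c(mean, sd)` for patient-only continuous
#'   covariates.
#' @param missing named list of missingness fractions in `[0, 1]` for
#'   covariates (and `fibrosis_hrct`).
#' @param fibrosis_prevalence probability of fibrosis-related pathology among
#'   patients with an HRCT assessment.
#' @param seed integer RNG seed (NULL for the current stream).
#'
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(
    n_patient = 27L, n_control = 10L,
    metrics = list(
      pbvi_pct    = list(patient = c(16, 4),    control = c(20, 5)),
      pbv_ml      = list(patient = c(466, 87),  control = c(471, 122)),
      pbvv_ml     = list(patient = c(32, 8),    control = c(33, 7)),
      pbvv_sv_pct = list(patient = c(45, 10),   control = c(40, 6)),
      sv_i_ml_m2  = list(patient = c(44, 11),   control = c(54, 7)),
      hr_bpm      = list(patient = c(76, 11),   control = c(64, 7)),
      bsa_m2      = list(patient = c(1.81, 0.16), control = c(1.78, 0.21)),
      age_y       = list(patient = c(57, 13),   control = c(54, 9))
    ),
    covariates = list(
      dlco_pct  = c(65, 18),
      vc_pct    = c(85, 18),
      spap_mmhg = c(36, 14)
    ),
    missing = list(dlco_pct = 4 / 27, vc_pct = 2 / 27, spap_mmhg = 4 / 27,
                   fibrosis_hrct = 3 / 27),
    fibrosis_prevalence = 15 / 24,
    seed = NULL) {
  n_patient <- as.integer(n_patient); n_control <- as.integer(n_control)
  if (n_patient < 2L || n_control < 2L) stop("each group needs n >= 2")
  for (m in names(metrics)) {
    for (g in c("patient", "control")) {
      v <- metrics[[m]][[g]]
      if (length(v) != 2L || v[2] < 0)
        stop("metric '", m, "' needs c(mean, sd) with sd >= 0 for group ", g)
    }
  }
  for (m in names(covariates)) {
    if (length(covariates[[m]]) != 2L || covariates[[m]][2] < 0)
      stop("covariate '", m, "' needs c(mean, sd) with sd >= 0")
  }
  if (any(unlist(missing) < 0) || any(unlist(missing) > 1))
    stop("missingness fractions must be in [0, 1]")
  if (fibrosis_prevalence < 0 || fibrosis_prevalence > 1)
    stop("fibrosis_prevalence must be in [0, 1]")
  structure(
    list(n_patient = n_patient, n_control = n_control, metrics = metrics,
         covariates = covariates, missing = missing,
         fibrosis_prevalence = fibrosis_prevalence, seed = seed),
    class = "cohort_spec"
  )
}

#' Generate a synthetic two-group cohort
#'
#' Draws each metric independently from the per-group normal distributions in
#' the spec, attaches patient-only covariates with the specified missingness,
#' and returns a [cohort_table()]. Bit-reproducible under a fixed seed.
#'
#' @param spec a [cohort_spec()].
#' @param seed optional seed overriding `spec$seed`.
#'
#' @return A [cohort_table()] with one row per subject.
#' @export
gen_cohort <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- spec$seed
  with_seed(seed, {
    n <- c(spec$n_patient, spec$n_control)
    group <- rep(c("patient", "control"), n)
    df <- data.frame(
      id = sprintf("%s_%02d", ifelse(group == "patient", "pt", "ctl"),
                   c(seq_len(n[1]), seq_len(n[2]))),
      group = group,
      stringsAsFactors = FALSE
    )
    for (m in names(spec$metrics)) {
      pm <- spec$metrics[[m]]$patient
      cm <- spec$metrics[[m]]$control
      df[[m]] <- c(rnorm(n[1], pm[1], pm[2]), rnorm(n[2], cm[1], cm[2]))
    }
    for (cv in names(spec$covariates)) {
      p <- spec$covariates[[cv]]
      vals <- c(rnorm(n[1], p[1], p[2]), rep(NA_real_, n[2]))
      miss <- spec$missing[[cv]]
      if (!is.null(miss) && miss > 0) {
        drop <- runif(n[1]) < miss
        vals[seq_len(n[1])][drop] <- NA_real_
      }
      df[[cv]] <- vals
    }
    fib <- c(runif(n[1]) < spec$fibrosis_prevalence, rep(NA, n[2]))
    miss <- spec$missing$fibrosis_hrct
    if (!is.null(miss) && miss > 0) {
      drop <- runif(n[1]) < miss
      fib[seq_len(n[1])][drop] <- NA
    }
    df$fibrosis_hrct <- fib
    cohort_table(df)
  })
}

#' Generate a complete synthetic subject bundle
#'
#' Builds every input the per-subject pipeline consumes — first-pass series
#' with PA/LA ROIs, pulmonary trunk and vein flow curves, lung mask stack,
#' LV/RV end-diastolic and end-systolic stacks, demographics — from one set
#' of ground-truth parameters. Mask stacks use slab geometry so their
#' analytic volumes are exact and the end-to-end error budget is dominated by
#' the bolus and flow stages. The returned `truth` element carries every
#' generator parameter plus the implied PBV and PBVI.
#'
#' @param seed integer RNG seed shared (with fixed offsets) by all noisy
#'   generators.
#' @param ptt_true pulmonary transit time, s.
#' @param sv_true pulmonary-trunk stroke volume, mL.
#' @param hr_bpm heart rate, beats/min.
#' @param pbvv_true pulmonary blood volume variation, mL.
#' @param lung_volume_ml lung volume, mL.
#' @param lv_edv,lv_esv,rv_edv,rv_esv ventricular volumes, mL.
#' @param height_cm,weight_kg demographics for BSA.
#' @param bolus_noise voxel noise fraction for the first-pass series.
#' @param flow_noise flow noise SD in mL/s.
#' @param n_veins number of pulmonary veins.
#' @param group `"patient"` or `"control"`.
#' @param id subject identifier.
#'
#' @return A list of class `subject_bundle` with elements `series`, `roi_pa`,
#'   `roi_la`, `arterial`, `venous`, `lung`, `lv_ed`, `lv_es`, `rv_ed`,
#'   `rv_es`, `height_cm`, `weight_kg`, `hr_bpm`, `covariates`, `group`,
#'   `id`, `truth`.
#' @export
gen_subject_bundle <- function(seed = NULL, ptt_true = 7, sv_true = 70,
                               hr_bpm = 70, pbvv_true = 32,
                               lung_volume_ml = 3500,
                               lv_edv = 150, lv_esv = 60,
                               rv_edv = 160, rv_esv = 72,
                               height_cm = 175, weight_kg = 75,
                               bolus_noise = 0.02, flow_noise = 2,
                               n_veins = 4L, group = "patient",
                               id = "synthetic_01") {
  seed_b <- if (is.null(seed)) NULL else seed
  seed_f <- if (is.null(seed)) NULL else seed + 1L
  fp <- gen_first_pass_series(
    bolus_ground_truth(ptt_true, noise_sigma = bolus_noise, seed = seed_b))
  fl <- gen_flow_set(
    flow_ground_truth(sv_true, hr = hr_bpm, pbvv_true = pbvv_true,
                      n_veins = n_veins, noise_sigma = flow_noise,
                      seed = seed_f))
  lung <- slab_stack_for_volume(lung_volume_ml, n_slices = 55L,
                                pixel_spacing = 1.4, slice_thickness = 5,
                                label = "lung")
  mk_vent <- function(vol, lab) {
    slab_stack_for_volume(vol, n_slices = 12L, pixel_spacing = 1.4,
                          slice_thickness = 8, label = lab)
  }
  truth <- list(
    ptt_true = ptt_true, sv_true = sv_true, hr_bpm = hr_bpm,
    pbvv_true = pbvv_true,
    co_true = cardiac_output(sv_true, hr_bpm),
    lung_volume_ml = attr(lung, "volume_true_ml"),
    pbv_true = compute_pbv(ptt_true, cardiac_output(sv_true, hr_bpm)),
    bolus = fp$truth, flow = fl$truth
  )
  truth$pbvi_true <- compute_pbvi(truth$pbv_true, truth$lung_volume_ml)
  structure(
    list(series = fp$series, roi_pa = fp$roi_pa, roi_la = fp$roi_la,
         arterial = fl$arterial, venous = fl$venous, lung = lung,
         lv_ed = mk_vent(lv_edv, "lv_endo"), lv_es = mk_vent(lv_esv, "lv_endo"),
         rv_ed = mk_vent(rv_edv, "rv_endo"), rv_es = mk_vent(rv_esv, "rv_endo"),
         height_cm = height_cm, weight_kg = weight_kg, hr_bpm = hr_bpm,
         covariates = list(), group = group, id = id, truth = truth),
    class = "subject_bundle"
  )
}

# Slab stack whose voxel count best approximates the requested volume; the
# residual rounding error is below one voxel volume.
slab_stack_for_volume <- function(volume_ml, n_slices, pixel_spacing,
                                  slice_thickness, label) {
  voxel_ml <- pixel_spacing^2 * slice_thickness / 1000
  n_vox <- round(volume_ml / voxel_ml)
  base <- n_vox %/% n_slices
  extra <- n_vox %% n_slices
  vps <- rep(base, n_slices) + c(rep(1L, extra), rep(0L, n_slices - extra))
  gen_mask_stack("slab", n_slices = n_slices, voxels_per_slice = vps,
                 pixel_spacing = pixel_spacing,
                 slice_thickness = slice_thickness, label = label)
}
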