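# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: plain loops and textbook formulas only.

# Discrete first moment by an explicit loop (rectangle weighting).
centroid_bruteforce <- function(times, intensities) {
  num <- 0
  den <- 0
  for (i in seq_along(times)) {
    num <- num + times[i] * intensities[i]
    den <- den + intensities[i]
  }
  num / den
}

# Two-sided permutation p value for a two-group mean difference. For two
# groups the permutation ordering of |mean difference| is the same as that of
# the pooled |t|, so this is an oracle for the pooled t-test p.
permutation_p <- function(a, b, n_perm = 10000L) {
  pool <- c(a, b)
  n1 <- length(a)
  obs <- abs(mean(a) - mean(b))
  hits <- 0L
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool), n1)
    d <- abs(mean(pool[idx]) - mean(pool[-idx]))
    if (d >= obs - 1e-12) hits <- hits + 1L
  }
  hits / n_perm
}

# Ellipsoid volume by voxel counting on an n-times finer grid than the
# requested geometry (independent of gen_mask_stack's internals).
ellipsoid_count_volume <- function(semi_axes, h_mm) {
  a <- semi_axes[1]; b <- semi_axes[2]; cc <- semi_axes[3]
  xs <- seq(-a - h_mm, a + h_mm, by = h_mm)
  ys <- seq(-b - h_mm, b + h_mm, by = h_mm)
  zs <- seq(-cc - h_mm, cc + h_mm, by = h_mm)
  f <- outer(outer((xs / a)^2, (ys / b)^2, `+`), (zs / cc)^2, `+`)
  sum(f <= 1) * h_mm^3 / 1000
}

# Baseline-corrected curves for a synthetic first-pass experiment, the usual
# preamble of PTT tests.
ptt_from_bundle <- function(fp, n_pre = 5, window_mode = "full") {
  tic_pa <- baseline_correct(extract_tic(fp$series, fp$roi_pa), n_pre)
  tic_la <- baseline_correct(extract_tic(fp$series, fp$roi_la), n_pre)
  suppressWarnings(compute_ptt(
    tic_pa, tic_la,
    window_pa = analysis_window(tic_pa, window_mode),
    window_la = analysis_window(tic_la, window_mode)
  ))$ptt_s
}

# Cyclic rotation of a flow curve's samples: the same physical cycle observed
# from a different start point.
rotate_flow <- function(curve, k) {
  n <- length(curve$times)
  k <- ((k - 1L) %% n) + 1L
  idx <- c(seq(k, n), seq_len(k - 1L))
  t0 <- curve$times[k]
  t_new <- (curve$times[idx] - t0) %% curve$cycle_length
  flow_curve(sort(t_new), curve$flow[idx][order(t_new)],
             vessel = curve$vessel, cycle_length = curve$cycle_length)
}
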