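#' Phase-contrast flow curve
#'
#' Instantaneous volumetric flow versus time over one cardiac cycle, as
#' measured by velocity-encoded (phase-contrast) CMR in a vessel cross
#' section.
#'
#' @param times sample times in seconds, strictly increasing, all within
#'   `[0, cycle_length)`.
#' @param flow flow in mL/s, same length as `times`; at least 8 samples.
#' @param vessel vessel label, e.g. `"pulmonary_trunk"`, `"aorta"`,
#'   `"pulmonary_vein_1"`.
#' @param cycle_length cardiac cycle length (RR interval) in seconds.
#'
#' @return An object of class `flow_curve`.
#' @export
flow_curve <- function(times, flow, vessel = "pulmonary_trunk", cycle_length) {
  times <- as.numeric(times)
  flow <- as.numeric(flow)
  if (length(times) != length(flow))
    stop("`times` and `flow` must have equal length")
  if (length(times) < 8L) stop("a flow curve needs at least 8 samples")
  if (any(diff(times) <= 0)) stop("`times` must be strictly increasing")
  cycle_length <- as.numeric(cycle_length)
  if (!is.finite(cycle_length) || cycle_length <= 0)
    stop("`cycle_length` must be positive")
  if (times[1] < 0 || times[length(times)] >= cycle_length)
    stop("`times` must lie within [0, cycle_length)")
  structure(
    list(times = times, flow = flow, vessel = as.character(vessel),
         cycle_length = cycle_length),
    class = "flow_curve"
  )
}

#' @export
print.flow_curve <- function(x, ...) {
  cat(sprintf("<flow curve> %s: %d samples / %.3g s cycle, SV = %.1f mL\n",
              x$vessel, length(x$times), x$cycle_length, cycle_volume(x)))
  invisible(x)
}

#' Stroke volume: integral of flow over one cardiac cycle
#'
#' Integrates the flow curve over the full cycle with a cyclic trapezoidal
#' rule: the curve is closed by wrapping the first sample to
#' `times[1] + cycle_length` before integrating, so the periodic boundary is
#' handled without extrapolation.
#'
#' @param flow a [flow_curve()].
#'
#' @return Cycle volume (stroke volume for the pulmonary trunk or aorta)
#'   in mL.
#' @export
cycle_volume <- function(flow) {
  stopifnot(inherits(flow, "flow_curve"))
  t <- c(flow$times, flow$times[1] + flow$cycle_length)
  q <- c(flow$flow, flow$flow[1])
  trapz(t, q)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Cardiac output from stroke volume and heart rate
#'
#' @param sv stroke volume in mL.
#' @param hr heart rate in beats/min, > 0.
#'
#' @return Cardiac output in L/min (`sv * hr / 1000`).
#' @export
cardiac_output <- function(sv, hr) {
  if (any(hr <= 0)) stop("heart rate must be positive")
  sv * hr / 1000
}

#' Net pulmonary flow: arterial inflow minus summed venous outflow
#'
#' All curves are resampled to a common uniform grid over one cycle by linear
#' interpolation with cyclic boundary handling; the venous curves are summed
#' and subtracted from the arterial curve. Cycle lengths must agree within
#' `tol` (retrospectively gated acquisitions are reconstructed to a common RR
#' interval, so 2% is the default).
#'
#' @param arterial pulmonary-trunk [flow_curve()].
#' @param venous list of pulmonary-vein [flow_curve()]s (1-5 veins).
#' @param n_out number of points of the uniform output grid (default 128).
#' @param tol relative cycle-length mismatch tolerance (default 0.02).
#'
#' @return A [flow_curve()] of the net flow on the uniform grid, with the
#'   arterial cycle length.
#' @export
net_flow <- function(arterial, venous, n_out = 128L, tol = 0.02) {
  stopifnot(inherits(arterial, "flow_curve"))
  if (inherits(venous, "flow_curve")) venous <- list(venous)
  if (!length(venous) || !all(vapply(venous, inherits, logical(1), "flow_curve")))
    stop("`venous` must be a list of flow_curve objects")
  T_ref <- arterial$cycle_length
  rel <- vapply(venous, function(v) abs(v$cycle_length - T_ref) / T_ref,
                numeric(1))
  if (any(rel > tol)) {
    bad <- vapply(venous[rel > tol], `[[`, character(1), "vessel")
    stop(sprintf("cycle length mismatch beyond %.1f%% for: %s",
                 100 * tol, paste(bad, collapse = ", ")))
  }
  same_grid <- all(vapply(venous, function(v) {
    length(v$times) == length(arterial$times) &&
      max(abs(v$times - arterial$times)) <= 1e-9 * T_ref &&
      abs(v$cycle_length - T_ref) <= 1e-9 * T_ref
  }, logical(1)))
  if (same_grid) {
    # identical sampling: subtract on the native grid, no interpolation
    qv <- Reduce(`+`, lapply(venous, `[[`, "flow"))
    return(flow_curve(arterial$times, arterial$flow - qv,
                      vessel = "net_pulmonary", cycle_length = T_ref))
  }
  grid <- seq(0, T_ref, length.out = n_out + 1L)[seq_len(n_out)]
  qa <- resample_cyclic(arterial, grid, T_ref)
  qv <- Reduce(`+`, lapply(venous, resample_cyclic, grid = grid, T_ref = T_ref))
  flow_curve(grid, qa - qv, vessel = "net_pulmonary", cycle_length = T_ref)
}

# Linear interpolation on [0, T) treating the curve as periodic: the sample
# set is extended one period to each side before interpolating.
resample_cyclic <- function(curve, grid, T_ref) {
  t <- curve$times * (T_ref / curve$cycle_length)  # rescale to reference RR
  q <- curve$flow
  t_ext <- c(t - T_ref, t, t + T_ref)
  q_ext <- rep(q, 3L)
  approx(t_ext, q_ext, xout = grid)$y
}

#' Cumulative pulmonary blood volume curve
#'
#' Running (cumulative trapezoidal) integral of the net flow from cycle
#' start, i.e. the blood volume stored in the pulmonary circulation relative
#' to its value at the start of the cycle. With measurement noise the curve
#' does not close exactly (`V(T) != V(0) = 0`); with `drift_correct = TRUE` a
#' linear ramp is removed so that it does, and the removed closure error is
#' reported as a quality-control metric.
#'
#' @param net a net [flow_curve()], usually from [net_flow()].
#' @param drift_correct remove the linear drift so the curve closes
#'   (default `TRUE`; turn off for noise-free validation).
#'
#' @return An object of class `volume_curve`: `times` (including the cycle
#'   end `T`), `cumulative_volume` in mL (starting at 0), `cycle_length`,
#'   and `drift_ml` (the closure error removed; 0 if not corrected).
#' @export
cumulative_volume <- function(net, drift_correct = TRUE) {
  stopifnot(inherits(net, "flow_curve"))
  t <- c(net$times, net$times[1] + net$cycle_length)
  q <- c(net$flow, net$flow[1])
  v <- c(0, cumsum(diff(t) * (head(q, -1) + tail(q, -1)) / 2))
  t <- t - t[1]
  drift <- v[length(v)]
  if (drift_correct) {
    v <- v - drift * t / t[length(t)]
  }
  structure(
    list(times = t, cumulative_volume = v, cycle_length = net$cycle_length,
         drift_ml = if (drift_correct) drift else 0),
    class = "volume_curve"
  )
}

#' Pulmonary blood volume variation (PBVV)
#'
#' The difference between the maximum and the minimum of the cumulative
#' pulmonary volume curve over the cardiac cycle — the peak-to-trough
#' excursion of blood stored in the pulmonary circulation. Always >= 0.
#'
#' @param vol a [cumulative_volume()] curve.
#'
#' @return PBVV in mL.
#' @export
compute_pbvv <- function(vol) {
  stopifnot(inherits(vol, "volume_curve"))
  max(vol$cumulative_volume) - min(vol$cumulative_volume)
}

#' PBVV normalised to pulmonary-trunk stroke volume
#'
#' `100 * pbvv / sv`, in percent. The denominator is always the
#' pulmonary-trunk stroke volume (not aortic): the ratio is a global index of
#' pulmonary vascular distensibility — the fraction of each stroke volume
#' transiently stored in the distended pulmonary vessels (Windkessel effect).
#'
#' @param pbvv pulmonary blood volume variation in mL.
#' @param sv_pt pulmonary-trunk stroke volume in mL, > 0.
#'
#' @return PBVV/SV in percent.
#' @export
pbvv_sv_ratio <- function(pbvv, sv_pt) {
  if (any(sv_pt <= 0)) stop("pulmonary-trunk stroke volume must be positive")
  100 * pbvv / sv_pt
}
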