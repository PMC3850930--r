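#' Pipeline configuration
#'
#' All analysis choices of the per-subject pipeline in one validated object.
#' Defaults follow the package's standard analysis: rectangle-rule centroid,
#' 5 pre-contrast baseline frames, analysis window ending at the first local
#' minimum after the peak (recirculation cutoff), drift-corrected cumulative
#' volume, 128-point resampling of flow curves.
#'
#' @param centroid_rule quadrature for [curve_centroid()]: `"rectangle"` or
#'   `"trapezoid"`.
#' @param n_pre pre-contrast baseline frames for [baseline_correct()].
#' @param clip_negative clip negative baseline-corrected intensities.
#' @param window_mode recirculation handling for [analysis_window()]:
#'   `"local_min"`, `"full"` or `"gamma_fit"`.
#' @param drift_correct drift-correct the cumulative volume curve.
#' @param resample_n uniform grid size for [net_flow()].
#' @param cycle_tol relative cycle-length mismatch tolerance.
#' @param seed optional integer seed recorded with outputs.
#' @param log_level `"quiet"` or `"info"`.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(centroid_rule = c("rectangle", "trapezoid"),
                            n_pre = 5L, clip_negative = TRUE,
                            window_mode = c("local_min", "full", "gamma_fit"),
                            drift_correct = TRUE, resample_n = 128L,
                            cycle_tol = 0.02, seed = NULL,
                            log_level = c("quiet", "info")) {
  cfg <- list(
    centroid_rule = match.arg(centroid_rule),
    n_pre = as.integer(n_pre),
    clip_negative = isTRUE(clip_negative),
    window_mode = match.arg(window_mode),
    drift_correct = isTRUE(drift_correct),
    resample_n = as.integer(resample_n),
    cycle_tol = as.numeric(cycle_tol),
    seed = if (is.null(seed)) NULL else as.integer(seed),
    log_level = match.arg(log_level)
  )
  if (cfg$n_pre < 1L) stop("n_pre must be >= 1")
  if (cfg$resample_n < 16L) stop("resample_n must be >= 16")
  if (cfg$cycle_tol <= 0) stop("cycle_tol must be positive")
  structure(cfg, class = "pipeline_config")
}

#' Write / read a pipeline configuration as YAML
#'
#' Round-trip stable: reading a written config reproduces the object.
#'
#' @param cfg a [pipeline_config()].
#' @param path `.yaml` file path.
#' @return `write_config`: `path`, invisibly. `read_config`: a
#'   [pipeline_config()].
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "pipeline_config"))
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(pipeline_config, raw)
}

#' Short content hash of a pipeline configuration
#'
#' FNV-1a hash of the canonical JSON form; recorded in every output record so
#' that identical config + inputs can be recognised as producing identical
#' outputs.
#'
#' @param cfg a [pipeline_config()].
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  s <- as.character(jsonlite::toJSON(unclass(cfg), auto_unbox = TRUE,
                                     digits = NA, null = "null"))
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    # xor with a byte touches only the low 8 bits (keeps h a double < 2^32)
    h <- (h - h %% 256) + bitwXor(as.integer(h %% 256), as.integer(b %% 256))
    # multiply by the FNV prime mod 2^32, exact in doubles via 16-bit split
    lo <- (h %% 65536) * 16777619
    hi <- (h %/% 65536) * 16777619 + lo %/% 65536
    h <- ((hi %% 65536) * 65536 + lo %% 65536)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

log_info <- function(cfg, fmt, ...) {
  if (identical(cfg$log_level, "info"))
    message(sprintf(paste0("[pulmocmr] ", fmt), ...))
  invisible(NULL)
}

#' Run the full per-subject pipeline
#'
#' Executes, in order: time-intensity curve extraction and baseline
#' correction, PTT by the centroid method; stroke volume and cardiac output
#' from the pulmonary-trunk flow curve; PBV = PTT x CO; planimetric lung
#' volume and PBVI; net flow, cumulative volume and PBVV with the PBVV/SV
#' ratio; LV/RV volumetry with Mosteller BSA indexing. Each stage is
#' isolated: a failing or absent stage leaves its fields `NA`, adds a flag
#' naming the stage, and does not prevent downstream stages that do not
#' depend on it (a bundle without venous curves still gets PBV and PBVI).
#' The result is deterministic given inputs and config.
#'
#' @param bundle a `subject_bundle` (from [gen_subject_bundle()],
#'   [read_subject_bundle()], or assembled by hand).
#' @param cfg a [pipeline_config()].
#'
#' @return A list of class `subject_record` with fields `id`, `group`,
#'   `ptt_s`, `sv_ml`, `hr_bpm`, `co_l_min`, `pbv_ml`, `lung_volume_ml`,
#'   `pbvi_pct`, `pbvv_ml`, `pbvv_sv_pct`, `lv_edv_ml`, `lv_esv_ml`,
#'   `lv_sv_ml`, `lv_ef_pct`, `rv_edv_ml`, `rv_esv_ml`, `rv_sv_ml`,
#'   `rv_ef_pct`, `bsa_m2`, `sv_i_ml_m2`, `height_cm`, `weight_kg`,
#'   covariates, and `qc` (config hash, drift, windows, flags).
#' @export
run_subject <- function(bundle, cfg = pipeline_config()) {
  stopifnot(inherits(bundle, "subject_bundle"),
            inherits(cfg, "pipeline_config"))
  rec <- list(id = bundle$id, group = bundle$group,
              hr_bpm = bundle$hr_bpm,
              height_cm = bundle$height_cm, weight_kg = bundle$weight_kg)
  na_fields <- c("ptt_s", "sv_ml", "co_l_min", "pbv_ml", "lung_volume_ml",
                 "pbvi_pct", "pbvv_ml", "pbvv_sv_pct",
                 "lv_edv_ml", "lv_esv_ml", "lv_sv_ml", "lv_ef_pct",
                 "rv_edv_ml", "rv_esv_ml", "rv_sv_ml", "rv_ef_pct",
                 "bsa_m2", "sv_i_ml_m2")
  rec[na_fields] <- NA_real_
  qc <- list(config_hash = config_hash(cfg), flags = character(0),
             drift_ml = NA_real_)
  # each stage returns a named list of results, or NULL on failure (which is
  # recorded as a QC flag and does not abort the remaining stages)
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      qc$flags <<- c(qc$flags, paste0("stage_failed:", name))
      qc[[paste0("error_", name)]] <<- conditionMessage(e)
      NULL
    })
  }

  # --- pulmonary transit time -------------------------------------------
  res <- stage("ptt", function() {
    if (is.null(bundle$series)) stop("no first-pass series")
    tic_pa <- baseline_correct(extract_tic(bundle$series, bundle$roi_pa),
                               cfg$n_pre, clip_negative = cfg$clip_negative)
    tic_la <- baseline_correct(extract_tic(bundle$series, bundle$roi_la),
                               cfg$n_pre, clip_negative = cfg$clip_negative)
    if (cfg$window_mode == "gamma_fit") {
      c_pa <- fit_gamma_variate(tic_pa)$centroid
      c_la <- fit_gamma_variate(tic_la)$centroid
      list(ptt_s = c_la - c_pa, window_pa = "gamma_fit",
           window_la = "gamma_fit", flags = character(0))
    } else {
      w_pa <- analysis_window(tic_pa, cfg$window_mode)
      w_la <- analysis_window(tic_la, cfg$window_mode)
      ptt <- suppressWarnings(
        compute_ptt(tic_pa, tic_la, window_pa = w_pa, window_la = w_la,
                    rule = cfg$centroid_rule))
      list(ptt_s = ptt$ptt_s, window_pa = w_pa, window_la = w_la,
           flags = ptt$flags)
    }
  })
  if (!is.null(res)) {
    rec$ptt_s <- res$ptt_s
    qc$window_pa <- res$window_pa
    qc$window_la <- res$window_la
    qc$flags <- c(qc$flags, res$flags)
    log_info(cfg, "PTT = %.3f s", rec$ptt_s)
  }

  # --- stroke volume, cardiac output ------------------------------------
  res <- stage("flow", function() {
    if (is.null(bundle$arterial)) stop("no arterial flow curve")
    sv <- cycle_volume(bundle$arterial)
    hr <- bundle$hr_bpm
    if (is.null(hr) || is.na(hr)) hr <- 60 / bundle$arterial$cycle_length
    list(sv_ml = sv, hr_bpm = hr, co_l_min = cardiac_output(sv, hr))
  })
  if (!is.null(res)) {
    rec$sv_ml <- res$sv_ml
    rec$hr_bpm <- res$hr_bpm
    rec$co_l_min <- res$co_l_min
    log_info(cfg, "SV = %.1f mL, CO = %.2f L/min", rec$sv_ml, rec$co_l_min)
  }

  # --- PBV ---------------------------------------------------------------
  res <- stage("pbv", function() {
    if (is.na(rec$ptt_s) || is.na(rec$co_l_min)) stop("PTT or CO unavailable")
    compute_pbv(rec$ptt_s, rec$co_l_min)
  })
  if (!is.null(res)) rec$pbv_ml <- res

  # --- lung volume and PBVI ---------------------------------------------
  res <- stage("lung", function() {
    if (is.null(bundle$lung)) stop("no lung mask stack")
    planimetric_volume(bundle$lung)
  })
  if (!is.null(res)) rec$lung_volume_ml <- res
  res <- stage("pbvi", function() {
    if (is.na(rec$pbv_ml) || is.na(rec$lung_volume_ml))
      stop("PBV or lung volume unavailable")
    compute_pbvi(rec$pbv_ml, rec$lung_volume_ml)
  })
  if (!is.null(res)) rec$pbvi_pct <- res

  # --- PBVV --------------------------------------------------------------
  res <- stage("pbvv", function() {
    if (is.null(bundle$arterial) || !length(bundle$venous))
      stop("arterial and venous flow curves required")
    net <- net_flow(bundle$arterial, bundle$venous,
                    n_out = cfg$resample_n, tol = cfg$cycle_tol)
    vol <- cumulative_volume(net, drift_correct = cfg$drift_correct)
    list(pbvv_ml = compute_pbvv(vol), drift_ml = vol$drift_ml)
  })
  if (!is.null(res)) {
    rec$pbvv_ml <- res$pbvv_ml
    qc$drift_ml <- res$drift_ml
    if (!is.na(rec$sv_ml))
      rec$pbvv_sv_pct <- pbvv_sv_ratio(rec$pbvv_ml, rec$sv_ml)
    log_info(cfg, "PBVV = %.1f mL (drift %.2f mL)", rec$pbvv_ml, res$drift_ml)
  }

  # --- BSA and ventricular volumetry ------------------------------------
  res <- stage("bsa", function() {
    if (is.null(bundle$height_cm) || is.null(bundle$weight_kg))
      stop("height/weight unavailable")
    bsa_mosteller(bundle$height_cm, bundle$weight_kg)
  })
  if (!is.null(res)) {
    rec$bsa_m2 <- res
    if (!is.na(rec$sv_ml)) rec$sv_i_ml_m2 <- rec$sv_ml / rec$bsa_m2
  }
  for (prefix in c("lv", "rv")) {
    ed <- bundle[[paste0(prefix, "_ed")]]
    es <- bundle[[paste0(prefix, "_es")]]
    res <- stage(prefix, function() {
      if (is.null(ed) || is.null(es)) stop("missing ", prefix, " stacks")
      bsa <- if (is.na(rec$bsa_m2)) NULL else rec$bsa_m2
      suppressWarnings(ventricular_metrics(ed, es, bsa = bsa))
    })
    if (!is.null(res)) {
      rec[[paste0(prefix, "_edv_ml")]] <- res$edv_ml
      rec[[paste0(prefix, "_esv_ml")]] <- res$esv_ml
      rec[[paste0(prefix, "_sv_ml")]] <- res$sv_ml
      rec[[paste0(prefix, "_ef_pct")]] <- res$ef_pct
      qc$flags <- c(qc$flags, res$flags)
    }
  }

  for (cv in names(bundle$covariates)) rec[[cv]] <- bundle$covariates[[cv]]
  rec$qc <- qc
  structure(rec, class = "subject_record")
}

#' @export
print.subject_record <- function(x, ...) {
  cat(sprintf("<subject record> %s (%s)\n", x$id, x$group))
  fmt <- function(v, u) if (is.null(v) || is.na(v)) "NA" else sprintf("%.1f %s", v, u)
  cat(sprintf("  PTT %s | SV %s | CO %s\n", fmt(x$ptt_s, "s"),
              fmt(x$sv_ml, "mL"), fmt(x$co_l_min, "L/min")))
  cat(sprintf("  PBV %s | lung %s | PBVI %s | PBVV %s | PBVV/SV %s\n",
              fmt(x$pbv_ml, "mL"), fmt(x$lung_volume_ml, "mL"),
              fmt(x$pbvi_pct, "%"), fmt(x$pbvv_ml, "mL"),
              fmt(x$pbvv_sv_pct, "%")))
  if (length(x$qc$flags)) cat("  flags:", paste(x$qc$flags, collapse = ", "), "\n")
  invisible(x)
}

#' Run the pipeline over a cohort of subject bundles
#'
#' Runs [run_subject()] on every bundle, isolating per-subject failures
#' (a failed subject contributes a record of `NA`s and a flag, and does not
#' abort the batch), assembles a [cohort_table()], and computes group
#' summaries for the requested metrics. An all-subject failure is an error.
#'
#' @param bundles list of `subject_bundle`s.
#' @param cfg a [pipeline_config()].
#' @param metrics metric columns to summarise (default: the headline
#'   pulmonary and ventricular metrics).
#'
#' @return List: `records` (per-subject records), `cohort`
#'   ([cohort_table()]), `summaries` (from [summarize_groups()], `NULL` if a
#'   group has fewer than 2 usable subjects).
#' @export
run_cohort <- function(bundles, cfg = pipeline_config(),
                       metrics = c("pbvi_pct", "pbv_ml", "pbvv_ml",
                                   "pbvv_sv_pct", "sv_i_ml_m2")) {
  stopifnot(length(bundles) >= 1L)
  records <- lapply(bundles, function(b) {
    tryCatch(run_subject(b, cfg), error = function(e) {
      structure(list(id = b$id, group = b$group,
                     qc = list(flags = paste0("subject_failed: ",
                                              conditionMessage(e)))),
                class = "subject_record")
    })
  })
  failed <- vapply(records, function(r)
    any(startsWith(r$qc$flags, "subject_failed")), logical(1))
  if (all(failed)) stop("all subjects failed: ",
                        records[[1]]$qc$flags[1])
  scalar_fields <- c("id", "group", "ptt_s", "sv_ml", "hr_bpm", "co_l_min",
                     "pbv_ml", "lung_volume_ml", "pbvi_pct", "pbvv_ml",
                     "pbvv_sv_pct", "lv_edv_ml", "lv_esv_ml", "lv_sv_ml",
                     "lv_ef_pct", "rv_edv_ml", "rv_esv_ml", "rv_sv_ml",
                     "rv_ef_pct", "bsa_m2", "sv_i_ml_m2")
  rows <- lapply(records, function(r) {
    vals <- lapply(scalar_fields, function(f) {
      v <- r[[f]]
      if (is.null(v)) NA else v
    })
    names(vals) <- scalar_fields
    as.data.frame(vals, stringsAsFactors = FALSE)
  })
  cohort <- cohort_table(do.call(rbind, rows))
  summaries <- NULL
  tab <- table(cohort$group)
  if (length(tab) == 2L && all(tab >= 2)) {
    present <- metrics[vapply(metrics, function(m)
      sum(!is.na(cohort[[m]][cohort$group == "patient"])) >= 2 &&
        sum(!is.na(cohort[[m]][cohort$group == "control"])) >= 2,
      logical(1))]
    if (length(present))
      summaries <- summarize_groups(cohort, present)
  }
  list(records = records, cohort = cohort, summaries = summaries)
}
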