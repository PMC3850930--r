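# File formats: flow curves and cohorts as CSV, images/masks as NIfTI,
# records and ground truth as JSON, pipeline config as YAML. All round-trip
# to machine precision for the values the pipeline consumes.

#' Write / read a flow curve as CSV
#'
#' Columns `time_s,flow_ml_s`, preceded by comment header lines
#' `# vessel:` and `# cycle_length_s:`.
#'
#' @param curve a [flow_curve()].
#' @param path output path.
#' @return `write_flow_csv`: `path`, invisibly. `read_flow_csv`: a
#'   [flow_curve()].
#' @export
write_flow_csv <- function(curve, path) {
  stopifnot(inherits(curve, "flow_curve"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# vessel: %s", curve$vessel),
               sprintf("# cycle_length_s: %.17g", curve$cycle_length)), con)
  write.csv(data.frame(time_s = curve$times, flow_ml_s = curve$flow),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_flow_csv
#' @export
read_flow_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  get_field <- function(key) {
    line <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(line)) stop("flow CSV is missing '# ", key, ":' header: ", path)
    trimws(sub(paste0("^#\\s*", key, ":"), "", line[1]))
  }
  vessel <- get_field("vessel")
  cycle_length <- as.numeric(get_field("cycle_length_s"))
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "flow_ml_s") %in% names(df)))
    stop("flow CSV must have columns time_s, flow_ml_s: ", path)
  flow_curve(df$time_s, df$flow_ml_s, vessel = vessel,
             cycle_length = cycle_length)
}

#' Write / read a time-intensity curve as CSV
#'
#' Columns `time_s,intensity_au`, with `# label:` and `# baseline_frames:`
#' comment headers.
#'
#' @param x a [tic()].
#' @param path output path.
#' @return `write_tic_csv`: `path`, invisibly. `read_tic_csv`: a [tic()].
#' @export
write_tic_csv <- function(x, path) {
  stopifnot(inherits(x, "tic"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# label: %s", x$label),
               sprintf("# baseline_frames: %d", x$baseline_frames)), con)
  write.csv(data.frame(time_s = x$times, intensity_au = x$intensities),
            con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tic_csv
#' @export
read_tic_csv <- function(path) {
  hdr <- readLines(path, n = 10L)
  hdr <- hdr[startsWith(hdr, "#")]
  label <- "other"
  baseline_frames <- 0L
  l <- grep("^#\\s*label:", hdr, value = TRUE)
  if (length(l)) label <- trimws(sub("^#\\s*label:", "", l[1]))
  b <- grep("^#\\s*baseline_frames:", hdr, value = TRUE)
  if (length(b))
    baseline_frames <- as.integer(trimws(sub("^#\\s*baseline_frames:", "", b[1])))
  df <- read.csv(path, comment.char = "#")
  if (!all(c("time_s", "intensity_au") %in% names(df)))
    stop("curve CSV must have columns time_s, intensity_au: ", path)
  tic(df$time_s, df$intensity_au, baseline_frames = baseline_frames,
      label = label)
}

#' Write / read a cohort table as CSV
#'
#' One row per subject, named metric columns, `group` column with values
#' `patient`/`control`.
#'
#' @param cohort a [cohort_table()].
#' @param path file path.
#' @return `write_cohort_csv`: `path`, invisibly. `read_cohort_csv`: a
#'   [cohort_table()].
#' @export
write_cohort_csv <- function(cohort, path) {
  write.csv(as.data.frame(cohort), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("id", "group") %in% names(df)))
    stop("cohort CSV must have `id` and `group` columns: ", path)
  if ("fibrosis_hrct" %in% names(df))
    df$fibrosis_hrct <- as.logical(df$fibrosis_hrct)
  cohort_table(df)
}

#' Write / read a segmentation stack as NIfTI
#'
#' The mask is stored as a 3D volume with voxel geometry in the NIfTI
#' `pixdim` header; on reading, values other than 0/1 are rejected. The
#' label and slice gap are not representable in a plain NIfTI header and
#' must be supplied on read.
#'
#' @param stack a [segmentation_stack()].
#' @param path `.nii` file path.
#' @param label,slice_gap metadata applied to the stack read back.
#' @return `write_mask_nifti`: `path`, invisibly. `read_mask_nifti`: a
#'   [segmentation_stack()].
#' @export
write_mask_nifti <- function(stack, path) {
  stopifnot(inherits(stack, "segmentation_stack"))
  img <- RNifti::asNifti(array(as.integer(stack$mask), dim = dim(stack$mask)))
  RNifti::pixdim(img) <- c(stack$pixel_spacing,
                           stack$slice_thickness + stack$slice_gap)
  RNifti::writeNifti(img, path, datatype = "int16")
  invisible(path)
}

#' @rdname write_mask_nifti
#' @export
read_mask_nifti <- function(path, label = "other", slice_gap = 0) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  if (length(dim(arr)) == 2L) arr <- array(arr, dim = c(dim(arr), 1L))
  if (!all(arr %in% c(0, 1)))
    stop("mask NIfTI contains values other than 0/1: ", path)
  pd <- RNifti::pixdim(img)
  if (length(pd) < 3L || is.na(pd[3]) || pd[3] <= 0) pd[3] <- 1
  segmentation_stack(arr, pixel_spacing = pd[1:2],
                     slice_thickness = pd[3] - slice_gap,
                     slice_gap = slice_gap, label = label)
}

#' Write / read a first-pass image series as NIfTI
#'
#' Stored as a 4D volume (rows x cols x 1 x frames) with the in-plane
#' spacing and frame interval in `pixdim`; frame times are reconstructed as
#' a uniform grid starting at 0, which is how the generator samples.
#'
#' @param series an [image_series()] with uniform frame spacing.
#' @param path `.nii` file path.
#' @return `write_series_nifti`: `path`, invisibly. `read_series_nifti`: an
#'   [image_series()].
#' @export
write_series_nifti <- function(series, path) {
  stopifnot(inherits(series, "image_series"))
  dt <- diff(series$frame_times)
  if (diff(range(dt)) > 1e-9 * mean(dt))
    stop("NIfTI export requires uniform frame spacing")
  d <- dim(series$data)
  img <- RNifti::asNifti(array(series$data, dim = c(d[1], d[2], 1L, d[3])))
  RNifti::pixdim(img) <- c(series$pixel_spacing, 1, mean(dt))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' @rdname write_series_nifti
#' @export
read_series_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) != 4L || d[3] != 1L)
    stop("expected a rows x cols x 1 x frames series: ", path)
  pd <- RNifti::pixdim(img)
  dt <- pd[4]
  image_series(array(arr, dim = d[c(1, 2, 4)]),
               frame_times = (seq_len(d[4]) - 1L) * dt,
               pixel_spacing = pd[1:2])
}

#' Write / read a subject record as JSON
#'
#' @param record a `subject_record` (see [run_subject()]).
#' @param path `.json` file path.
#' @return `write_record_json`: `path`, invisibly. `read_record_json`: the
#'   record list.
#' @export
write_record_json <- function(record, path) {
  jsonlite::write_json(unclass(record), path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_record_json
#' @export
read_record_json <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(rec, class = "subject_record")
}

#' Write a subject bundle to a directory
#'
#' Serialises every input of the per-subject pipeline into standard formats:
#' NIfTI for the image series and masks, CSV per flow curve, JSON for
#' demographics and (when present) the generator ground truth. The directory
#' can be read back with [read_subject_bundle()] or consumed by the `subject`
#' command of the CLI script.
#'
#' @param bundle a `subject_bundle` (see [gen_subject_bundle()]).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_subject_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "subject_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(...) file.path(dir, ...)
  write_series_nifti(bundle$series, p("series.nii"))
  write_roi <- function(roi, path) {
    stack <- segmentation_stack(roi$mask, bundle$series$pixel_spacing, 1)
    write_mask_nifti(stack, path)
  }
  write_roi(bundle$roi_pa, p("roi_pa.nii"))
  write_roi(bundle$roi_la, p("roi_la.nii"))
  write_flow_csv(bundle$arterial, p("flow_arterial.csv"))
  for (i in seq_along(bundle$venous))
    write_flow_csv(bundle$venous[[i]], p(sprintf("flow_vein_%d.csv", i)))
  for (m in c("lung", "lv_ed", "lv_es", "rv_ed", "rv_es"))
    if (!is.null(bundle[[m]])) write_mask_nifti(bundle[[m]], p(paste0(m, ".nii")))
  meta <- list(id = bundle$id, group = bundle$group,
               height_cm = bundle$height_cm, weight_kg = bundle$weight_kg,
               hr_bpm = bundle$hr_bpm, covariates = bundle$covariates,
               n_veins = length(bundle$venous))
  jsonlite::write_json(meta, p("demographics.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(bundle$truth)) {
    jsonlite::write_json(bundle$truth, p("ground_truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

#' Read a subject bundle from a directory
#'
#' @param dir a directory written by [write_subject_bundle()].
#' @return A `subject_bundle`.
#' @export
read_subject_bundle <- function(dir) {
  p <- function(...) file.path(dir, ...)
  must <- function(path) {
    if (!file.exists(path)) stop("subject bundle is missing ", basename(path))
    path
  }
  meta <- jsonlite::read_json(must(p("demographics.json")),
                              simplifyVector = TRUE)
  series <- read_series_nifti(must(p("series.nii")))
  read_roi <- function(path, label) {
    stack <- read_mask_nifti(path)
    roi_mask(stack$mask[, , 1], label)
  }
  venous <- list()
  i <- 1L
  while (file.exists(p(sprintf("flow_vein_%d.csv", i)))) {
    venous[[i]] <- read_flow_csv(p(sprintf("flow_vein_%d.csv", i)))
    i <- i + 1L
  }
  opt_mask <- function(name, label) {
    path <- p(paste0(name, ".nii"))
    if (file.exists(path)) read_mask_nifti(path, label = label) else NULL
  }
  truth <- NULL
  if (file.exists(p("ground_truth.json")))
    truth <- jsonlite::read_json(p("ground_truth.json"), simplifyVector = TRUE)
  structure(
    list(series = series,
         roi_pa = read_roi(must(p("roi_pa.nii")), "pulmonary_trunk"),
         roi_la = read_roi(must(p("roi_la.nii")), "left_atrium"),
         arterial = read_flow_csv(must(p("flow_arterial.csv"))),
         venous = venous,
         lung = opt_mask("lung", "lung"),
         lv_ed = opt_mask("lv_ed", "lv_endo"),
         lv_es = opt_mask("lv_es", "lv_endo"),
         rv_ed = opt_mask("rv_ed", "rv_endo"),
         rv_es = opt_mask("rv_es", "rv_endo"),
         height_cm = meta$height_cm, weight_kg = meta$weight_kg,
         hr_bpm = meta$hr_bpm,
         covariates = as.list(meta$covariates),
         group = meta$group, id = meta$id, truth = truth),
    class = "subject_bundle"
  )
}
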