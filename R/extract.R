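# Metadata extraction: one 18-feature record per DICOM series.

# DICOM tags of the directly-read features.
FEATURE_TAGS <- c(
  scanning_sequence   = "0018,0020",
  sequence_variant    = "0018,0021",
  scan_options        = "0018,0022",
  mr_acquisition_type = "0018,0023",
  sequence_name       = "0018,0024",
  image_type          = "0008,0008",
  repetition_time     = "0018,0080",
  echo_time           = "0018,0081",
  inversion_time      = "0018,0082",
  flip_angle          = "0018,1314",
  pixel_bandwidth     = "0018,0095",
  manufacturer        = "0008,0070"
)

# Vendor-specific private tags holding diffusion b-values.
B_VALUE_TAGS <- c(GE = "0043,1039", Philips = "2001,1003",
                  Siemens = "0019,100c")

# Canonical form of ImageOrientationPatient: each of the six direction
# cosines rounded to 2 decimals, backslash-joined. Tolerates float jitter
# while remaining a single categorical feature.
canonicalize_orientation <- function(cosines) {
  if (length(cosines) != 6 || anyNA(cosines)) return(NA_character_)
  paste(as.character(round(as.numeric(cosines), 2)), collapse = "\\")
}

# Split a backslash-joined DICOM multivalue into numerics.
split_numeric <- function(value) {
  if (is.null(value) || length(value) == 0) return(numeric(0))
  if (is.numeric(value)) return(as.numeric(value))
  if (!nzchar(value)) return(numeric(0))
  suppressWarnings(as.numeric(strsplit(value, "\\", fixed = TRUE)[[1]]))
}

# String tag value from one instance: NA if absent, "" if present but
# zero-length (EMPTY), else the trimmed string.
instance_string <- function(instance, key) {
  el <- instance[[key]]
  if (is.null(el)) return(NA_character_)
  as.character(el$value)[1]
}

# Scalar numeric tag value from one instance (first element of a
# multivalue); NA if absent, empty or unparseable.
instance_numeric <- function(instance, key) {
  el <- instance[[key]]
  if (is.null(el)) return(NA_real_)
  vals <- split_numeric(el$value)
  if (length(vals) == 0 || is.na(vals[1])) NA_real_ else vals[1]
}

# Per-instance diffusion b-value, routed by manufacturer (case-insensitive
# substring match). GE stores a multivalue whose first element is the
# b-value.
instance_b_value <- function(instance, manufacturer) {
  if (is.na(manufacturer)) return(NA_real_)
  vendor <- names(B_VALUE_TAGS)[
    vapply(names(B_VALUE_TAGS),
           function(v) grepl(v, manufacturer, ignore.case = TRUE),
           logical(1))]
  if (length(vendor) != 1) return(NA_real_)
  instance_numeric(instance, B_VALUE_TAGS[[vendor]])
}

#' Extract a metadata record from a DICOM series
#'
#' Reads every DICOM file in `series_path` (one series) and produces a
#' single 18-feature metadata record. Series-level tags come from the first
#' instance in filename-sorted order; a conflicting value in a later
#' instance raises a warning and is ignored. Echo times are collected
#' across all instances: when at least two distinct values exist, the two
#' smallest populate `multiecho_te1`/`multiecho_te2`. The diffusion
#' b-value is read from the vendor-specific private tag selected by the
#' manufacturer string — (0043,1039) for GE, (2001,1003) for Philips,
#' (0019,100c) for Siemens — and summarized as the maximum over instances.
#' Field of view is PixelSpacing times the matrix size. Absent tags yield
#' the missing marker (`NA`); present but zero-length string tags yield the
#' empty marker (`""`).
#'
#' @param series_path Directory containing the DICOM files of one series.
#' @return A one-row data.frame with the 20-column record layout
#'   (18 features plus `label`, `source_id`); `source_id` is the series
#'   directory name.
#' @seealso [read_dicom()], [emit_dicom_fixtures()]
#' @export
extract_record <- function(series_path) {
  if (!dir.exists(series_path)) {
    stop(sprintf("series directory '%s' does not exist", series_path),
         call. = FALSE)
  }
  files <- sort(list.files(series_path, full.names = TRUE))
  files <- files[!dir.exists(files)]
  if (length(files) == 0) {
    stop(sprintf("series directory '%s' contains no files", series_path),
         call. = FALSE)
  }
  instances <- lapply(files, read_dicom)

  record <- empty_record_table(1)
  first <- instances[[1]]

  # Series-level string tags: first instance wins; warn on conflicts.
  string_features <- setdiff(names(FEATURE_TAGS), NUMERIC_FEATURES)
  for (feat in string_features) {
    key <- FEATURE_TAGS[[feat]]
    vals <- vapply(instances, instance_string, character(1), key = key)
    record[[feat]] <- vals[1]
    if (length(unique(vals[!is.na(vals)])) > 1) {
      warning(sprintf(
        "series '%s': conflicting values for %s across instances; %s",
        series_path, feat, "keeping the first instance"), call. = FALSE)
    }
  }

  for (feat in intersect(names(FEATURE_TAGS), NUMERIC_FEATURES)) {
    record[[feat]] <- instance_numeric(first, FEATURE_TAGS[[feat]])
  }

  orient <- first[["0020,0037"]]
  record$image_orientation <- if (is.null(orient)) NA_character_ else {
    canonicalize_orientation(split_numeric(orient$value))
  }

  # FOV = PixelSpacing x matrix size. PixelSpacing is (row, col) spacing.
  spacing <- split_numeric(first[["0028,0030"]]$value)
  rows <- instance_numeric(first, "0028,0010")
  cols <- instance_numeric(first, "0028,0011")
  if (length(spacing) == 2 && !anyNA(spacing)) {
    if (!is.na(cols)) record$fov_x <- spacing[2] * cols
    if (!is.na(rows)) record$fov_y <- spacing[1] * rows
  }

  # Multi-echo: the two smallest distinct echo times across instances.
  tes <- vapply(instances, instance_numeric, numeric(1),
                key = FEATURE_TAGS[["echo_time"]])
  tes <- sort(unique(tes[!is.na(tes)]))
  if (length(tes) >= 2) {
    record$multiecho_te1 <- tes[1]
    record$multiecho_te2 <- tes[2]
  }

  bvals <- vapply(instances, instance_b_value, numeric(1),
                  manufacturer = record$manufacturer)
  if (any(!is.na(bvals))) record$b_value_max <- max(bvals, na.rm = TRUE)

  record$source_id <- basename(normalizePath(series_path, mustWork = FALSE))
  record
}

#' Extract records from a tree of DICOM series
#'
#' Treats every sub-directory of `root` as one series and extracts a record
#' from each. A series that fails to parse is logged and skipped; the
#' failure count is attached to the result.
#'
#' @param root Directory whose sub-directories are DICOM series.
#' @return Record table with one row per successfully extracted series and
#'   attribute `"failures"` (character vector of failed series with
#'   messages).
#' @export
extract_records <- function(root) {
  series_dirs <- sort(list.dirs(root, recursive = FALSE))
  records <- vector("list", length(series_dirs))
  failures <- character(0)
  for (i in seq_along(series_dirs)) {
    res <- tryCatch(extract_record(series_dirs[i]), error = function(e) e)
    if (inherits(res, "error")) {
      failures <- c(failures,
                    sprintf("%s: %s", series_dirs[i], conditionMessage(res)))
    } else {
      records[[i]] <- res
    }
  }
  out <- do.call(rbind, records[!vapply(records, is.null, logical(1))])
  if (is.null(out)) out <- empty_record_table(0)
  attr(out, "failures") <- failures
  out
}
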