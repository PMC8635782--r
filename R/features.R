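#' @keywords internal
#' @importFrom ranger ranger
"_PACKAGE"

# The 18 metadata features used by the classifier, in canonical column
# order: sequence-specific DICOM tags first, then timing parameters,
# spatial/contrast properties, computed geometry, and the manufacturer.
FEATURES <- c(
  "scanning_sequence",   # (0018,0020)
  "sequence_variant",    # (0018,0021)
  "scan_options",        # (0018,0022)
  "mr_acquisition_type", # (0018,0023)
  "sequence_name",       # (0018,0024)
  "image_type",          # (0008,0008), backslash-joined multivalue
  "repetition_time",     # (0018,0080), ms
  "echo_time",           # (0018,0081), ms
  "inversion_time",      # (0018,0082), ms
  "flip_angle",          # (0018,1314), degrees
  "pixel_bandwidth",     # (0018,0095), Hz/pixel
  "image_orientation",   # (0020,0037), canonicalized direction cosines
  "b_value_max",         # vendor-specific private tag, s/mm^2
  "fov_x",               # PixelSpacing[col] * Columns, mm
  "fov_y",               # PixelSpacing[row] * Rows, mm
  "multiecho_te1",       # smallest distinct echo time across instances, ms
  "multiecho_te2",       # second smallest distinct echo time, ms
  "manufacturer"         # (0008,0070)
)

NUMERIC_FEATURES <- c(
  "repetition_time", "echo_time", "inversion_time", "flip_angle",
  "pixel_bandwidth", "b_value_max", "fov_x", "fov_y",
  "multiecho_te1", "multiecho_te2"
)

CATEGORICAL_FEATURES <- setdiff(FEATURES, NUMERIC_FEATURES)

# Full record layout: 18 features, then the optional class label and a
# provenance identifier.
RECORD_COLUMNS <- c(FEATURES, "label", "source_id")

# Class names. The first seven are the "known" classes used for model
# building; ASL and Field Map are held out as unknown sequence types.
KNOWN_CLASSES   <- c("3DT1", "2D FLAIR", "PD/T2", "T2-star", "DTI",
                     "fMRI", "junk")
UNKNOWN_CLASSES <- c("ASL", "Field Map")

# Sentinel values used by the feature engineering step. Missing numerics
# become 1,000,000 (effectively infinity on the ms scales involved);
# missing categoricals become the category string "1000000"; empty (present
# but zero-length) strings become the category "empty".
MISSING_SENTINEL <- 1e6
MISSING_CATEGORY <- "1000000"
EMPTY_CATEGORY   <- "empty"

# Token used for missing values in the CSV/JSON-lines table dialect, so
# that a missing string and an empty string survive a round trip.
MISSING_TOKEN <- "__MISSING__"

#' Metadata feature names
#'
#' The 18 DICOM-derived metadata features used throughout the package, in
#' canonical column order.
#'
#' @return Character vector of 18 feature names.
#' @export
#' @examples
#' metadata_features()
metadata_features <- function() FEATURES

#' Feature kinds
#'
#' Maps each of the 18 features to its kind: `"numeric"` for the timing,
#' geometry and diffusion parameters, `"categorical"` for the string-valued
#' tags.
#'
#' @return Named character vector (`"numeric"` or `"categorical"`), one
#'   entry per feature.
#' @export
feature_kinds <- function() {
  kinds <- ifelse(FEATURES %in% NUMERIC_FEATURES, "numeric", "categorical")
  stats::setNames(kinds, FEATURES)
}

#' Class labels of the study design
#'
#' @return For `known_classes()`, the seven sequence types used to build
#'   models; for `unknown_classes()`, the two types held out to test
#'   unknown-sequence flagging.
#' @export
known_classes <- function() KNOWN_CLASSES

#' @rdname known_classes
#' @export
unknown_classes <- function() UNKNOWN_CLASSES

# Internal: validate that a data.frame has the record layout.
check_record_table <- function(records, arg = "records") {
  if (!is.data.frame(records)) {
    stop(sprintf("`%s` must be a data.frame of metadata records", arg),
         call. = FALSE)
  }
  missing_cols <- setdiff(FEATURES, names(records))
  if (length(missing_cols) > 0) {
    stop(sprintf("`%s` lacks feature column(s): %s", arg,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)
  }
  invisible(records)
}

# Internal: an empty record table with the canonical 20-column layout.
empty_record_table <- function(n = 0) {
  cols <- lapply(RECORD_COLUMNS, function(col) {
    if (col %in% NUMERIC_FEATURES) rep(NA_real_, n) else rep(NA_character_, n)
  })
  names(cols) <- RECORD_COLUMNS
  as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
}
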