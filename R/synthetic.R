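# Synthetic metadata generator. Emulates the statistical structure of a
# multi-site research MRI archive: class-conditional acquisition-parameter
# ranges that overlap across classes (notably repetition time), many
# string variants of the vendor-generated sequence name, ~50% missing
# sequence names, vendor dialects for the diffusion b-value tag, a
# heterogeneous localizer/scout/calibration "junk" class, and two
# sequence types (ASL, field map) held out as unknowns whose parameters
# partially overlap the known classes.

ORIENT_AX   <- "1\\0\\0\\0\\1\\0"
ORIENT_SAG  <- "0\\1\\0\\0\\0\\-1"
ORIENT_COR  <- "1\\0\\0\\0\\0\\-1"
ORIENT_TILT <- "1\\0\\0\\0\\0.97\\-0.26"

# Run-local RNG scope: seeds deterministically, restores the caller's
# RNG state on exit.
with_local_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  code
}

#' Define a class profile
#'
#' Describes how records of one sequence type are drawn: per-feature
#' categorical pools (with weights) and numeric distributions. A numeric
#' feature may be a length-2 range `c(lo, hi)` (uniform, rounded to 2
#' decimals), a list `list(min=, max=, digits=)`, a list
#' `list(values=, weights=)` for a discrete pool, or absent entirely
#' (missing by design, e.g. inversion time for non-IR sequences).
#'
#' @param name Class label the profile generates.
#' @param categorical Named list of pools: character vector (uniform) or
#'   named numeric vector of weights.
#' @param numeric Named list of numeric specifications (see above).
#' @param dual_echo If `TRUE`, `multiecho_te1`/`multiecho_te2` are drawn
#'   and `echo_time` is set to the first echo.
#' @param subtypes Optional list of sub-profiles (for the heterogeneous
#'   "junk" class); `weight` gives each subtype's mixture weight.
#' @param weight Mixture weight when used as a subtype.
#' @return A `class_profile` object.
#' @export
class_profile <- function(name, categorical = list(), numeric = list(),
                          dual_echo = FALSE, subtypes = NULL, weight = 1) {
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  for (feat in names(categorical)) {
    pool <- categorical[[feat]]
    w <- if (is.character(pool)) rep(1, length(pool)) else as.numeric(pool)
    stopifnot(all(w > 0))
  }
  for (feat in names(numeric)) {
    spec <- numeric[[feat]]
    if (is.numeric(spec) && length(spec) == 2) {
      stopifnot(spec[1] <= spec[2])
    }
  }
  structure(list(name = name, categorical = categorical, numeric = numeric,
                 dual_echo = isTRUE(dual_echo), subtypes = subtypes,
                 weight = weight),
            class = "class_profile")
}

# The 148 vendor-style DTI sequence-name variants (4 b-value families x
# 37 run suffixes).
dti_name_variants <- function() {
  sprintf("ep_b%d#%d", rep(c(700, 1000, 1500, 2000), each = 37), 1:37)
}

default_profiles <- function() {
  list(
    class_profile("3DT1",
      categorical = list(
        scanning_sequence = c("GR\\IR" = 0.65, "GR" = 0.35),
        sequence_variant = c("SK\\SP\\MP" = 0.5, "SP\\MP" = 0.25,
                             "NONE" = 0.25),
        scan_options = c("IR" = 0.55, "IR\\WE" = 0.2, "FAST_GEMS" = 0.25),
        mr_acquisition_type = "3D",
        sequence_name = c("tfl3d1_16ns", "*tfl3d1_16ns", "tfl3d1_ns",
                          "EFGRE3D", "T1TFE"),
        image_type = c("ORIGINAL\\PRIMARY\\M\\ND" = 0.6,
                       "ORIGINAL\\PRIMARY\\M\\ND\\NORM" = 0.4),
        image_orientation = c("0\\1\\0\\0\\0\\-1" = 0.8,
                              "1\\0\\0\\0\\1\\0" = 0.2)),
      numeric = list(
        repetition_time = c(6.4, 2740), echo_time = c(2, 5),
        inversion_time = c(450, 1100), flip_angle = c(8, 15),
        pixel_bandwidth = c(130, 240),
        fov_x = list(min = 220, max = 256, digits = 0),
        fov_y = list(min = 220, max = 256, digits = 0))),
    class_profile("2D FLAIR",
      categorical = list(
        scanning_sequence = c("SE\\IR" = 0.7, "IR" = 0.3),
        sequence_variant = c("SK\\SP\\MP\\OSP" = 0.5, "SP" = 0.5),
        scan_options = c("IR\\PFP" = 0.6, "IR" = 0.4),
        mr_acquisition_type = c("2D" = 0.9, "3D" = 0.1),
        sequence_name = c("*tir2d1rs15", "tir2d1rs15", "spcir_278ns",
                          "T2FLAIR"),
        image_type = c("ORIGINAL\\PRIMARY\\M\\ND" = 0.7,
                       "ORIGINAL\\PRIMARY\\M\\ND\\NORM\\FIL" = 0.3),
        image_orientation = ORIENT_AX),
      numeric = list(
        repetition_time = c(6000, 11000), echo_time = c(80, 140),
        inversion_time = c(2000, 2800), flip_angle = c(120, 180),
        pixel_bandwidth = c(220, 290),
        fov_x = list(min = 220, max = 256, digits = 0),
        fov_y = list(min = 220, max = 256, digits = 0))),
    class_profile("PD/T2",
      categorical = list(
        scanning_sequence = "SE",
        sequence_variant = c("SK" = 0.6, "NONE" = 0.4),
        scan_options = c("PFP" = 0.7, "FAST_GEMS" = 0.3),
        mr_acquisition_type = "2D",
        sequence_name = c("*tse2d1_5", "tse2d1_5", "FSE", "tse2d1rs7"),
        image_type = "ORIGINAL\\PRIMARY\\M\\ND",
        image_orientation = ORIENT_AX),
      numeric = list(
        repetition_time = c(2017, 16000), flip_angle = c(90, 165),
        pixel_bandwidth = c(130, 220),
        multiecho_te1 = c(8, 20), multiecho_te2 = c(80, 110),
        fov_x = list(min = 220, max = 256, digits = 0),
        fov_y = list(min = 220, max = 256, digits = 0)),
      dual_echo = TRUE),
    class_profile("T2-star",
      categorical = list(
        scanning_sequence = "GR",
        sequence_variant = c("SP" = 0.6, "SS" = 0.4),
        scan_options = c("FAST_GEMS" = 0.3, "PFP" = 0.3, "NONE" = 0.4),
        mr_acquisition_type = c("2D" = 0.8, "3D" = 0.2),
        sequence_name = c("*fl2d5", "fl2d5", "GRE", "swi3d1r"),
        image_type = c("ORIGINAL\\PRIMARY\\M\\ND" = 0.7,
                       "ORIGINAL\\PRIMARY\\P\\ND" = 0.3),
        image_orientation = ORIENT_AX),
      numeric = list(
        repetition_time = c(400, 1500), flip_angle = c(15, 25),
        pixel_bandwidth = c(260, 320),
        multiecho_te1 = c(5, 12), multiecho_te2 = c(15, 25),
        fov_x = list(min = 200, max = 240, digits = 0),
        fov_y = list(min = 200, max = 240, digits = 0)),
      dual_echo = TRUE),
    class_profile("DTI",
      categorical = list(
        scanning_sequence = "EP",
        sequence_variant = c("SK\\SP" = 0.7, "SK" = 0.3),
        scan_options = c("PFP\\FS" = 0.7, "FS" = 0.3),
        mr_acquisition_type = "2D",
        sequence_name = dti_name_variants(),
        image_type = c("ORIGINAL\\PRIMARY\\DIFFUSION\\NONE" = 0.5,
                       "ORIGINAL\\PRIMARY\\M\\ND\\MOSAIC" = 0.3,
                       "ORIGINAL\\PRIMARY\\DIFFUSION\\NONE\\MOSAIC" = 0.2),
        image_orientation = c("1\\0\\0\\0\\1\\0" = 0.7,
                              "1\\0\\0\\0\\0.97\\-0.26" = 0.3)),
      numeric = list(
        repetition_time = c(3800, 14000), echo_time = c(60, 110),
        flip_angle = list(values = 90),
        pixel_bandwidth = c(1200, 2400),
        b_value_max = list(values = c(700, 1000, 1500, 2000, 2500, 3000)),
        fov_x = list(min = 210, max = 256, digits = 0),
        fov_y = list(min = 210, max = 256, digits = 0))),
    class_profile("fMRI",
      categorical = list(
        scanning_sequence = "EP",
        sequence_variant = "SK",
        scan_options = c("FS" = 0.8, "FS\\PFP" = 0.2),
        mr_acquisition_type = "2D",
        sequence_name = c("epfid2d1_64", "*epfid2d1_64", "epfid2d1_96"),
        image_type = c("ORIGINAL\\PRIMARY\\M\\ND\\MOSAIC" = 0.7,
                       "ORIGINAL\\PRIMARY\\EPI\\NONE" = 0.3),
        image_orientation = c("1\\0\\0\\0\\1\\0" = 0.6,
                              "1\\0\\0\\0\\0.97\\-0.26" = 0.4)),
      numeric = list(
        repetition_time = c(1500, 2800), echo_time = c(25, 35),
        flip_angle = c(70, 90), pixel_bandwidth = c(2000, 3500),
        fov_x = list(min = 192, max = 240, digits = 0),
        fov_y = list(min = 192, max = 240, digits = 0))),
    class_profile("junk", subtypes = list(
      class_profile("localizer", weight = 0.45,
        categorical = list(
          scanning_sequence = "GR",
          sequence_variant = c("SP" = 0.5, "NONE" = 0.5),
          scan_options = c("NONE" = 0.6, "FAST_GEMS" = 0.4),
          mr_acquisition_type = "2D",
          sequence_name = c("localizer", "LOCALIZER", "Localizer_3plane",
                            "*fl2d1"),
          image_type = c("ORIGINAL\\PRIMARY\\OTHER" = 0.6,
                         "ORIGINAL\\PRIMARY\\M\\ND" = 0.4),
          image_orientation = c("1\\0\\0\\0\\1\\0" = 0.4,
                                "0\\1\\0\\0\\0\\-1" = 0.3,
                                "1\\0\\0\\0\\0\\-1" = 0.3)),
        numeric = list(
          repetition_time = c(8, 25), echo_time = c(2, 6),
          flip_angle = c(20, 30), pixel_bandwidth = c(300, 800),
          fov_x = list(min = 250, max = 300, digits = 0),
          fov_y = list(min = 250, max = 300, digits = 0))),
      class_profile("aahead_scout", weight = 0.3,
        categorical = list(
          scanning_sequence = "GR",
          sequence_variant = "SP",
          scan_options = "NONE",
          mr_acquisition_type = "3D",
          sequence_name = c("AAHead_Scout_32ch-head-coil", "AAHead_Scout"),
          image_type = "ORIGINAL\\PRIMARY\\M\\ND",
          image_orientation = ORIENT_AX),
        numeric = list(
          repetition_time = c(80, 130), echo_time = c(2, 4),
          flip_angle = list(values = 8), pixel_bandwidth = c(300, 500),
          fov_x = list(min = 250, max = 300, digits = 0),
          fov_y = list(min = 250, max = 300, digits = 0))),
      class_profile("calibration", weight = 0.25,
        categorical = list(
          scanning_sequence = c("RM" = 0.8, "GR" = 0.2),
          sequence_variant = "NONE",
          scan_options = c("ASSET" = 0.7, "NONE" = 0.3),
          mr_acquisition_type = "2D",
          sequence_name = c("ASSET calibration", "calibration",
                            "asset_cal"),
          image_type = "ORIGINAL\\PRIMARY\\OTHER\\ASSET CAL",
          image_orientation = ORIENT_AX),
        numeric = list(
          repetition_time = c(150, 1500), echo_time = c(1, 3),
          flip_angle = c(1, 10), pixel_bandwidth = c(400, 1000),
          fov_x = list(min = 300, max = 480, digits = 0),
          fov_y = list(min = 300, max = 480, digits = 0))))),
    class_profile("ASL",
      categorical = list(
        scanning_sequence = "EP",
        sequence_variant = c("SK" = 0.5, "SK\\SP" = 0.5),
        scan_options = "PER",
        mr_acquisition_type = c("2D" = 0.5, "3D" = 0.5),
        sequence_name = c("ep2d_pasl", "*ep2d_pasl", "pcasl_3d"),
        image_type = "ORIGINAL\\PRIMARY\\ASL\\NONE",
        image_orientation = ORIENT_AX),
      numeric = list(
        repetition_time = c(3500, 4500), echo_time = c(38, 52),
        flip_angle = list(values = 90), pixel_bandwidth = c(2000, 2400),
        fov_x = list(min = 210, max = 240, digits = 0),
        fov_y = list(min = 210, max = 240, digits = 0))),
    class_profile("Field Map",
      categorical = list(
        scanning_sequence = "GR",
        sequence_variant = "SP",
        scan_options = "FM",
        mr_acquisition_type = "2D",
        sequence_name = c("*fm2d2r", "fm2d2r", "B0map"),
        image_type = "ORIGINAL\\PRIMARY\\P\\ND\\PHASE",
        image_orientation = ORIENT_AX),
      numeric = list(
        repetition_time = c(400, 700), flip_angle = c(55, 65),
        pixel_bandwidth = c(400, 700),
        multiecho_te1 = c(4, 6), multiecho_te2 = c(65, 85),
        fov_x = list(min = 250, max = 300, digits = 0),
        fov_y = list(min = 250, max = 300, digits = 0)),
      dual_echo = TRUE)
  )
}

#' Default generator configuration
#'
#' Encodes the study's default corpus: nine class profiles (the seven
#' known sequence types plus ASL and field map as unknowns) with class
#' counts matching the archive composition (3DT1 3,807; 2D FLAIR 1,458;
#' PD/T2 2,384; T2-star 1,773; DTI 9,385; fMRI 7,482; junk 4,589; ASL 87;
#' Field Map 1,376). Repetition-time ranges overlap across classes (3DT1
#' 6.4-2,740 ms, PD/T2 2,017-16,000 ms, fMRI 1,500-2,800 ms, DTI
#' 3,800-14,000 ms); the DTI profile carries 148 sequence-name variants
#' and the fMRI profile three; half of all sequence names are missing;
#' "junk" is a localizer/scout/calibration mixture; and the vendor mix
#' drives which private DICOM tag carries the b-value in emitted fixtures.
#'
#' @param seed Default seed used by [generate_records()] when none is
#'   given.
#' @return A `generator_config` list with `profiles`, `class_counts`,
#'   `missing_rates`, `empty_rates`, `vendor_mix`, `seed`.
#' @export
default_generator_config <- function(seed = 20211117) {
  missing_rates <- c(
    scanning_sequence = 0.02, sequence_variant = 0.05, scan_options = 0.08,
    mr_acquisition_type = 0.05, sequence_name = 0.5, image_type = 0.02,
    repetition_time = 0.02, echo_time = 0.02, inversion_time = 0.02,
    flip_angle = 0.05, pixel_bandwidth = 0.1, image_orientation = 0.05,
    b_value_max = 0.02, fov_x = 0.02, fov_y = 0.02,
    multiecho_te1 = 0.02, multiecho_te2 = 0.02, manufacturer = 0
  )
  empty_rates <- c(sequence_name = 0.05, scan_options = 0.05)
  structure(list(
    profiles = default_profiles(),
    class_counts = c("3DT1" = 3807, "2D FLAIR" = 1458, "PD/T2" = 2384,
                     "T2-star" = 1773, "DTI" = 9385, "fMRI" = 7482,
                     "junk" = 4589, "ASL" = 87, "Field Map" = 1376),
    missing_rates = missing_rates,
    empty_rates = empty_rates,
    vendor_mix = c("SIEMENS" = 0.6, "GE MEDICAL SYSTEMS" = 0.25,
                   "Philips Medical Systems" = 0.15),
    seed = as.integer(seed)
  ), class = "generator_config")
}

#' @export
print.generator_config <- function(x, ...) {
  cat(sprintf("generator_config: %d class profiles, %s scans by default\n",
              length(x$profiles),
              format(sum(x$class_counts), big.mark = ",")))
  counts <- paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
                  collapse = ", ")
  cat(" ", counts, "\n")
  invisible(x)
}

draw_numeric_feature <- function(spec, n) {
  if (is.list(spec) && !is.null(spec$values)) {
    w <- if (is.null(spec$weights)) rep(1, length(spec$values)) else spec$weights
    return(spec$values[sample.int(length(spec$values), n, replace = TRUE,
                                  prob = w)])
  }
  if (is.list(spec)) {
    return(round(stats::runif(n, spec$min, spec$max), spec$digits))
  }
  round(stats::runif(n, spec[1], spec[2]), 2)
}

draw_categorical_feature <- function(pool, n) {
  if (is.character(pool)) {
    sample(pool, n, replace = TRUE)
  } else {
    sample(names(pool), n, replace = TRUE, prob = as.numeric(pool))
  }
}

# Draw n records from one (sub)profile, before missingness.
draw_profile <- function(profile, n, vendor_mix) {
  rec <- empty_record_table(n)
  for (feat in names(profile$categorical)) {
    rec[[feat]] <- draw_categorical_feature(profile$categorical[[feat]], n)
  }
  for (feat in names(profile$numeric)) {
    rec[[feat]] <- draw_numeric_feature(profile$numeric[[feat]], n)
  }
  if (profile$dual_echo) {
    # first and second gradient/spin echo; the scalar echo time is the
    # first echo
    rec$echo_time <- rec$multiecho_te1
  }
  rec$manufacturer <- draw_categorical_feature(vendor_mix, n)
  rec
}

#' Generate a labeled synthetic corpus
#'
#' Draws records class by class from the configured profiles, then applies
#' per-feature missingness and emptiness independently per record at the
#' configured rates. Fully reproducible for a fixed seed.
#'
#' @param config A [default_generator_config()]-style configuration.
#' @param n_per_class `NULL` (use `config$class_counts`), a single total
#'   (split proportionally to the configured counts), or a named vector of
#'   per-class counts. Classes with count 0 are absent from the output.
#' @param seed Seed; defaults to `config$seed`.
#' @return Labeled record table (`label` column filled, `source_id` set to
#'   `syn_<class>_<i>`).
#' @export
generate_records <- function(config, n_per_class = NULL,
                             seed = config$seed) {
  stopifnot(inherits(config, "generator_config"))
  profile_names <- vapply(config$profiles, `[[`, character(1), "name")

  if (is.null(n_per_class)) {
    counts <- config$class_counts
  } else if (is.null(names(n_per_class))) {
    stopifnot(length(n_per_class) == 1)
    frac <- config$class_counts / sum(config$class_counts)
    counts <- round(frac * n_per_class)
  } else {
    counts <- n_per_class
  }
  absent <- setdiff(names(counts), profile_names)
  if (length(absent) > 0) {
    stop(sprintf("no profile for class(es): %s",
                 paste(absent, collapse = ", ")), call. = FALSE)
  }
  counts <- counts[counts > 0]

  with_local_seed(seed, {
    frames <- list()
    for (class in names(counts)) {
      profile <- config$profiles[[match(class, profile_names)]]
      n <- as.integer(counts[[class]])
      if (!is.null(profile$subtypes)) {
        w <- vapply(profile$subtypes, `[[`, numeric(1), "weight")
        sub_n <- as.integer(stats::rmultinom(1, n, w))
        rec <- do.call(rbind, lapply(seq_along(profile$subtypes), function(i) {
          draw_profile(profile$subtypes[[i]], sub_n[i], config$vendor_mix)
        }))
      } else {
        rec <- draw_profile(profile, n, config$vendor_mix)
      }

      # independent per-feature missingness / emptiness
      for (feat in FEATURES) {
        rate <- unname(config$missing_rates[feat])
        if (length(rate) == 1 && !is.na(rate) && rate > 0) {
          drop <- stats::runif(n) < rate
          rec[[feat]][drop] <- if (feat %in% NUMERIC_FEATURES) {
            NA_real_
          } else NA_character_
        }
        erate <- unname(config$empty_rates[feat])
        if (feat %in% CATEGORICAL_FEATURES && length(erate) == 1 &&
            !is.na(erate) && erate > 0) {
          blank <- stats::runif(n) < erate & !is.na(rec[[feat]])
          rec[[feat]][blank] <- ""
        }
      }
      # dual-echo consistency: a record keeps either both echoes or, when
      # one is dropped, no multi-echo information at all
      half <- is.na(rec$multiecho_te1) != is.na(rec$multiecho_te2)
      rec$multiecho_te1[half] <- NA_real_
      rec$multiecho_te2[half] <- NA_real_
      if (isTRUE(profile$dual_echo)) {
        has <- !is.na(rec$multiecho_te1)
        rec$echo_time[has] <- rec$multiecho_te1[has]
      }
      # both FOV components derive from one PixelSpacing tag, so they are
      # missing together
      fov_na <- is.na(rec$fov_x) | is.na(rec$fov_y)
      rec$fov_x[fov_na] <- NA_real_
      rec$fov_y[fov_na] <- NA_real_

      rec$label <- class
      slug <- gsub("[^A-Za-z0-9]+", "", class)
      rec$source_id <- sprintf("syn_%s_%05d", slug, seq_len(n))
      frames[[class]] <- rec
    }
    out <- do.call(rbind, frames)
    rownames(out) <- NULL
    out
  })
}

#' Emit minimal DICOM fixture series
#'
#' Writes one tiny DICOM series per record (no pixel data) such that
#' [extract_record()] inverts the emission: missing string features omit
#' the tag, empty ones write a zero-length element, the diffusion b-value
#' goes to the manufacturer's private tag — (0043,1039) for GE as a
#' multivalue whose first element is the b-value, (2001,1003) for Philips
#' (FL), (0019,100c) for Siemens (IS) — and dual-echo records become two
#' instances whose echo times are the two echoes. Field of view is encoded
#' as a 256x256 matrix with PixelSpacing `fov/256`, exact for integer
#' fields of view.
#'
#' @param records Record table; `echo_time` must equal `multiecho_te1`
#'   whenever both echoes are present (the generator guarantees this).
#' @param path Output directory; one sub-directory per record, named by
#'   `source_id`.
#' @return Character vector of series directories, invisibly.
#' @export
emit_dicom_fixtures <- function(records, path) {
  check_record_table(records)
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  fmt_ds <- function(x) sprintf("%.10g", x)

  string_tags <- list(
    image_type = list(0x0008, 0x0008, "CS"),
    manufacturer = list(0x0008, 0x0070, "LO"),
    scanning_sequence = list(0x0018, 0x0020, "CS"),
    sequence_variant = list(0x0018, 0x0021, "CS"),
    scan_options = list(0x0018, 0x0022, "CS"),
    mr_acquisition_type = list(0x0018, 0x0023, "CS"),
    sequence_name = list(0x0018, 0x0024, "SH")
  )
  numeric_tags <- list(
    repetition_time = list(0x0018, 0x0080, "DS"),
    inversion_time = list(0x0018, 0x0082, "DS"),
    pixel_bandwidth = list(0x0018, 0x0095, "DS"),
    flip_angle = list(0x0018, 0x1314, "DS")
  )

  dirs <- character(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    sid <- if (!is.na(r$source_id)) r$source_id else sprintf("series_%05d", i)
    series_dir <- file.path(path, sid)
    dir.create(series_dir, showWarnings = FALSE)
    dirs[i] <- series_dir

    base <- list()
    for (feat in names(string_tags)) {
      v <- r[[feat]]
      if (is.na(v)) next
      t <- string_tags[[feat]]
      base[[length(base) + 1]] <- list(group = t[[1]], element = t[[2]],
                                       vr = t[[3]], value = v)
    }
    for (feat in names(numeric_tags)) {
      v <- r[[feat]]
      if (is.na(v)) next
      t <- numeric_tags[[feat]]
      base[[length(base) + 1]] <- list(group = t[[1]], element = t[[2]],
                                       vr = t[[3]], value = fmt_ds(v))
    }
    if (!is.na(r$image_orientation)) {
      base[[length(base) + 1]] <- list(group = 0x0020, element = 0x0037,
                                       vr = "DS", value = r$image_orientation)
    }
    if (!is.na(r$fov_x) && !is.na(r$fov_y)) {
      fx <- r$fov_x
      fy <- r$fov_y
      base[[length(base) + 1]] <- list(group = 0x0028, element = 0x0010,
                                       vr = "US", value = 256)
      base[[length(base) + 1]] <- list(group = 0x0028, element = 0x0011,
                                       vr = "US", value = 256)
      base[[length(base) + 1]] <- list(
        group = 0x0028, element = 0x0030, vr = "DS",
        value = paste(fmt_ds(fy / 256), fmt_ds(fx / 256), sep = "\\"))
    }
    if (!is.na(r$b_value_max) && !is.na(r$manufacturer)) {
      b <- r$b_value_max
      if (grepl("GE", r$manufacturer, ignore.case = TRUE)) {
        base[[length(base) + 1]] <- list(group = 0x0043, element = 0x1039,
                                        vr = "DS",
                                        value = paste(fmt_ds(b), "8", "0", "0",
                                                      sep = "\\"))
      } else if (grepl("Philips", r$manufacturer, ignore.case = TRUE)) {
        base[[length(base) + 1]] <- list(group = 0x2001, element = 0x1003,
                                        vr = "FL", value = b)
      } else if (grepl("Siemens", r$manufacturer, ignore.case = TRUE)) {
        base[[length(base) + 1]] <- list(group = 0x0019, element = 0x100c,
                                        vr = "IS", value = fmt_ds(b))
      }
    }

    tes <- if (!is.na(r$multiecho_te1) && !is.na(r$multiecho_te2)) {
      c(r$multiecho_te1, r$multiecho_te2)
    } else if (!is.na(r$echo_time)) {
      r$echo_time
    } else {
      NA_real_
    }
    for (k in seq_along(tes)) {
      inst <- base
      if (!is.na(tes[k])) {
        inst[[length(inst) + 1]] <- list(group = 0x0018, element = 0x0081,
                                         vr = "DS", value = fmt_ds(tes[k]))
      }
      inst[[length(inst) + 1]] <- list(group = 0x0020, element = 0x0013,
                                       vr = "IS", value = as.character(k))
      write_dicom(file.path(series_dir, sprintf("%06d.dcm", k)), inst)
    }
  }
  invisible(dirs)
}
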