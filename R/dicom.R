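# Minimal DICOM Part-10 codec: explicit VR little endian only, header
# elements only (pixel data and sequences are skipped, not decoded). This
# covers everything the metadata extractor needs and everything the fixture
# emitter writes; other transfer syntaxes raise an error rather than
# returning wrong values.

DICOM_STRING_VRS <- c("AE", "AS", "CS", "DA", "DS", "DT", "IS", "LO",
                      "LT", "PN", "SH", "ST", "TM", "UI", "UC", "UR")
DICOM_LONG_VRS <- c("OB", "OW", "OF", "SQ", "UT", "UN")
DICOM_KNOWN_VRS <- c(DICOM_STRING_VRS, DICOM_LONG_VRS,
                     "US", "SS", "UL", "SL", "FL", "FD", "AT")

tag_key <- function(group, element) sprintf("%04x,%04x", group, element)

r_uint <- function(bytes) sum(as.numeric(bytes) * 256^(seq_along(bytes) - 1))

w_uint <- function(value, n_bytes) {
  out <- raw(n_bytes)
  for (i in seq_len(n_bytes)) {
    out[i] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

# Decode one element value according to its VR.
decode_dicom_value <- function(vr, bytes) {
  if (length(bytes) == 0) return("")
  if (vr %in% DICOM_STRING_VRS) {
    txt <- rawToChar(bytes[bytes != as.raw(0)])
    return(sub("[ ]+$", "", txt))
  }
  switch(vr,
    US = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = FALSE, endian = "little"),
    SS = readBin(bytes, "integer", n = length(bytes) / 2, size = 2,
                 signed = TRUE, endian = "little"),
    UL = ,
    SL = readBin(bytes, "integer", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FL = readBin(bytes, "double", n = length(bytes) / 4, size = 4,
                 endian = "little"),
    FD = readBin(bytes, "double", n = length(bytes) / 8, size = 8,
                 endian = "little"),
    bytes  # OB/OW/UN/...: keep raw
  )
}

#' Read DICOM header elements
#'
#' Parses the header of a single DICOM file (explicit VR little endian) and
#' returns its data elements. Pixel data and nested sequences are skipped.
#'
#' @param path Path to a DICOM file.
#' @return Named list keyed by `"gggg,eeee"` (lower-case hex tag); each
#'   entry is a list with `vr` and decoded `value` (character for string
#'   VRs, numeric for binary VRs, raw otherwise).
#' @export
read_dicom <- function(path) {
  bytes <- readBin(path, "raw", n = file.size(path))
  fail <- function(msg) {
    stop(sprintf("cannot read DICOM file '%s': %s", path, msg),
         call. = FALSE)
  }
  if (length(bytes) < 132) fail("file too short to be DICOM")
  if (rawToChar(bytes[129:132]) != "DICM") fail("missing DICM magic")

  pos <- 133L
  n <- length(bytes)
  elements <- list()
  seen_pixel_data <- FALSE
  while (pos + 7 <= n) {
    group <- r_uint(bytes[pos:(pos + 1)])
    element <- r_uint(bytes[(pos + 2):(pos + 3)])
    vr <- rawToChar(bytes[(pos + 4):(pos + 5)])
    if (!vr %in% DICOM_KNOWN_VRS) {
      fail(sprintf("unknown VR '%s' at tag (%04x,%04x); only explicit VR %s",
                   vr, group, element, "little endian is supported"))
    }
    if (vr %in% DICOM_LONG_VRS) {
      len <- r_uint(bytes[(pos + 8):(pos + 11)])
      pos <- pos + 12L
    } else {
      len <- r_uint(bytes[(pos + 6):(pos + 7)])
      pos <- pos + 8L
    }
    if (len == 4294967295) {
      fail(sprintf("undefined-length element (%04x,%04x) is not supported",
                   group, element))
    }
    if (pos + len - 1 > n) {
      fail(sprintf("truncated element (%04x,%04x)", group, element))
    }
    value_bytes <- if (len > 0) bytes[pos:(pos + len - 1)] else raw(0)
    pos <- pos + len
    if (group == 0x7fe0 && element == 0x0010) {      # pixel data: stop
      seen_pixel_data <- TRUE
      break
    }
    if (vr == "SQ") next                             # sequences: skip
    elements[[tag_key(group, element)]] <-
      list(vr = vr, value = decode_dicom_value(vr, value_bytes))
  }
  if (!seen_pixel_data && pos <= n) {
    fail("truncated element header at end of file")
  }
  if (length(elements) == 0) fail("no data elements found")
  ts <- elements[["0002,0010"]]
  if (!is.null(ts) && !identical(ts$value, "1.2.840.10008.1.2.1")) {
    fail(sprintf("unsupported transfer syntax '%s'", ts$value))
  }
  elements
}

# Encode one element. `value` is a character scalar (multivalues already
# backslash-joined) for string VRs, or a numeric vector for binary VRs.
encode_dicom_element <- function(group, element, vr, value) {
  if (vr %in% DICOM_STRING_VRS) {
    body <- charToRaw(as.character(value))
    if (length(body) %% 2 == 1) {
      pad <- if (vr == "UI") as.raw(0) else charToRaw(" ")
      body <- c(body, pad)
    }
  } else {
    body <- switch(vr,
      US = writeBin(as.integer(value), raw(), size = 2, endian = "little"),
      UL = writeBin(as.integer(value), raw(), size = 4, endian = "little"),
      FL = writeBin(as.double(value), raw(), size = 4, endian = "little"),
      FD = writeBin(as.double(value), raw(), size = 8, endian = "little"),
      stop(sprintf("cannot encode VR '%s'", vr), call. = FALSE)
    )
  }
  header <- c(w_uint(group, 2), w_uint(element, 2), charToRaw(vr))
  if (vr %in% DICOM_LONG_VRS) {
    header <- c(header, raw(2), w_uint(length(body), 4))
  } else {
    header <- c(header, w_uint(length(body), 2))
  }
  c(header, body)
}

#' Write a minimal DICOM file
#'
#' Writes a Part-10 file (preamble, `DICM` magic, file meta group, explicit
#' VR little endian data set) containing the given header elements. Used by
#' [emit_dicom_fixtures()]; there is no pixel data.
#'
#' @param path Output file path.
#' @param elements List of elements, each `list(group=, element=, vr=,
#'   value=)`; written in ascending tag order.
#' @return `path`, invisibly.
#' @export
write_dicom <- function(path, elements) {
  uid_root <- "1.2.826.0.1.3680043.10.1457"
  meta <- list(
    list(group = 0x0002, element = 0x0002, vr = "UI",
         value = "1.2.840.10008.5.1.4.1.1.4"),
    list(group = 0x0002, element = 0x0003, vr = "UI",
         value = paste0(uid_root, ".", sum(utf8ToInt(path)) %% 99991)),
    list(group = 0x0002, element = 0x0010, vr = "UI",
         value = "1.2.840.10008.1.2.1")
  )
  meta_raw <- do.call(c, lapply(meta, function(el) {
    encode_dicom_element(el$group, el$element, el$vr, el$value)
  }))
  group_len <- encode_dicom_element(0x0002, 0x0000, "UL", length(meta_raw))

  ord <- order(vapply(elements, function(el) el$group * 65536 + el$element,
                      numeric(1)))
  body <- lapply(elements[ord], function(el) {
    encode_dicom_element(el$group, el$element, el$vr, el$value)
  })
  body_raw <- if (length(body) > 0) do.call(c, body) else raw(0)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(raw(128), charToRaw("DICM"), group_len, meta_raw, body_raw),
           con)
  invisible(path)
}
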