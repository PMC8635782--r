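# extract_record: inversion of the fixture emitter, vendor b-value
# routing, computed geometry, missing-vs-empty semantics, conflict
# handling.

series_with <- function(instances, dir = withr::local_tempdir(
                          .local_envir = parent.frame())) {
  for (i in seq_along(instances)) {
    write_dicom(file.path(dir, sprintf("%06d.dcm", i)), instances[[i]])
  }
  dir
}

el <- function(group, element, vr, value) {
  list(group = group, element = element, vr = vr, value = value)
}

test_that("emitted fixtures invert back to their source records", {
  rec <- small_corpus(n = 3, seed = 21)   # 3 per class, all 9 classes
  out <- withr::local_tempdir()
  dirs <- emit_dicom_fixtures(rec, out)
  extracted <- do.call(rbind, lapply(dirs, extract_record))
  # emission keys series directories by source_id; realign
  extracted <- extracted[match(rec$source_id, extracted$source_id), ]
  expect_records_equal(extracted, rec)
})

test_that("b-value is routed by manufacturer and maximized over instances", {
  base <- list(el(0x0008, 0x0070, "LO", "SIEMENS"),
               el(0x0018, 0x0020, "CS", "EP"))
  siemens <- series_with(list(
    c(base, list(el(0x0019, 0x100c, "IS", "0"))),
    c(base, list(el(0x0019, 0x100c, "IS", "1000")))))
  expect_equal(extract_record(siemens)$b_value_max, 1000)

  # GE multivalue: first element per instance is the b-value
  ge <- series_with(list(list(
    el(0x0008, 0x0070, "LO", "GE MEDICAL SYSTEMS"),
    el(0x0043, 0x1039, "DS", "2000\\8\\0\\0"))))
  expect_equal(extract_record(ge)$b_value_max, 2000)

  philips <- series_with(list(list(
    el(0x0008, 0x0070, "LO", "Philips Medical Systems"),
    el(0x2001, 0x1003, "FL", 800))))
  expect_equal(extract_record(philips)$b_value_max, 800)

  # unknown manufacturer: the routed tag does not exist, so no b-value
  # even though some vendor tag is present
  other <- series_with(list(list(
    el(0x0008, 0x0070, "LO", "ACME IMAGING"),
    el(0x0019, 0x100c, "IS", "1000"))))
  expect_true(is.na(extract_record(other)$b_value_max))

  # routing is a pure function of the manufacturer: unrelated vendor tags
  # never contribute
  siemens_with_noise <- series_with(list(list(
    el(0x0008, 0x0070, "LO", "SIEMENS"),
    el(0x0019, 0x100c, "IS", "1000"),
    el(0x0043, 0x1039, "DS", "9999\\8"),
    el(0x2001, 0x1003, "FL", 5555))))
  expect_equal(extract_record(siemens_with_noise)$b_value_max, 1000)
})

test_that("field of view is pixel spacing times matrix size", {
  s <- series_with(list(list(
    el(0x0028, 0x0010, "US", 256),
    el(0x0028, 0x0011, "US", 128),
    el(0x0028, 0x0030, "DS", "1\\0.5"))))
  r <- extract_record(s)
  expect_equal(r$fov_x, 0.5 * 128)  # column spacing x Columns
  expect_equal(r$fov_y, 1 * 256)    # row spacing x Rows
})

test_that("absent tags are missing, zero-length tags are empty", {
  s <- series_with(list(list(
    el(0x0018, 0x0020, "CS", "SE"),
    el(0x0018, 0x0022, "CS", ""))))
  r <- extract_record(s)
  expect_true(is.na(r$sequence_name))        # tag absent entirely
  expect_identical(r$scan_options, "")       # present but zero length
  expect_identical(r$scanning_sequence, "SE")
  expect_true(is.na(r$repetition_time))
})

test_that("multi-echo TEs need at least two distinct echo times", {
  one_echo <- series_with(list(
    list(el(0x0018, 0x0081, "DS", "30")),
    list(el(0x0018, 0x0081, "DS", "30"))))
  r <- extract_record(one_echo)
  expect_true(is.na(r$multiecho_te1) && is.na(r$multiecho_te2))
  expect_equal(r$echo_time, 30)

  three <- series_with(list(
    list(el(0x0018, 0x0081, "DS", "25")),
    list(el(0x0018, 0x0081, "DS", "5")),
    list(el(0x0018, 0x0081, "DS", "15"))))
  r <- extract_record(three)
  expect_equal(r$multiecho_te1, 5)   # two smallest distinct
  expect_equal(r$multiecho_te2, 15)
  expect_equal(r$echo_time, 25)      # first instance in sorted order
})

test_that("conflicting series-level tags warn and keep the first instance", {
  s <- series_with(list(
    list(el(0x0018, 0x0020, "CS", "GR")),
    list(el(0x0018, 0x0020, "CS", "SE"))))
  expect_warning(r <- extract_record(s), "conflicting")
  expect_identical(r$scanning_sequence, "GR")
})

test_that("unreadable files abort extraction with the file named", {
  dir <- withr::local_tempdir()
  write_dicom(file.path(dir, "000001.dcm"),
              list(el(0x0018, 0x0020, "CS", "SE")))
  writeLines(strrep("x", 200), file.path(dir, "000002.dcm"))
  expect_error(extract_record(dir), "000002.dcm")
  expect_error(extract_record(file.path(dir, "no_such")), "does not exist")
})

test_that("extract_records skips failing series and counts them", {
  rec <- small_corpus(n = 1, seed = 5,
                      classes = c("3DT1", "fMRI", "DTI", "PD/T2", "junk"))
  root <- withr::local_tempdir()
  emit_dicom_fixtures(rec, root)
  bad <- file.path(root, "zz_corrupt")
  dir.create(bad)
  writeLines(strrep("x", 200), file.path(bad, "000001.dcm"))

  out <- extract_records(root)
  expect_equal(nrow(out), 5)
  expect_length(attr(out, "failures"), 1)
  expect_match(attr(out, "failures"), "zz_corrupt")
})
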