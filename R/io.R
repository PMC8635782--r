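# Tabular metadata I/O. Two dialects, chosen by file extension:
#   *.csv            comma-separated, character fields quoted
#   *.json / *.jsonl JSON-lines, one object per scan
# Missing values are serialized as the token "__MISSING__" (CSV) / null
# (JSON); empty strings stay "" so that missing and empty survive a round
# trip, as the feature engineering step must distinguish them.

io_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "csv") return("csv")
  if (ext %in% c("json", "jsonl", "ndjson")) return("jsonl")
  stop(sprintf("unsupported table format '.%s' (use .csv or .jsonl)", ext),
       call. = FALSE)
}

#' Read a metadata table
#'
#' Reads scan metadata records from a CSV or JSON-lines file written by
#' [write_records()] (or produced externally in the same layout). The file
#' must contain the 18 feature columns; `label` and `source_id` are
#' optional. The token `"__MISSING__"` (CSV) or `null` (JSON) denotes a
#' missing value; an empty string denotes a present-but-empty header.
#' An empty-string entry in a numeric column is read as missing.
#'
#' @param path Input file (`.csv`, `.json` or `.jsonl`).
#' @return Record table (data.frame, 20-column canonical layout).
#' @export
read_records <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("metadata table '%s' does not exist", path), call. = FALSE)
  }
  if (io_format(path) == "csv") {
    raw <- utils::read.csv(path, colClasses = "character",
                           check.names = FALSE, stringsAsFactors = FALSE)
    raw_cols <- as.list(raw)
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0) return(empty_record_table(0))
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
    all_names <- unique(unlist(lapply(rows, names)))
    raw_cols <- lapply(all_names, function(nm) {
      vapply(rows, function(r) {
        v <- r[[nm]]
        if (is.null(v) || (length(v) == 1 && is.na(v))) MISSING_TOKEN
        else as.character(v)
      }, character(1))
    })
    names(raw_cols) <- all_names
  }

  unknown <- setdiff(names(raw_cols), RECORD_COLUMNS)
  if (length(unknown) > 0) {
    stop(sprintf("unexpected column(s) in '%s': %s", path,
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  absent <- setdiff(FEATURES, names(raw_cols))
  if (length(absent) > 0) {
    stop(sprintf("'%s' lacks feature column(s): %s", path,
                 paste(absent, collapse = ", ")), call. = FALSE)
  }

  n <- if (length(raw_cols) > 0) length(raw_cols[[1]]) else 0
  out <- empty_record_table(n)
  for (col in names(raw_cols)) {
    vals <- raw_cols[[col]]
    if (col %in% NUMERIC_FEATURES) {
      vals[vals == MISSING_TOKEN | vals == ""] <- NA_character_
      parsed <- suppressWarnings(as.numeric(vals))
      bad <- which(!is.na(vals) & is.na(parsed))
      if (length(bad) > 0) {
        stop(sprintf("malformed numeric '%s' in column '%s' of '%s', row %d",
                     vals[bad[1]], col, path, bad[1]), call. = FALSE)
      }
      out[[col]] <- parsed
    } else {
      vals[vals == MISSING_TOKEN] <- NA_character_
      out[[col]] <- vals
    }
  }
  out
}

#' Write a metadata table
#'
#' Writes records in the canonical 20-column order (the 18 features, then
#' `label`, `source_id`). `write_records(read_records(path), path2)`
#' reproduces `path` byte for byte for files this function wrote.
#'
#' @param records Record table.
#' @param path Output file (`.csv`, `.json` or `.jsonl`).
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  check_record_table(records)
  fmt <- io_format(path)
  for (col in setdiff(RECORD_COLUMNS, names(records))) {
    records[[col]] <- if (col %in% NUMERIC_FEATURES) NA_real_
                      else NA_character_
  }
  records <- records[, RECORD_COLUMNS, drop = FALSE]

  if (fmt == "csv") {
    char_cols <- which(!RECORD_COLUMNS %in% NUMERIC_FEATURES)
    utils::write.table(records, path, sep = ",", quote = char_cols,
                       qmethod = "double", na = MISSING_TOKEN,
                       row.names = FALSE, col.names = TRUE)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    for (i in seq_len(nrow(records))) {
      row <- as.list(records[i, , drop = FALSE])
      writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null",
                                  digits = NA), con)
    }
    if (nrow(records) == 0) invisible(NULL)  # header-less empty file
  }
  invisible(path)
}
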