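# Feature engineering: sentinel substitution, schema fitting, one-hot
# encoding. The classifier never sees raw records, only the numeric matrix
# produced here.

#' Replace missing and empty values with sentinels
#'
#' Missing numeric values become 1,000,000 (standing in for infinity on
#' the millisecond scales involved); missing categorical values become the
#' category string `"1000000"`; empty categorical values (a header present
#' with zero length) become the category `"empty"`. Present values are
#' unchanged, so the operation is total and idempotent.
#'
#' @param records Record table (possibly a single row).
#' @return Record table of the same shape with sentinels substituted.
#' @export
#' @examples
#' r <- generate_records(default_generator_config(), n_per_class = 2)
#' s <- substitute_sentinels(r)
#' stopifnot(!anyNA(s[, metadata_features()]))
substitute_sentinels <- function(records) {
  check_record_table(records)
  for (col in intersect(NUMERIC_FEATURES, names(records))) {
    records[[col]][is.na(records[[col]])] <- MISSING_SENTINEL
  }
  for (col in intersect(CATEGORICAL_FEATURES, names(records))) {
    vals <- records[[col]]
    vals[is.na(vals)] <- MISSING_CATEGORY
    vals[vals == ""] <- EMPTY_CATEGORY
    records[[col]] <- vals
  }
  records
}

#' Fit a one-hot feature schema
#'
#' Learns, from (sentinel-substituted) training records, the vocabulary of
#' every categorical feature: a feature with n distinct observed values
#' expands into n binary indicator columns. Numeric features map to one
#' column each. Vocabularies are sorted byte-wise so the layout is
#' identical across runs regardless of input order.
#'
#' @param records Sentinel-substituted record table (at least one row).
#' @param kinds Named character vector assigning `"numeric"` or
#'   `"categorical"` to each feature; defaults to [feature_kinds()].
#' @return A `feature_schema` object: `kinds`, `vocabularies` (named list
#'   of character vectors), and `layout` (data.frame with columns
#'   `feature`, `category`, `column_id`; `category` is `NA` for numeric
#'   columns).
#' @export
fit_schema <- function(records, kinds = feature_kinds()) {
  check_record_table(records)
  if (nrow(records) == 0) {
    stop("cannot fit a feature schema on zero records", call. = FALSE)
  }
  stopifnot(setequal(names(kinds), FEATURES),
            all(kinds %in% c("numeric", "categorical")))

  vocabularies <- list()
  layout <- list()
  for (feat in FEATURES) {
    if (kinds[[feat]] == "numeric") {
      layout[[length(layout) + 1]] <-
        data.frame(feature = feat, category = NA_character_,
                   stringsAsFactors = FALSE)
    } else {
      vocab <- sort(unique(as.character(records[[feat]])), method = "radix")
      vocabularies[[feat]] <- vocab
      layout[[length(layout) + 1]] <-
        data.frame(feature = feat, category = vocab,
                   stringsAsFactors = FALSE)
    }
  }
  layout <- do.call(rbind, layout)
  layout$column_id <- sprintf("c%04d", seq_len(nrow(layout)))
  structure(list(kinds = kinds, vocabularies = vocabularies,
                 layout = layout),
            class = "feature_schema")
}

#' @export
print.feature_schema <- function(x, ...) {
  n_cat <- sum(x$kinds == "categorical")
  cat(sprintf("feature_schema: %d features (%d numeric, %d categorical), %d matrix columns\n",
              length(x$kinds), sum(x$kinds == "numeric"), n_cat,
              nrow(x$layout)))
  invisible(x)
}

#' Encode records into the model matrix
#'
#' Applies a fitted schema: numeric features pass through as-is (including
#' the 1,000,000 sentinel); a categorical value sets exactly its own
#' indicator column to 1. A value never seen at fit time leaves all of that
#' feature's columns at 0, signalling "none of the known values".
#'
#' @param records Sentinel-substituted record table.
#' @param schema A [fit_schema()] result.
#' @return Numeric matrix, one row per record, with attributes `schema`
#'   and `row_ids` (the records' `source_id`, if present).
#' @export
encode_records <- function(records, schema) {
  check_record_table(records)
  stopifnot(inherits(schema, "feature_schema"))
  n <- nrow(records)
  layout <- schema$layout
  mat <- matrix(0, nrow = n, ncol = nrow(layout),
                dimnames = list(NULL, layout$column_id))
  for (feat in FEATURES) {
    cols <- which(layout$feature == feat)
    if (schema$kinds[[feat]] == "numeric") {
      mat[, cols] <- as.numeric(records[[feat]])
    } else if (n > 0) {
      idx <- match(as.character(records[[feat]]), schema$vocabularies[[feat]])
      hit <- which(!is.na(idx))
      mat[cbind(hit, cols[1] + idx[hit] - 1L)] <- 1
    }
  }
  attr(mat, "schema") <- schema
  attr(mat, "row_ids") <- if ("source_id" %in% names(records)) {
    records$source_id
  } else {
    as.character(seq_len(n))
  }
  mat
}

# Convenience: sentinel-substitute, fit (or reuse) a schema, and encode.
prepare_matrix <- function(records, schema = NULL) {
  subst <- substitute_sentinels(records)
  if (is.null(schema)) schema <- fit_schema(subst)
  list(matrix = encode_records(subst, schema), schema = schema)
}

#' Decode the categorical block of an encoded matrix
#'
#' Inverse of [encode_records()] for categorical features with seen
#' values: maps each one-hot block back to its category string (`NA` when
#' the block is all zero).
#'
#' @param matrix An [encode_records()] result.
#' @param schema The schema that produced it.
#' @return data.frame of categorical feature values.
#' @export
decode_categories <- function(matrix, schema) {
  layout <- schema$layout
  out <- list()
  for (feat in names(schema$vocabularies)) {
    cols <- which(layout$feature == feat)
    block <- matrix[, cols, drop = FALSE]
    idx <- max.col(block, ties.method = "first")
    idx[rowSums(block) == 0] <- NA_integer_
    out[[feat]] <- schema$vocabularies[[feat]][idx]
  }
  as.data.frame(out, stringsAsFactors = FALSE, check.names = FALSE)
}
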