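# Random-forest classifier: training, prediction with confidence and
# unknown-sequence flagging, aggregated feature importance, persistence.

#' Random-forest model configuration
#'
#' Defaults follow the tuned operating point: 100 trees of maximum depth
#' 16 with Gini impurity. `max_bins` records the bin count of the
#' discretizing forest implementation the method was tuned with; the
#' exact-split forest used here only applies it when `bin_numeric = TRUE`,
#' in which case numeric columns are quantile-binned to at most `max_bins`
#' levels before training (exact splits are a superset of binned splits,
#' so the default leaves binning off).
#'
#' @param num_trees Number of trees (>= 1).
#' @param max_depth Maximum tree depth (>= 1).
#' @param max_bins Bin count for optional numeric pre-binning.
#' @param bin_numeric Apply quantile pre-binning to numeric columns?
#' @param impurity Split criterion; only `"gini"` is supported.
#' @param seed Integer seed making training deterministic.
#' @return A `model_config` list.
#' @export
model_config <- function(num_trees = 100, max_depth = 16, max_bins = 32,
                         bin_numeric = FALSE, impurity = "gini", seed = 1) {
  stopifnot(num_trees >= 1, max_depth >= 1, max_bins >= 2,
            identical(impurity, "gini"))
  structure(list(num_trees = as.integer(num_trees),
                 max_depth = as.integer(max_depth),
                 max_bins = as.integer(max_bins),
                 bin_numeric = isTRUE(bin_numeric),
                 impurity = impurity,
                 seed = as.integer(seed)),
            class = "model_config")
}

# Quantile pre-binning of numeric columns: fit breaks on the training
# matrix, replace values by the midpoint of their bin.
fit_binning <- function(mat, schema, max_bins) {
  numeric_cols <- schema$layout$column_id[is.na(schema$layout$category)]
  breaks <- lapply(numeric_cols, function(col) {
    qs <- unique(stats::quantile(mat[, col],
                                 probs = seq(0, 1, length.out = max_bins + 1),
                                 names = FALSE))
    if (length(qs) < 2) NULL else qs
  })
  names(breaks) <- numeric_cols
  breaks[!vapply(breaks, is.null, logical(1))]
}

apply_binning <- function(mat, breaks) {
  for (col in names(breaks)) {
    b <- breaks[[col]]
    mids <- (b[-1] + b[-length(b)]) / 2
    idx <- findInterval(mat[, col], b, all.inside = TRUE)
    mat[, col] <- mids[idx]
  }
  mat
}

#' Train the sequence-type classifier
#'
#' Fits a probability random forest on an encoded feature matrix. Given
#' the same matrix, labels and seed, training is fully deterministic
#' (single-threaded, seeded).
#'
#' @param matrix An [encode_records()] matrix (its schema travels with the
#'   model so prediction can start from raw records).
#' @param labels Character vector of class labels, one per row.
#' @param config A [model_config()].
#' @return A `seq_model`: the fitted forest, its feature schema, the
#'   sorted class list, and the configuration.
#' @export
train_model <- function(matrix, labels, config = model_config()) {
  if (nrow(matrix) != length(labels)) {
    stop(sprintf("matrix has %d rows but %d labels were given",
                 nrow(matrix), length(labels)), call. = FALSE)
  }
  if (nrow(matrix) == 0) stop("cannot train on zero rows", call. = FALSE)
  labels <- as.character(labels)
  if (anyNA(labels)) stop("labels contain NA", call. = FALSE)
  classes <- sort(unique(labels), method = "radix")

  binning <- NULL
  if (config$bin_numeric) {
    schema <- attr(matrix, "schema")
    if (is.null(schema)) {
      stop("numeric pre-binning requires a schema-encoded matrix",
           call. = FALSE)
    }
    binning <- fit_binning(matrix, schema, config$max_bins)
    matrix <- apply_binning(matrix, binning)
  }

  forest <- NULL
  if (length(classes) > 1) {
    forest <- ranger::ranger(
      x = matrix, y = factor(labels, levels = classes),
      num.trees = config$num_trees, max.depth = config$max_depth,
      splitrule = "gini", probability = TRUE, importance = "impurity",
      seed = config$seed, num.threads = 1
    )
  }
  structure(list(forest = forest, schema = attr(matrix, "schema"),
                 columns = colnames(matrix), classes = classes,
                 config = config, binning = binning),
            class = "seq_model")
}

#' @export
print.seq_model <- function(x, ...) {
  cat(sprintf("seq_model: %d classes (%s)\n", length(x$classes),
              paste(x$classes, collapse = ", ")))
  cat(sprintf("  forest: %d trees, max depth %d, gini impurity, seed %d\n",
              x$config$num_trees, x$config$max_depth, x$config$seed))
  cat(sprintf("  features: %d matrix columns\n", length(x$columns)))
  invisible(x)
}

# Accept either an encoded matrix or a raw record table.
coerce_model_input <- function(model, newdata) {
  if (is.data.frame(newdata)) {
    if (is.null(model$schema)) {
      stop("model was trained on a schema-less matrix; encode the records first",
           call. = FALSE)
    }
    newdata <- encode_records(substitute_sentinels(newdata), model$schema)
  }
  expected <- if (is.null(model$schema)) model$columns
              else model$schema$layout$column_id
  if (ncol(newdata) != length(expected) ||
      !identical(colnames(newdata), expected)) {
    stop("feature matrix columns do not match the model's schema",
         call. = FALSE)
  }
  if (!is.null(model$binning)) newdata <- apply_binning(newdata, model$binning)
  newdata
}

#' Predict sequence types with confidence
#'
#' For each scan, the class probabilities are the per-tree leaf class
#' probabilities averaged over the forest; the predicted label is the
#' highest-probability class (ties broken by sorted class order) and the
#' confidence is that maximum probability. A scan whose confidence falls
#' strictly below `threshold` is flagged as a possible unknown sequence
#' type.
#'
#' @param object A [train_model()] result.
#' @param newdata Encoded matrix or raw record table.
#' @param threshold Flagging threshold on the confidence (default 0.8).
#' @param ... Unused.
#' @return data.frame with `scan_id`, `predicted_label`, `confidence`,
#'   `unknown_flag`, and one `prob_<class>` column per class.
#' @export
predict.seq_model <- function(object, newdata, threshold = 0.8, ...) {
  row_ids <- if (is.data.frame(newdata) && "source_id" %in% names(newdata)) {
    newdata$source_id
  } else NULL
  mat <- coerce_model_input(object, newdata)
  if (is.null(row_ids)) {
    row_ids <- attr(mat, "row_ids")
    if (is.null(row_ids)) row_ids <- as.character(seq_len(nrow(mat)))
  }

  if (is.null(object$forest)) {
    probs <- matrix(1, nrow = nrow(mat), ncol = 1,
                    dimnames = list(NULL, object$classes))
  } else {
    probs <- stats::predict(object$forest, data = mat,
                            num.threads = 1)$predictions
    probs <- probs[, object$classes, drop = FALSE]
  }
  idx <- max.col(probs, ties.method = "first")
  confidence <- probs[cbind(seq_len(nrow(probs)), idx)]
  out <- data.frame(
    scan_id = row_ids,
    predicted_label = object$classes[idx],
    confidence = confidence,
    unknown_flag = confidence < threshold,
    stringsAsFactors = FALSE
  )
  prob_df <- as.data.frame(probs)
  names(prob_df) <- paste0("prob_", object$classes)
  out <- cbind(out, prob_df)
  attr(out, "classes") <- object$classes
  out
}

#' Aggregated feature importance
#'
#' Sums the forest's impurity-based per-column importances over each
#' original feature's one-hot block (numeric features map one-to-one) and
#' normalizes across the 18 features so the result sums to 1.
#'
#' @param model A [train_model()] result.
#' @return Named numeric vector over the 18 features, sorted decreasing.
#' @export
feature_importance <- function(model) {
  stopifnot(inherits(model, "seq_model"))
  if (is.null(model$schema)) {
    vi <- model$forest$variable.importance
    return(sort(vi / max(sum(vi), .Machine$double.eps), decreasing = TRUE))
  }
  layout <- model$schema$layout
  per_col <- stats::setNames(rep(0, nrow(layout)), layout$column_id)
  if (!is.null(model$forest)) {
    vi <- model$forest$variable.importance
    per_col[names(vi)] <- vi
  }
  agg <- tapply(per_col[layout$column_id], layout$feature, sum)
  agg <- agg[FEATURES]
  names(agg) <- FEATURES
  total <- sum(agg)
  if (total > 0) agg <- agg / total
  sort(agg, decreasing = TRUE)
}

MODEL_FORMAT <- "mriseqid_model"
MODEL_FORMAT_VERSION <- 1L

#' Save / load a trained model
#'
#' The artifact embeds the feature schema, class list and configuration,
#' so a reloaded model predicts from raw records exactly as the original
#' did.
#'
#' @param model A `seq_model`.
#' @param path File path for the model artifact.
#' @return `save_model()`: `path`, invisibly. `load_model()`: the model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seq_model"))
  saveRDS(list(format = MODEL_FORMAT, version = MODEL_FORMAT_VERSION,
               model = model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e) {
    stop(sprintf("'%s' is not a readable model artifact: %s", path,
                 conditionMessage(e)), call. = FALSE)
  })
  if (!is.list(obj) || !identical(obj$format, MODEL_FORMAT)) {
    stop(sprintf("'%s' is not a %s artifact", path, MODEL_FORMAT),
         call. = FALSE)
  }
  if (!identical(obj$version, MODEL_FORMAT_VERSION)) {
    stop(sprintf("model artifact version %s is not supported (expected %d)",
                 obj$version, MODEL_FORMAT_VERSION), call. = FALSE)
  }
  obj$model
}
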