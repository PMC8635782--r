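# Evaluation protocol: disproportionate stratified sampling, repeated
# learning curves, confidence distributions, unknown-class experiments,
# and the hyperparameter grid. The one-hot schema is always fitted on the
# training rows only, so test-set category vocabularies never leak into
# the model.

#' Experiment configuration
#'
#' @param training_sizes Per-class training counts for learning curves.
#' @param repeats Independent repetitions per training size; repeat `r`
#'   derives its seed as `seed + r`.
#' @param threshold Confidence threshold for unknown flagging.
#' @param known_classes Classes used to build models.
#' @param unknown_classes Classes held out to test unknown flagging.
#' @param model Forest configuration ([model_config()]); its seed is
#'   replaced by the derived per-repeat seed.
#' @param confidence_bins Number of equal-width histogram bins on `[0,1]`.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(training_sizes = c(20, 50, 100, 200, 400,
                                                 600, 800, 1200),
                              repeats = 20, threshold = 0.8,
                              known_classes = KNOWN_CLASSES,
                              unknown_classes = UNKNOWN_CLASSES,
                              model = model_config(),
                              confidence_bins = 20, seed = 1) {
  stopifnot(repeats >= 1, all(training_sizes >= 1),
            length(intersect(known_classes, unknown_classes)) == 0)
  structure(list(training_sizes = as.integer(training_sizes),
                 repeats = as.integer(repeats), threshold = threshold,
                 known_classes = known_classes,
                 unknown_classes = unknown_classes,
                 model = model, confidence_bins = as.integer(confidence_bins),
                 seed = as.integer(seed)),
            class = "experiment_config")
}

#' Disproportionate stratified split
#'
#' Samples exactly `n_per_class` records of each class for training,
#' without replacement; every remaining record of those classes goes to
#' the test set. Drawing a fixed count per class counteracts the heavy
#' class imbalance of real archives (e.g. a class of 3,807 scans at
#' `n_per_class = 20` contributes 20 training and 3,787 test scans).
#'
#' @param records Labeled record table.
#' @param n_per_class Training count per class.
#' @param classes Classes to include; defaults to all labels present.
#' @param seed Seed for the sampling.
#' @return List with `train` and `test` record tables.
#' @export
stratified_split <- function(records, n_per_class, classes = NULL,
                             seed = 1) {
  check_record_table(records)
  if (is.null(classes)) {
    classes <- sort(unique(records$label), method = "radix")
  }
  with_local_seed(seed, {
    train_idx <- integer(0)
    for (class in classes) {
      idx <- which(records$label == class)
      if (length(idx) < n_per_class) {
        stop(sprintf(
          "class '%s' has %d records, fewer than n_per_class = %d",
          class, length(idx), n_per_class), call. = FALSE)
      }
      train_idx <- c(train_idx, sample(idx, n_per_class))
    }
    test_idx <- setdiff(which(records$label %in% classes), train_idx)
    list(train = records[sort(train_idx), , drop = FALSE],
         test = records[test_idx, , drop = FALSE])
  })
}

# One split-train-evaluate pass: schema fitted on the training rows only.
fit_eval <- function(corpus, n_per_class, config, seed,
                     classes = config$known_classes) {
  split <- stratified_split(corpus, n_per_class, classes = classes,
                            seed = seed)
  train_sub <- substitute_sentinels(split$train)
  schema <- fit_schema(train_sub)
  mc <- config$model
  mc$seed <- as.integer(seed)
  model <- train_model(encode_records(train_sub, schema),
                       split$train$label, mc)
  preds <- predict(model, split$test, threshold = config$threshold)
  list(model = model, predictions = preds, test = split$test,
       accuracy = mean(preds$predicted_label == split$test$label))
}

#' Learning curve under repeated stratified holdout
#'
#' For every training size and repeat: split, fit the one-hot schema on
#' the training rows, train the forest, and measure the fraction of
#' correct predictions on all remaining records of the known classes.
#'
#' @param corpus Labeled record table covering the known classes.
#' @param config An [experiment_config()].
#' @return A `learning_curve` object: `runs` (size, repeat, accuracy) and
#'   `summary` (per-size mean and standard deviation).
#' @export
run_learning_curve <- function(corpus, config = experiment_config()) {
  runs <- list()
  for (size in config$training_sizes) {
    for (r in seq_len(config$repeats)) {
      res <- fit_eval(corpus, size, config, seed = config$seed + r)
      runs[[length(runs) + 1]] <- data.frame(
        size = size, repeat_index = r, accuracy = res$accuracy)
    }
  }
  runs <- do.call(rbind, runs)
  summary <- do.call(rbind, lapply(split(runs, runs$size), function(g) {
    data.frame(size = g$size[1], mean_accuracy = mean(g$accuracy),
               sd_accuracy = stats::sd(g$accuracy))
  }))
  summary <- summary[order(summary$size), ]
  rownames(summary) <- NULL
  structure(list(runs = runs, summary = summary, config = config),
            class = "learning_curve")
}

#' @export
print.learning_curve <- function(x, ...) {
  cat("learning_curve (", max(x$runs$repeat_index), "repeats )\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

confidence_histogram <- function(confidences, n_bins) {
  edges <- seq(0, 1, length.out = n_bins + 1)
  counts <- graphics::hist(confidences, breaks = edges, plot = FALSE,
                           include.lowest = TRUE, right = FALSE)$counts
  # right-open bins except the last, which includes confidence 1
  data.frame(bin_low = edges[-length(edges)], bin_high = edges[-1],
             percent = 100 * counts / max(1, length(confidences)))
}

#' Prediction-confidence distribution by training size
#'
#' Pools test-set confidences over repeats for each training size and
#' reports the percent distribution over equal-width bins, the fraction
#' flagged below the threshold, medians, and a per-class breakdown.
#'
#' @param corpus Labeled record table.
#' @param config An [experiment_config()].
#' @param sizes Training sizes to compare.
#' @return A `confidence_report`: `histogram` (size, bin_low, bin_high,
#'   percent), `flagged` (size, fraction below threshold), `medians`
#'   (size, median confidence), `per_class` (size, class, median),
#'   `confidences` (list of pooled vectors by size).
#' @export
run_confidence_distribution <- function(corpus,
                                        config = experiment_config(),
                                        sizes = c(20, 100, 600, 1200)) {
  hists <- list(); flagged <- list(); medians <- list()
  per_class <- list(); pooled <- list()
  for (size in sizes) {
    conf <- numeric(0); truth <- character(0)
    for (r in seq_len(config$repeats)) {
      res <- fit_eval(corpus, size, config, seed = config$seed + r)
      conf <- c(conf, res$predictions$confidence)
      truth <- c(truth, res$test$label)
    }
    key <- as.character(size)
    pooled[[key]] <- conf
    h <- confidence_histogram(conf, config$confidence_bins)
    hists[[key]] <- cbind(size = size, h)
    flagged[[key]] <- data.frame(
      size = size, fraction = mean(conf < config$threshold))
    medians[[key]] <- data.frame(size = size,
                                 median = stats::median(conf))
    per_class[[key]] <- do.call(rbind, lapply(
      sort(unique(truth), method = "radix"), function(cl) {
        data.frame(size = size, class = cl,
                   median = stats::median(conf[truth == cl]))
      }))
  }
  structure(list(histogram = do.call(rbind, hists),
                 flagged = do.call(rbind, flagged),
                 medians = do.call(rbind, medians),
                 per_class = do.call(rbind, per_class),
                 confidences = pooled,
                 threshold = config$threshold),
            class = "confidence_report")
}

#' @export
print.confidence_report <- function(x, ...) {
  cat("confidence_report (threshold", x$threshold, ")\n")
  cat("median confidence by training size:\n")
  print(x$medians, row.names = FALSE)
  cat(sprintf("fraction flagged (< %.2f):\n", x$threshold))
  print(x$flagged, row.names = FALSE)
  invisible(x)
}

#' Unknown-class experiment
#'
#' Trains on the known classes only (erroring if an unknown label leaks
#' into training) and predicts the scans of the unknown classes,
#' reporting their confidence distribution, which known class each
#' unknown scan was assigned to, and the same quantities for the known
#' test scans as a reference. With `exclude_class`, runs the
#' leave-one-known-out variant: the named class is removed from training
#' (schema refitted without it) and treated as the unknown.
#'
#' @param corpus Labeled record table including unknown-class records.
#' @param config An [experiment_config()].
#' @param n_per_class Training count per known class (default 1,200).
#' @param exclude_class Optional known class to hold out instead of the
#'   configured unknown classes.
#' @param repeats Independent repetitions pooled in the report.
#' @return An `unknown_class_result`: `breakdown` (unknown class x
#'   predicted label percents), `unknown_confidence`/`known_confidence`
#'   (pooled vectors), `medians`, `flagged_unknown`/`flagged_known`
#'   (fractions below the threshold), `histogram` of unknown confidences,
#'   `known_classes`.
#' @export
run_unknown_class_experiment <- function(corpus,
                                         config = experiment_config(),
                                         n_per_class = 1200,
                                         exclude_class = NULL,
                                         repeats = 1) {
  if (is.null(exclude_class)) {
    known <- config$known_classes
    unknown <- config$unknown_classes
  } else {
    stopifnot(exclude_class %in% config$known_classes)
    known <- setdiff(config$known_classes, exclude_class)
    unknown <- exclude_class
  }
  if (length(intersect(known, unknown)) > 0) {
    stop("unknown class present in training labels", call. = FALSE)
  }
  unknown_rows <- corpus[corpus$label %in% unknown, , drop = FALSE]
  if (nrow(unknown_rows) == 0) {
    stop(sprintf("corpus has no records of unknown class(es): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }

  u_conf <- numeric(0); u_pred <- character(0); u_true <- character(0)
  k_conf <- numeric(0)
  for (r in seq_len(repeats)) {
    res <- fit_eval(corpus, n_per_class, config, seed = config$seed + r,
                    classes = known)
    stopifnot(all(res$model$classes %in% known))
    up <- predict(res$model, unknown_rows, threshold = config$threshold)
    u_conf <- c(u_conf, up$confidence)
    u_pred <- c(u_pred, up$predicted_label)
    u_true <- c(u_true, unknown_rows$label)
    k_conf <- c(k_conf, res$predictions$confidence)
  }

  breakdown <- 100 * prop.table(table(true = u_true, predicted = u_pred),
                                margin = 1)
  structure(list(
    breakdown = breakdown,
    unknown_confidence = u_conf,
    known_confidence = k_conf,
    medians = c(unknown = stats::median(u_conf),
                known = stats::median(k_conf)),
    flagged_unknown = mean(u_conf < config$threshold),
    flagged_known = mean(k_conf < config$threshold),
    histogram = confidence_histogram(u_conf, config$confidence_bins),
    known_classes = known, unknown_classes = unknown,
    threshold = config$threshold),
    class = "unknown_class_result")
}

#' @export
print.unknown_class_result <- function(x, ...) {
  cat("unknown_class_result:", paste(x$unknown_classes, collapse = ", "),
      "predicted by a model over",
      paste(x$known_classes, collapse = ", "), "\n")
  cat(sprintf("median confidence: unknown %.3f vs known %.3f\n",
              x$medians["unknown"], x$medians["known"]))
  cat(sprintf("flagged below %.2f: unknown %.1f%%, known %.1f%%\n",
              x$threshold, 100 * x$flagged_unknown, 100 * x$flagged_known))
  cat("assignment of unknown scans (%):\n")
  print(round(x$breakdown, 1))
  invisible(x)
}

#' Hyperparameter grid search
#'
#' Accuracy over an exhaustive grid of forest sizes and depths (and
#' optionally bin counts, enabling quantile pre-binning), each cell
#' trained on the same stratified sample of `n_per_class` scans per known
#' class and tested on the remainder.
#'
#' @param corpus Labeled record table.
#' @param trees_range,depth_range Integer vectors to grid over.
#' @param bins_range Optional integer vector of bin counts; `NULL` leaves
#'   numeric columns unbinned.
#' @param n_per_class Training count per class (default 50).
#' @param config An [experiment_config()].
#' @return data.frame with `num_trees`, `max_depth`, `max_bins` and
#'   `accuracy`, one row per grid cell (CSV-exportable).
#' @export
run_hyperparameter_grid <- function(corpus, trees_range, depth_range,
                                    bins_range = NULL, n_per_class = 50,
                                    config = experiment_config()) {
  split <- stratified_split(corpus, n_per_class,
                            classes = config$known_classes,
                            seed = config$seed)
  train_sub <- substitute_sentinels(split$train)
  schema <- fit_schema(train_sub)
  train_mat <- encode_records(train_sub, schema)
  test_sub <- substitute_sentinels(split$test)
  test_mat <- encode_records(test_sub, schema)

  cells <- expand.grid(num_trees = trees_range, max_depth = depth_range,
                       max_bins = if (is.null(bins_range)) NA else bins_range)
  cells$accuracy <- NA_real_
  for (i in seq_len(nrow(cells))) {
    mc <- model_config(
      num_trees = cells$num_trees[i], max_depth = cells$max_depth[i],
      max_bins = if (is.na(cells$max_bins[i])) 32 else cells$max_bins[i],
      bin_numeric = !is.na(cells$max_bins[i]), seed = config$seed)
    model <- train_model(train_mat, split$train$label, mc)
    preds <- predict(model, test_mat, threshold = config$threshold)
    cells$accuracy[i] <- mean(preds$predicted_label == split$test$label)
  }
  cells
}
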