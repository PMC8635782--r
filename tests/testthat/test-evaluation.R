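# Evaluation protocol: stratified-split arithmetic, schema hygiene,
# experiment plumbing, and reproducibility.

test_that("stratified split takes n per class and leaves the remainder", {
  corpus <- default_corpus()
  sp <- stratified_split(corpus, 20, classes = known_classes(), seed = 3)

  expect_true(all(table(sp$train$label) == 20))
  # the archive has 3,807 3DT1 scans: 20 train, 3,787 test
  expect_equal(sum(sp$test$label == "3DT1"), 3807 - 20)
  expect_equal(nrow(sp$train) + nrow(sp$test),
               sum(corpus$label %in% known_classes()))
  expect_length(intersect(sp$train$source_id, sp$test$source_id), 0)
  expect_setequal(c(sp$train$source_id, sp$test$source_id),
                  corpus$source_id[corpus$label %in% known_classes()])
})

test_that("splits are seeded and complain about short classes", {
  corpus <- small_corpus(n = 30, seed = 5, classes = c("3DT1", "fMRI"))
  s1 <- stratified_split(corpus, 10, seed = 11)
  s2 <- stratified_split(corpus, 10, seed = 11)
  expect_identical(s1, s2)
  s3 <- stratified_split(corpus, 10, seed = 12)
  expect_false(identical(s1$train$source_id, s3$train$source_id))
  expect_error(stratified_split(corpus, 31), "'3DT1' has 30")
})

test_that("schemas are fitted on training rows only", {
  corpus <- small_corpus(n = 40, seed = 7, classes = known_classes())
  cfg <- experiment_config(repeats = 1, seed = 5)
  res <- mriseqid:::fit_eval(corpus, 10, cfg, seed = 5)
  sp <- stratified_split(corpus, 10, classes = cfg$known_classes, seed = 5)
  train_vocab <- sort(unique(substitute_sentinels(sp$train)$sequence_name),
                      method = "radix")
  expect_identical(res$model$schema$vocabularies$sequence_name, train_vocab)
})

test_that("the learning curve aggregates sizes and repeats", {
  corpus <- small_corpus(n = 60, seed = 15, classes = known_classes())
  cfg <- experiment_config(training_sizes = c(5, 30), repeats = 3, seed = 2)
  lc <- run_learning_curve(corpus, cfg)

  expect_equal(nrow(lc$runs), 6)
  expect_equal(lc$summary$size, c(5, 30))
  expect_true(all(lc$runs$accuracy >= 0 & lc$runs$accuracy <= 1))
  expect_true(all(lc$summary$sd_accuracy >= 0))

  single <- run_learning_curve(corpus, experiment_config(
    training_sizes = 10, repeats = 1, seed = 2))
  expect_equal(nrow(single$runs), 1)
  expect_true(is.na(single$summary$sd_accuracy) ||
              single$summary$sd_accuracy == 0)
})

test_that("confidence reports are normalized percent distributions", {
  corpus <- small_corpus(n = 60, seed = 25, classes = known_classes())
  cfg <- experiment_config(repeats = 2, seed = 4, confidence_bins = 20)
  rep_ <- run_confidence_distribution(corpus, cfg, sizes = c(5, 30))

  for (s in c("5", "30")) {
    h <- rep_$histogram[rep_$histogram$size == as.integer(s), ]
    expect_equal(sum(h$percent), 100, tolerance = 1e-6)
    expect_equal(nrow(h), 20)
    conf <- rep_$confidences[[s]]
    expect_true(all(conf >= 1 / 7 - 1e-12 & conf <= 1))
  }
  expect_equal(rep_$flagged$fraction,
               vapply(rep_$confidences, function(x) mean(x < 0.8),
                      numeric(1)),
               ignore_attr = TRUE)
})

test_that("unknown-class experiments never train on unknowns", {
  corpus <- small_corpus(n = 40, seed = 35)
  cfg <- experiment_config(repeats = 1, seed = 6)
  res <- run_unknown_class_experiment(corpus, cfg, n_per_class = 20)

  expect_true(all(rownames(res$breakdown) %in% unknown_classes()))
  expect_true(all(colnames(res$breakdown) %in% known_classes()))
  expect_error(
    experiment_config(known_classes = known_classes(),
                      unknown_classes = "DTI"))
  no_unknowns <- corpus[corpus$label %in% known_classes(), ]
  expect_error(run_unknown_class_experiment(no_unknowns, cfg,
                                            n_per_class = 20),
               "no records of unknown")
})

test_that("leave-one-out mode holds out a known class", {
  corpus <- small_corpus(n = 40, seed = 45,
                         classes = known_classes())
  cfg <- experiment_config(repeats = 1, seed = 8)
  res <- run_unknown_class_experiment(corpus, cfg, n_per_class = 20,
                                      exclude_class = "DTI")
  expect_length(res$known_classes, 6)
  expect_false("DTI" %in% res$known_classes)
  expect_identical(res$unknown_classes, "DTI")
  expect_true(all(colnames(res$breakdown) %in% res$known_classes))
})

test_that("the hyperparameter grid enumerates all cells deterministically", {
  corpus <- small_corpus(n = 30, seed = 55, classes = known_classes())
  cfg <- experiment_config(seed = 10)
  g1 <- run_hyperparameter_grid(corpus, trees_range = c(2, 4),
                                depth_range = c(2, 4), n_per_class = 10,
                                config = cfg)
  expect_equal(nrow(g1), 4)
  expect_setequal(interaction(g1$num_trees, g1$max_depth, drop = TRUE),
                  interaction(c(2, 4, 2, 4), c(2, 2, 4, 4), drop = TRUE))
  g2 <- run_hyperparameter_grid(corpus, trees_range = c(2, 4),
                                depth_range = c(2, 4), n_per_class = 10,
                                config = cfg)
  expect_identical(g1, g2)

  # quantile pre-binning path
  gb <- run_hyperparameter_grid(corpus, trees_range = 8, depth_range = 8,
                                bins_range = c(4, 32), n_per_class = 10,
                                config = cfg)
  expect_equal(nrow(gb), 2)
  expect_true(all(gb$accuracy > 0.5))
})
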