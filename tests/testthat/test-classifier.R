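# Classifier behaviour: degenerate cases, seeded determinism, confidence
# semantics, importance aggregation, and persistence.

test_that("a single-class forest predicts that class with confidence 1", {
  d <- separable_matrix(n_per_class = 10, seed = 31)
  keep <- d$labels == "3DT1"
  model <- train_model(d$matrix[keep, , drop = FALSE], d$labels[keep])
  preds <- predict(model, d$matrix)
  expect_true(all(preds$predicted_label == "3DT1"))
  expect_true(all(preds$confidence == 1))
  expect_false(any(preds$unknown_flag))
})

test_that("a perfectly separable binary column yields held-out accuracy 1", {
  # two classes distinguished by a single indicator; any consistent
  # learner must classify held-out rows perfectly
  set.seed(41)
  n <- 50
  x <- matrix(stats::runif(4 * n * 2), ncol = 4,
              dimnames = list(NULL, paste0("c", 1:4)))
  x[, 1] <- rep(c(0, 1), each = n)
  y <- rep(c("A", "B"), each = n)
  hold <- c(sample(1:n, 10), sample(n + (1:n), 10))

  model <- train_model(x[-hold, ], y[-hold], model_config(seed = 41))
  preds <- predict(model, x[hold, , drop = FALSE])
  expect_equal(mean(preds$predicted_label == y[hold]), 1.0)
})

test_that("training and prediction are deterministic under a fixed seed", {
  d <- separable_matrix(n_per_class = 40, seed = 43)
  m1 <- train_model(d$matrix, d$labels, model_config(seed = 7))
  m2 <- train_model(d$matrix, d$labels, model_config(seed = 7))
  expect_identical(predict(m1, d$matrix), predict(m2, d$matrix))
})

test_that("conflicting labels on identical rows give ~0.5 confidence", {
  # one duplicated feature row labelled A and B 50/50: symmetric
  # ambiguity, so the forest's class probability must sit near 0.5
  x <- matrix(1, nrow = 100, ncol = 3,
              dimnames = list(NULL, paste0("c", 1:3)))
  y <- rep(c("A", "B"), 50)
  model <- train_model(x, y, model_config(seed = 5))
  preds <- predict(model, x[1, , drop = FALSE])
  expect_lt(abs(preds$confidence - 0.5), 0.1)
  expect_true(preds$unknown_flag)  # 0.5 < 0.8
})

test_that("class probabilities are a distribution and confidence its max", {
  corp <- small_corpus(n = 60, seed = 47, classes = known_classes())
  prep <- mriseqid:::prepare_matrix(corp)
  model <- train_model(prep$matrix, corp$label, model_config(seed = 3))
  preds <- predict(model, prep$matrix)

  probs <- as.matrix(preds[, paste0("prob_", model$classes)])
  expect_true(all(abs(rowSums(probs) - 1) < 1e-9))
  expect_equal(preds$confidence, unname(apply(probs, 1, max)))
  expect_identical(preds$predicted_label,
                   model$classes[max.col(probs, ties.method = "first")])
  expect_true(all(preds$confidence >= 1 / length(model$classes) - 1e-12))
})

test_that("unknown_flag uses a strict less-than comparison", {
  d <- separable_matrix(n_per_class = 20, seed = 53)
  model <- train_model(d$matrix, d$labels, model_config(seed = 1))
  preds <- predict(model, d$matrix, threshold = 0.8)
  expect_identical(preds$unknown_flag, preds$confidence < 0.8)
  # at a threshold equal to an observed confidence the scan is NOT flagged
  at <- predict(model, d$matrix, threshold = preds$confidence[1])
  expect_false(at$unknown_flag[1])
})

test_that("a deep forest memorizes unique training rows", {
  corp <- small_corpus(n = 30, seed = 59, classes = known_classes())
  prep <- mriseqid:::prepare_matrix(corp)
  keep <- !duplicated(prep$matrix)
  model <- train_model(prep$matrix[keep, ], corp$label[keep],
                       model_config(seed = 2))
  preds <- predict(model, prep$matrix[keep, ])
  expect_equal(mean(preds$predicted_label == corp$label[keep]), 1.0)
})

test_that("confidence is invariant to class relabelling", {
  corp <- small_corpus(n = 40, seed = 61, classes = c("3DT1", "DTI", "fMRI"))
  prep <- mriseqid:::prepare_matrix(corp)
  m1 <- train_model(prep$matrix, corp$label, model_config(seed = 9))
  renamed <- c("3DT1" = "zeta", "DTI" = "alpha", "fMRI" = "mid")
  m2 <- train_model(prep$matrix, unname(renamed[corp$label]),
                    model_config(seed = 9))
  p1 <- predict(m1, prep$matrix)
  p2 <- predict(m2, prep$matrix)
  expect_equal(p1$confidence, p2$confidence)
  expect_identical(unname(renamed[p1$predicted_label]), p2$predicted_label)
})

test_that("feature importance aggregates one-hot blocks and sums to 1", {
  corp <- small_corpus(n = 80, seed = 67, classes = known_classes())
  prep <- mriseqid:::prepare_matrix(corp)
  model <- train_model(prep$matrix, corp$label, model_config(seed = 4))
  imp <- feature_importance(model)

  expect_setequal(names(imp), metadata_features())
  expect_equal(sum(imp), 1, tolerance = 1e-9)
  expect_true(all(imp >= 0))

  # oracle: sum the forest's raw per-column importances by hand
  vi <- model$forest$variable.importance
  layout <- prep$schema$layout
  manual <- tapply(vi[layout$column_id], layout$feature, sum)
  manual <- manual / sum(manual)
  expect_equal(unname(imp[names(manual)]), unname(manual),
               tolerance = 1e-12)
})

test_that("a constant column has zero importance", {
  set.seed(71)
  x <- cbind(informative = rep(c(0, 1), each = 30),
             constant = 5,
             noise = stats::runif(60))
  model <- train_model(x, rep(c("A", "B"), each = 30),
                       model_config(seed = 6))
  expect_equal(unname(model$forest$variable.importance["constant"]), 0)
})

test_that("models survive a save/load round trip bit-identically", {
  corp <- small_corpus(n = 50, seed = 73, classes = known_classes())
  prep <- mriseqid:::prepare_matrix(corp)
  model <- train_model(prep$matrix, corp$label, model_config(seed = 8))
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(model, path)
  back <- load_model(path)

  probe <- small_corpus(n = 20, seed = 74, classes = known_classes())
  expect_identical(predict(back, probe), predict(model, probe))

  # truncated artifacts error out instead of mispredicting
  bytes <- readBin(path, "raw", file.size(path))
  writeBin(bytes[1:20], path)
  expect_error(load_model(path), "not a readable model")

  other <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(something = "else"), other)
  expect_error(load_model(other), "artifact")
})

test_that("input validation catches shape mismatches", {
  d <- separable_matrix(n_per_class = 10, seed = 79)
  expect_error(train_model(d$matrix, d$labels[-1]), "labels")
  model <- train_model(d$matrix, d$labels)
  expect_error(predict(model, d$matrix[, -1]), "schema")
})
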