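# Shared fixtures, built in code. The full default corpus is generated
# once per test run and cached; small corpora are drawn on demand.

.corpus_cache <- new.env(parent = emptyenv())

default_corpus <- function() {
  if (is.null(.corpus_cache$full)) {
    .corpus_cache$full <- generate_records(default_generator_config())
  }
  .corpus_cache$full
}

small_corpus <- function(n = 120, seed = 11,
                         classes = c(known_classes(), unknown_classes())) {
  counts <- stats::setNames(rep(n, length(classes)), classes)
  generate_records(default_generator_config(), n_per_class = counts,
                   seed = seed)
}

# Compare two record tables: strings exactly (including the NA-vs-""
# distinction), numerics to a small relative tolerance.
expect_records_equal <- function(actual, expected, tol = 1e-8) {
  for (col in metadata_features()) {
    if (col %in% names(which(feature_kinds() == "numeric"))) {
      expect_equal(actual[[col]], expected[[col]], tolerance = tol,
                   label = paste("numeric feature", col))
    } else {
      expect_identical(actual[[col]], expected[[col]],
                       label = paste("categorical feature", col))
    }
  }
}

# A tiny perfectly separable two-class design: one informative binary
# column plus noise columns, wrapped in a real feature schema so model
# I/O paths stay realistic.
separable_matrix <- function(n_per_class = 50, seed = 1) {
  set.seed(seed)
  rec <- small_corpus(n = n_per_class, seed = seed,
                      classes = c("3DT1", "fMRI"))
  prep <- mriseqid:::prepare_matrix(rec)
  list(matrix = prep$matrix, labels = rec$label, schema = prep$schema,
       records = rec)
}
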