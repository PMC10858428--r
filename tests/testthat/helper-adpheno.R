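# Shared fixtures for the test suite.

# A minimal hand-written annotation tibble: one row per (sentence, category)
# match, NA category for unmatched sentences.
make_annotations <- function(rows) {
  tibble::tibble(
    patient_id = vapply(rows, `[[`, "", 1),
    doc_id = vapply(rows, `[[`, "", 2),
    sent_index = as.integer(vapply(rows, `[[`, 0, 3)),
    text = vapply(rows, `[[`, "", 4),
    category = as.integer(vapply(rows, function(r) {
      if (length(r[[5]]) == 1 && is.na(r[[5]])) NA_real_ else as.numeric(r[[5]])
    }, numeric(1))),
    status = vapply(rows, function(r) {
      if (length(r[[6]]) == 1 && is.na(r[[6]])) NA_character_ else as.character(r[[6]])
    }, "")
  )
}

# An indicator MLP with seeded random weights (useful where only the
# probability contract matters, not trained behaviour).
make_random_mlp <- function(seed, dimension = 768L, hidden = 8L, category = NA_integer_) {
  withr::with_seed(seed, {
    structure(
      list(
        W1 = matrix(runif(dimension * hidden, -0.5, 0.5), dimension, hidden),
        b1 = runif(hidden, -0.5, 0.5),
        W2 = matrix(runif(hidden * 2, -0.5, 0.5), hidden, 2),
        b2 = runif(2, -0.5, 0.5),
        category = category, seed = seed, dimension = dimension,
        hidden = hidden
      ),
      class = "indicator_mlp"
    )
  })
}

golden_assertions <- function() {
  utils::read.csv(
    system.file("extdata", "assertion_golden.csv", package = "adpheno"),
    stringsAsFactors = FALSE
  )
}
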