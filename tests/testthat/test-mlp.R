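test_that("relu clamps negatives and preserves shape", {
  expect_equal(relu(-3), 0)
  expect_equal(relu(2.5), 2.5)
  expect_equal(relu(c(-1, 0, 4)), c(0, 0, 4))
  m <- matrix(c(-1, 2, -3, 4), 2)
  expect_equal(dim(relu(m)), dim(m))
})

test_that("softmax is a shift-invariant probability map", {
  expect_equal(softmax(c(0, 0)), c(0.5, 0.5))
  expect_equal(softmax(c(log(3), 0)), c(0.75, 0.25)) # closed form e^{ln3}/(3+1)
  for (c0 in c(-100, 0, 57.3)) {
    expect_equal(softmax(c(c0, c0, c0)), rep(1 / 3, 3))
  }
  z <- c(1.2, -0.7, 3.1)
  expect_equal(softmax(z), softmax(z + 17), tolerance = 1e-12)
  expect_equal(sum(softmax(z)), 1, tolerance = 1e-9)
  expect_true(all(softmax(z) > 0))
})

test_that("indicator datasets are balanced and exclude target-matched negatives", {
  rows <- list()
  # 6 patients; category 2 positives, category 7 negatives pool
  for (i in 1:6) {
    p <- paste0("p", i)
    rows[[length(rows) + 1]] <- list(p, "d", 1, paste("Hay fever note", i), 2, "affirmed")
    rows[[length(rows) + 1]] <- list(p, "d", 2, paste("Asthma note", i, "a"), 7, "affirmed")
    rows[[length(rows) + 1]] <- list(p, "d", 3, paste("Asthma note", i, "b"), 7, "affirmed")
    rows[[length(rows) + 1]] <- list(p, "d", 4, paste("Plain note", i), NA, NA)
  }
  # one multi-category sentence: positive for both 2 and 7, negative for neither
  rows[[length(rows) + 1]] <- list("p1", "d", 5, "Hay fever with asthma.", 2, "affirmed")
  rows[[length(rows) + 1]] <- list("p1", "d", 5, "Hay fever with asthma.", 7, "affirmed")
  ann <- make_annotations(rows)

  ds2 <- assemble_indicator_dataset(ann, 2, seed = 1, train_fraction = 0.5)
  expect_equal(sum(ds2$train$y), sum(1 - ds2$train$y)) # balanced
  expect_equal(sum(ds2$test$y), sum(1 - ds2$test$y))
  multi <- "Hay fever with asthma."
  all_sent <- dplyr::bind_rows(ds2$train$sentences, ds2$test$sentences)
  expect_true(all(all_sent$label[all_sent$text == multi] == 1))
  ds7 <- assemble_indicator_dataset(ann, 7, seed = 1, train_fraction = 0.5)
  all7 <- dplyr::bind_rows(ds7$train$sentences, ds7$test$sentences)
  expect_true(all(all7$label[all7$text == multi] == 1))
  # patient grouping: no patient on both sides
  expect_length(intersect(ds2$train$sentences$patient_id,
                          ds2$test$sentences$patient_id), 0)
  # unannotated sentences are not negatives by default
  expect_false(any(grepl("Plain note", all_sent$text)))
})

test_that("a category without affirmed sentences raises a named error", {
  ann <- make_annotations(list(
    list("p1", "d", 1, "Asthma stable.", 7, "affirmed"),
    list("p2", "d", 1, "No eczema.", 4, "negated")
  ))
  expect_error(assemble_indicator_dataset(ann, 4, seed = 1), "category 4")
})

test_that("MLP training is deterministic and handles degenerate sizes", {
  ds <- list(category = 1L, train = list(
    x = matrix(c(1, 0, 0, 0, 0, 1), nrow = 2, byrow = TRUE, ncol = 3),
    y = c(1L, 0L)
  ))
  m1 <- train_indicator_mlp(ds, seed = 5)
  m2 <- train_indicator_mlp(ds, seed = 5)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  expect_identical(m1$b1, m2$b1)
  expect_identical(m1$b2, m2$b2)
  m3 <- train_indicator_mlp(ds, seed = 6)
  expect_false(identical(m1$W1, m3$W1))
})

test_that("the forward pass matches an independent hand computation", {
  m <- structure(
    list(
      W1 = matrix(c(0.5, -0.2, 0.1, 0.3, -0.4, 0.25), nrow = 3, ncol = 2),
      b1 = c(0.05, -0.1),
      W2 = matrix(c(0.7, -0.3, 0.2, 0.6), nrow = 2, ncol = 2),
      b2 = c(0.01, -0.02),
      category = 1L, dimension = 3L, hidden = 2L
    ),
    class = "indicator_mlp"
  )
  x <- c(0.2, -0.5, 0.8)
  # independent scalar-loop computation
  h <- numeric(2)
  for (j in 1:2) {
    z <- m$b1[j]
    for (i in 1:3) z <- z + x[i] * m$W1[i, j]
    h[j] <- max(0, z)
  }
  logits <- numeric(2)
  for (k in 1:2) {
    z <- m$b2[k]
    for (j in 1:2) z <- z + h[j] * m$W2[j, k]
    logits[k] <- z
  }
  expected <- exp(logits[2]) / sum(exp(logits))
  expect_equal(affirm_probability(m, x), expected, tolerance = 1e-12)
})

test_that("zeroed parameters give probability one half and classes sum to one", {
  m <- structure(
    list(W1 = matrix(0, 10, 4), b1 = numeric(4), W2 = matrix(0, 4, 2),
         b2 = numeric(2), category = 1L, dimension = 10L, hidden = 4L),
    class = "indicator_mlp"
  )
  x <- matrix(rnorm(30), nrow = 3)
  expect_equal(unname(affirm_probability(m, x)), rep(0.5, 3))
  mr <- make_random_mlp(3, dimension = 10, hidden = 4)
  p <- adpheno:::mlp_forward(mr, x)
  expect_equal(unname(rowSums(p)), rep(1, 3), tolerance = 1e-9)
})

test_that("classifier accuracy is the argmax agreement on the test split", {
  m <- make_random_mlp(7, dimension = 6, hidden = 3)
  x <- matrix(seq(-1, 1, length.out = 60), nrow = 10)
  y <- c(1L, 0L, 1L, 1L, 0L, 0L, 1L, 0L, 1L, 0L)
  ds <- list(category = 1L, test = list(x = x, y = y))
  p <- affirm_probability(m, x)
  expected <- mean(as.integer(p > 0.5) == y)
  expect_equal(evaluate_sentence_classifier(m, ds), expected)
  expect_error(evaluate_sentence_classifier(m, list(test = list(x = x[0, ], y = integer(0)))),
               "empty")
})

test_that("a separable dataset is learned within the fixed training recipe", {
  withr::with_seed(31, {
    n <- 200
    d <- 50
    centers <- rbind(c(rep(1, 10), rep(0, 40)), c(rep(0, 40), rep(1, 10)))
    y <- rep(c(1L, 0L), each = n / 2)
    x <- centers[2 - y, ] + matrix(rnorm(n * d, sd = 0.15), n, d)
    x <- x / sqrt(rowSums(x^2))
    pick <- sample(n, 160)
    ds <- list(category = 1L,
               train = list(x = x[pick, ], y = y[pick]),
               test = list(x = x[-pick, ], y = y[-pick]))
    m <- train_indicator_mlp(ds, seed = 1)
    expect_gte(evaluate_sentence_classifier(m, ds), 0.95)
  })
})
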