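make_labels <- function(n_pos, n_neg) {
  tibble::tibble(
    patient_id = sprintf("P%05d", seq_len(n_pos + n_neg)),
    gold_label = rep(c(TRUE, FALSE), c(n_pos, n_neg))
  )
}

test_that("the cohort split reproduces the reference arithmetic", {
  sp <- split_cohort(make_labels(137, 1789), train_fraction = 0.8, seed = 1)
  labs <- make_labels(137, 1789)
  is_pos <- function(ids) labs$gold_label[match(ids, labs$patient_id)]
  expect_equal(sum(is_pos(sp$train)), 109)
  expect_equal(sum(!is_pos(sp$train)), 109)
  expect_equal(sum(is_pos(sp$test_balanced)), 28)
  expect_equal(sum(!is_pos(sp$test_balanced)), 28)
  # prevalence-matched negatives: 65 makes 28/(28+65) closest to 0.30
  expect_equal(sum(!is_pos(sp$test_unbalanced)), 65)
  # the reference design's literal 63 is available explicitly
  sp63 <- split_cohort(make_labels(137, 1789), unbalanced_negatives = 63, seed = 1)
  expect_equal(sum(!is_pos(sp63$test_unbalanced)), 63)
  expect_equal(length(sp63$test_unbalanced), 91)
})

test_that("the floor rule governs small cohorts", {
  labs <- make_labels(10, 100)
  sp <- split_cohort(labs, train_fraction = 0.8, seed = 2)
  is_pos <- function(ids) labs$gold_label[match(ids, labs$patient_id)]
  expect_equal(sum(is_pos(sp$train)), 8)
  expect_equal(length(sp$train), 16)
  expect_equal(sum(is_pos(sp$test_balanced)), 2)
  expect_equal(length(sp$test_balanced), 4)
})

test_that("partitions are disjoint, share test positives, and are seed-deterministic", {
  labs <- make_labels(30, 300)
  sp <- split_cohort(labs, seed = 5)
  expect_length(intersect(sp$train, sp$test_balanced), 0)
  expect_length(intersect(sp$train, sp$test_unbalanced), 0)
  is_pos <- function(ids) labs$gold_label[match(ids, labs$patient_id)]
  expect_setequal(sp$test_balanced[is_pos(sp$test_balanced)],
                  sp$test_unbalanced[is_pos(sp$test_unbalanced)])
  # negatives are never reused between the two test sets
  expect_length(intersect(sp$test_balanced[!is_pos(sp$test_balanced)],
                          sp$test_unbalanced[!is_pos(sp$test_unbalanced)]), 0)
  sp2 <- split_cohort(labs, seed = 5)
  expect_identical(sp$membership, sp2$membership)
  expect_false(identical(split_cohort(labs, seed = 6)$membership, sp$membership))
})

test_that("insufficient negatives raise an informative error", {
  expect_error(split_cohort(make_labels(10, 12), seed = 1), "insufficient negative")
})

test_that("confusion counts tally the 2x2 table with AD as the positive class", {
  cc <- confusion_counts(rep(c(TRUE, FALSE), each = 10),
                         rep(c(TRUE, FALSE), each = 10))
  expect_equal(unlist(cc[c("TP", "TN", "FP", "FN")]),
               c(TP = 10, TN = 10, FP = 0, FN = 0))
  inv <- confusion_counts(rep(c(FALSE, TRUE), each = 10),
                          rep(c(TRUE, FALSE), each = 10))
  expect_equal(unlist(inv[c("TP", "TN", "FP", "FN")]),
               c(TP = 0, TN = 0, FP = 10, FN = 10))
  # hand-tallied 6-case fixture
  pred <- c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)
  gold <- c(TRUE, FALSE, TRUE, FALSE, TRUE, FALSE)
  cc6 <- confusion_counts(pred, gold)
  expect_equal(unlist(cc6[c("TP", "TN", "FP", "FN")]),
               c(TP = 2, TN = 2, FP = 1, FN = 1))
  expect_error(confusion_counts(c(TRUE, FALSE), TRUE), "equal length")
})

test_that("the six metric formulas are exact, with NA for zero denominators", {
  m <- compute_metrics(list(TP = 5, TN = 5, FP = 5, FN = 5))
  expect_equal(unlist(m), c(accuracy = 0.5, precision = 0.5, recall = 0.5,
                            f1 = 0.5, npv = 0.5, specificity = 0.5))
  u <- compute_metrics(list(TP = 0, FP = 0, FN = 5, TN = 5))
  expect_true(is.na(u$precision))
  expect_equal(u$recall, 0)
  expect_equal(u$specificity, 1)
  expect_true(is.na(u$f1))
  expect_error(compute_metrics(list(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("accuracy decomposes into recall and specificity weighted by class sizes", {
  withr::with_seed(99, {
    for (i in 1:25) {
      cc <- list(TP = sample(0:30, 1), TN = sample(0:30, 1),
                 FP = sample(0:30, 1), FN = sample(0:30, 1))
      if (Reduce(`+`, cc) == 0 || cc$TP + cc$FN == 0 || cc$TN + cc$FP == 0) next
      m <- compute_metrics(cc)
      P <- cc$TP + cc$FN
      N <- cc$TN + cc$FP
      expect_equal(m$accuracy, (m$recall * P + m$specificity * N) / (P + N))
      if (P == N) expect_equal(m$accuracy, (m$recall + m$specificity) / 2)
    }
  })
})

test_that("cross-validated tuning is deterministic and honours the grid", {
  withr::with_seed(7, {
    n <- 60
    x <- matrix(runif(n * 8), n, 8)
    y <- x[, 6] + 0.2 * runif(n) > 0.6
    vectors <- dplyr::bind_cols(tibble::tibble(patient_id = sprintf("q%03d", 1:n)),
                                stats::setNames(as.data.frame(x), paste0("v", 1:8)))
    labels <- tibble::tibble(patient_id = vectors$patient_id, gold_label = y)
  })
  one <- tune_and_train(vectors, labels, "decision_tree",
                        grid = list(list(cp = 0.25)), seed = 3)
  expect_equal(one$params$cp, 0.25)
  a <- tune_and_train(vectors, labels, "svm", seed = 4)
  b <- tune_and_train(vectors, labels, "svm", seed = 4)
  expect_identical(a$params, b$params)
  expect_identical(a$cv_accuracy, b$cv_accuracy)
  expect_identical(predict(a, vectors), predict(b, vectors))
  expect_error(tune_and_train(vectors, labels, "svm", grid = list(), seed = 1),
               "non-empty")
  bad <- labels
  bad$gold_label <- TRUE
  expect_error(tune_and_train(vectors, bad, "svm", seed = 1), "single class")
})

test_that("stacking over identical base models reproduces the common prediction", {
  withr::with_seed(11, {
    n <- 80
    x <- matrix(runif(n * 8), n, 8)
    y <- x[, 1] > 0.5
    vectors <- dplyr::bind_cols(tibble::tibble(patient_id = sprintf("r%03d", 1:n)),
                                stats::setNames(as.data.frame(x), paste0("v", 1:8)))
    labels <- tibble::tibble(patient_id = vectors$patient_id, gold_label = y)
  })
  base <- tune_and_train(vectors, labels, "decision_tree",
                         grid = list(list(cp = 0.01)), seed = 2)
  stacked <- stacking_predict(list(base, base, base), vectors, labels, vectors,
                              seed = 9)
  expect_equal(as.logical(stacked), as.logical(predict(base, vectors)))
  expect_error(stacking_predict(list(base), vectors, labels, vectors),
               "at least 2")
  # deterministic under a fixed seed
  expect_identical(stacking_predict(list(base, base), vectors, labels, vectors, seed = 9),
                   stacking_predict(list(base, base), vectors, labels, vectors, seed = 9))
})

test_that("the fitted roster reports metrics for every family on both test sets", {
  coh <- generate_cohort(20, 60, seed = 31)
  ann <- annotate_corpus(coh)
  bv <- binary_vectors(ann, patient_ids = coh$patients$patient_id)
  sp <- split_cohort(coh$patients, seed = 31)
  fit <- ad_phenotype(bv, coh$patients, sp, seed = 31)
  tt <- tidy(fit)
  expect_setequal(unique(tt$model), c(ad_model_families(), "stacking"))
  expect_setequal(unique(tt$test_set), c("test_balanced", "test_unbalanced"))
  expect_equal(nrow(tt), 16)
  expect_true(all(tt$TP + tt$TN + tt$FP + tt$FN ==
                    ifelse(tt$test_set == "test_balanced",
                           length(sp$test_balanced), length(sp$test_unbalanced))))
  g <- glance(fit)
  expect_equal(nrow(g), 1)
  expect_equal(g$test_set, "test_balanced")
  p <- autoplot(fit)
  expect_s3_class(p, "ggplot")
})
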