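models8 <- lapply(1:8, function(k) make_random_mlp(k, dimension = 768, hidden = 6,
                                                   category = k))
backend <- embedding_backend("hashing")

test_that("a single-sentence record yields that sentence's eight probabilities", {
  sents <- tibble::tibble(patient_id = "p1", doc_id = "d1", sent_index = 1L,
                          text = "Eczema noted on both arms.")
  pv <- probability_vectors(sents, models8, backend)
  emb <- embed_sentences(sents$text, backend)
  direct <- vapply(models8, function(m) affirm_probability(m, emb), numeric(1))
  expect_equal(unname(as.matrix(pv[paste0("v", 1:8)])[1, ]), unname(direct))
  expect_equal(pv$mode, "probability")
})

test_that("two sentences aggregate by elementwise max", {
  sents <- tibble::tibble(
    patient_id = "p1", doc_id = "d1", sent_index = 1:2,
    text = c("Eczema noted on both arms.", "Asthma is stable.")
  )
  pv <- probability_vectors(sents, models8, backend)
  emb <- embed_sentences(sents$text, backend)
  p <- vapply(models8, function(m) affirm_probability(m, emb), numeric(2))
  expect_equal(unname(as.matrix(pv[paste0("v", 1:8)])[1, ]),
               unname(pmax(p[1, ], p[2, ])))
})

test_that("patients without sentences receive zero vectors in both modes", {
  sents <- tibble::tibble(patient_id = character(0), doc_id = character(0),
                          sent_index = integer(0), text = character(0))
  pv <- probability_vectors(sents, models8, backend, patient_ids = c("a", "b"))
  expect_equal(unname(as.matrix(pv[paste0("v", 1:8)])),
               matrix(0, 2, 8))
  bv <- binary_vectors(make_annotations(list())[0, ], patient_ids = "a")
  expect_equal(unname(as.matrix(bv[paste0("v", 1:8)])[1, ]), rep(0, 8))
})

test_that("probability vectors are invariant to sentence order and document grouping", {
  coh <- generate_cohort(2, 3, seed = 23)
  sents <- segment_corpus(coh)
  pv1 <- probability_vectors(sents, models8, backend)
  shuffled <- sents[withr::with_seed(1, sample(nrow(sents))), ]
  shuffled$doc_id <- "all-in-one"
  pv2 <- probability_vectors(shuffled, models8, backend)
  expect_equal(pv1, pv2)
})

test_that("appending a sentence never decreases any vector element", {
  coh <- generate_cohort(3, 3, seed = 29)
  sents <- segment_corpus(coh)
  pv1 <- probability_vectors(sents, models8, backend)
  extra <- tibble::tibble(patient_id = unique(sents$patient_id),
                          doc_id = "extra", sent_index = 1L,
                          text = "Montelukast refilled today.")
  pv2 <- probability_vectors(dplyr::bind_rows(sents, extra), models8, backend)
  expect_true(all(as.matrix(pv2[paste0("v", 1:8)]) >=
                    as.matrix(pv1[paste0("v", 1:8)]) - 1e-12))
  # binary mode
  ann1 <- annotate_corpus(coh)
  ann2 <- annotate_sentences(dplyr::bind_rows(
    dplyr::distinct(ann1[, c("patient_id", "doc_id", "sent_index", "text")]), extra
  ))
  bv1 <- binary_vectors(ann1)
  bv2 <- binary_vectors(ann2)
  expect_true(all(as.matrix(bv2[paste0("v", 1:8)]) >=
                    as.matrix(bv1[paste0("v", 1:8)])))
})

test_that("binary vectors flag only affirmed categories", {
  ann <- make_annotations(list(
    list("p1", "d", 1, "Asthma is stable.", 7, "affirmed"),
    list("p2", "d", 1, "No eczema.", 4, "negated"),
    list("p2", "d", 2, "Mother has hay fever.", 2, "experiencer_other"),
    list("p3", "d", 1, "Feels fine.", NA, NA)
  ))
  bv <- binary_vectors(ann)
  m <- as.matrix(bv[paste0("v", 1:8)])
  rownames(m) <- bv$patient_id
  expect_equal(unname(m["p1", ]), c(0, 0, 0, 0, 0, 0, 1, 0)) # e7
  expect_equal(unname(m["p2", ]), rep(0, 8)) # non-affirmed mentions only
  expect_equal(unname(m["p3", ]), rep(0, 8))
})

test_that("binary mode equals thresholded probability mode under oracle sentence classifiers", {
  # idealized case: a perfect sentence classifier emits 1 exactly when the
  # sentence carries an affirmed match for its category, 0 otherwise; the
  # max-aggregated probability vector thresholded at any t in (0,1) must then
  # coincide with the binary vector.
  coh <- generate_cohort(20, 40, seed = 41)
  ann <- annotate_corpus(coh)
  ids <- coh$patients$patient_id
  oracle <- matrix(0, length(ids), 8, dimnames = list(ids, NULL))
  for (pid in ids) {
    rows <- ann[ann$patient_id == pid & !is.na(ann$category) &
                  ann$status == "affirmed", ]
    for (k in 1:8) {
      probs <- as.numeric(rows$category == k) # per-sentence oracle outputs
      oracle[pid, k] <- if (length(probs)) max(probs) else 0
    }
  }
  bv <- as.matrix(binary_vectors(ann, patient_ids = ids)[paste0("v", 1:8)])
  for (t in c(0.1, 0.5, 0.9)) {
    expect_equal(unname((oracle > t) * 1), unname(bv))
  }
})

test_that("patient vectors round-trip through CSV", {
  bv <- binary_vectors(make_annotations(list(
    list("p1", "d", 1, "Asthma is stable.", 7, "affirmed")
  )))
  path <- withr::local_tempfile(fileext = ".csv")
  write_patient_vectors(bv, path)
  back <- read_patient_vectors(path)
  expect_equal(back$patient_id, bv$patient_id)
  expect_equal(as.matrix(back[paste0("v", 1:8)]), as.matrix(bv[paste0("v", 1:8)]))
})
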