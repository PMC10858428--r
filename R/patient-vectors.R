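#' Probability-mode patient vectors (max aggregation)
#'
#' Every sentence of every document in a patient's record — not only
#' lexicon-matched ones — is embedded and passed through each of the eight
#' indicator classifiers; element k of the patient vector is the maximum
#' affirm probability any sentence achieves for category k. A patient with no
#' sentences gets an all-zero vector (no evidence).
#'
#' @param sentences A sentence tibble from [segment_corpus()] (or an
#'   `ad_cohort` / documents tibble, which is segmented first).
#' @param models A list of 8 [indicator_mlp][train_indicator_mlp()] objects,
#'   in category order.
#' @param backend The [embedding_backend()] the models were trained on.
#' @param patient_ids Optional character vector fixing which patients (and in
#'   what order) receive a row; patients absent from `sentences` get zero
#'   vectors.
#'
#' @return A tibble with `patient_id`, `v1` .. `v8` and `mode =
#'   "probability"`, ordered by `patient_id`.
#' @export
probability_vectors <- function(sentences, models,
                                backend = embedding_backend(),
                                patient_ids = NULL) {
  if (inherits(sentences, "ad_cohort") ||
      (!is.null(sentences$text) && is.null(sentences$sent_index))) {
    sentences <- segment_corpus(sentences)
  }
  if (length(models) != 8) abort("models must be a list of 8 indicator classifiers")
  for (m in models) {
    if (m$dimension != backend$dimension) {
      abort("backend dimension does not match classifier input dimension")
    }
  }
  ids <- patient_ids %||% sort(unique(sentences$patient_id))
  vec <- matrix(0, nrow = length(ids), ncol = 8,
                dimnames = list(ids, paste0("v", 1:8)))
  if (nrow(sentences) > 0) {
    ut <- unique(sentences$text)
    emb <- embed_sentences(ut, backend)
    probs <- vapply(models, function(m) affirm_probability(m, emb),
                    numeric(length(ut))) # |ut| x 8
    if (is.null(dim(probs))) probs <- matrix(probs, ncol = 8)
    sent_probs <- probs[match(sentences$text, ut), , drop = FALSE]
    for (g in split(seq_len(nrow(sentences)), sentences$patient_id)) {
      pid <- sentences$patient_id[g[1]]
      if (pid %in% ids) {
        vec[pid, ] <- apply(sent_probs[g, , drop = FALSE], 2, max)
      }
    }
  }
  bind_cols(tibble(patient_id = ids), as_tibble(vec)) %>%
    mutate(mode = "probability") %>%
    arrange(.data$patient_id)
}

#' Binary-mode patient vectors (rules only)
#'
#' Element k is 1 when at least one sentence in the patient's record carries
#' an affirmed match for category k, else 0. Only annotated matches are
#' consulted; negated, other-experiencer and hypothetical mentions do not
#' count.
#'
#' @param annotations Annotation tibble from [annotate_corpus()].
#' @param patient_ids Optional character vector fixing the output rows;
#'   patients with no affirmed matches get zero vectors.
#'
#' @return A tibble with `patient_id`, `v1` .. `v8` and `mode = "binary"`,
#'   ordered by `patient_id`.
#' @export
binary_vectors <- function(annotations, patient_ids = NULL) {
  ids <- patient_ids %||% sort(unique(annotations$patient_id))
  vec <- matrix(0, nrow = length(ids), ncol = 8,
                dimnames = list(ids, paste0("v", 1:8)))
  aff <- annotations[!is.na(annotations$category) &
                       annotations$status == "affirmed", , drop = FALSE]
  if (nrow(aff) > 0) {
    aff <- aff[aff$patient_id %in% ids, , drop = FALSE]
    for (i in seq_len(nrow(aff))) {
      vec[aff$patient_id[i], aff$category[i]] <- 1
    }
  }
  bind_cols(tibble(patient_id = ids), as_tibble(vec)) %>%
    mutate(mode = "binary") %>%
    arrange(.data$patient_id)
}

#' Write / read patient vectors as CSV
#'
#' Columns `patient_id`, `v1` .. `v8`, `mode`; rows ordered by `patient_id`.
#'
#' @param vectors A patient-vector tibble.
#' @param path CSV file path.
#' @return `path` invisibly (writer); the vector tibble (reader).
#' @export
write_patient_vectors <- function(vectors, path) {
  utils::write.csv(arrange(vectors, .data$patient_id), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_patient_vectors
#' @export
read_patient_vectors <- function(path) {
  as_tibble(utils::read.csv(path, colClasses = c(patient_id = "character")))
}
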