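#' Construct a sentence-embedding backend
#'
#' Two backends share one interface: `"hashing"` — a deterministic,
#' download-free signed-hash bag-of-tokens projection to `dimension`
#' dimensions, L2-normalized, suitable for tests and offline runs; and
#' `"transformer"` — a pretrained bidirectional-transformer checkpoint
#' (general-domain or clinical-domain) whose weights must be supplied
#' externally.
#'
#' @param name One of `"hashing"`, `"transformer"`.
#' @param dimension Embedding dimension (default 768, matching the
#'   transformer hidden size the sentence classifiers expect).
#' @param max_tokens Token input limit; text beyond it is truncated (head
#'   truncation, default 512).
#' @param model_ref For the transformer backend, an opaque reference to the
#'   checkpoint (e.g. a general-domain vs clinical-domain model name).
#' @param pooling For the transformer backend: `"cls"` (classification-position
#'   hidden state, default) or `"mean"`.
#' @param salt Integer salt mixed into the hashing backend's token hashes.
#'
#' @return An object of class `ad_embedding_backend`.
#' @export
embedding_backend <- function(name = c("hashing", "transformer"),
                              dimension = 768L, max_tokens = 512L,
                              model_ref = NULL, pooling = c("cls", "mean"),
                              salt = 0L) {
  name <- match.arg(name)
  pooling <- match.arg(pooling)
  if (dimension < 1 || max_tokens < 1) {
    abort("dimension and max_tokens must be positive")
  }
  structure(
    list(name = name, dimension = as.integer(dimension),
         max_tokens = as.integer(max_tokens), model_ref = model_ref,
         pooling = pooling, salt = as.integer(salt)),
    class = "ad_embedding_backend"
  )
}

#' @export
print.ad_embedding_backend <- function(x, ...) {
  cat("<ad_embedding_backend>", x$name, "- dim", x$dimension,
      "- max_tokens", x$max_tokens, "\n")
  invisible(x)
}

# Lowercase word tokens (alphanumeric runs).
word_tokens <- function(text) {
  t <- regmatches(tolower(text), gregexpr("[a-z0-9]+", tolower(text)))[[1]]
  t
}

#' Tokenize a sentence and truncate to the backend's input limit
#'
#' Truncation keeps the leading tokens; the pre-truncation token count is
#' reported so over-length inputs remain visible.
#'
#' @param text A single sentence.
#' @param backend An [embedding_backend()].
#'
#' @return A list with `tokens` (character vector, length `<= max_tokens`) and
#'   `token_count` (integer, the count before truncation).
#' @export
tokenize_and_truncate <- function(text, backend = embedding_backend()) {
  toks <- word_tokens(text)
  list(
    tokens = head(toks, backend$max_tokens),
    token_count = length(toks)
  )
}

# Deterministic 31-bit hash of a token string (polynomial rolling hash in
# double precision; exact because intermediate values stay below 2^52).
token_hash <- function(token, salt = 0L) {
  h <- 5381 + as.numeric(salt)
  for (b in utf8ToInt(token)) {
    h <- (h * 33 + b) %% 2147483647
  }
  h
}

# Memoized token -> (index, sign) map, keyed by (dimension, salt).
token_hash_env <- new.env(parent = emptyenv())

token_index_sign <- function(token, dimension, salt) {
  key <- paste0(dimension, ":", salt, ":", token)
  hit <- token_hash_env[[key]]
  if (!is.null(hit)) return(hit)
  h <- token_hash(token, salt)
  out <- c(index = (h %% dimension) + 1, sign = if ((h %/% dimension) %% 2 == 0) 1 else -1)
  token_hash_env[[key]] <- out
  out
}

embed_one_hashing <- function(text, backend) {
  toks <- tokenize_and_truncate(text, backend)$tokens
  v <- numeric(backend$dimension)
  if (length(toks) == 0) {
    v[1] <- 1 # canonical null-sentence embedding
    return(v)
  }
  for (tok in toks) {
    is_ <- token_index_sign(tok, backend$dimension, backend$salt)
    v[is_["index"]] <- v[is_["index"]] + is_["sign"]
  }
  nrm <- sqrt(sum(v^2))
  if (nrm == 0) v[1] <- 1 else v <- v / nrm
  v
}

#' Embed sentences as fixed-length vectors
#'
#' Deterministic for a fixed (text, backend) pair. With `cache`, embeddings of
#' repeated texts are computed once and reused; cached and uncached runs give
#' identical vectors.
#'
#' @param texts Character vector of sentences.
#' @param backend An [embedding_backend()].
#' @param cache Optional environment used as an embedding cache (keyed by
#'   sentence text).
#'
#' @return A numeric matrix, one row per sentence, `backend$dimension`
#'   columns.
#' @export
embed_sentences <- function(texts, backend = embedding_backend(), cache = NULL) {
  if (backend$name == "transformer") {
    abort(paste0(
      "transformer weights are not available for model_ref '",
      backend$model_ref %||% "<unset>",
      "'; supply a checkpoint or use the deterministic fallback: ",
      "embedding_backend(\"hashing\")"
    ))
  }
  out <- matrix(0, nrow = length(texts), ncol = backend$dimension)
  if (length(texts) == 0) return(out)
  if (is.null(cache)) {
    # compute unique texts once, then expand
    ut <- unique(texts)
    um <- matrix(0, nrow = length(ut), ncol = backend$dimension)
    for (i in seq_along(ut)) um[i, ] <- embed_one_hashing(ut[i], backend)
    out <- um[match(texts, ut), , drop = FALSE]
  } else {
    for (i in seq_along(texts)) {
      key <- texts[i]
      hit <- cache[[key]]
      if (is.null(hit)) {
        hit <- embed_one_hashing(texts[i], backend)
        cache[[key]] <- hit
      }
      out[i, ] <- hit
    }
  }
  rownames(out) <- NULL
  out
}

#' Corpus token statistics by gold-label group
#'
#' Reports, for AD-positive and AD-negative patients, the mean number of
#' documents, sentences and tokens per patient, sentences per document, tokens
#' per document, and tokens per sentence, under the backend's tokenizer.
#'
#' @param cohort An `ad_cohort`, or a documents tibble; in the latter case
#'   `labels` must give `patient_id` and `gold_label`.
#' @param backend An [embedding_backend()] supplying the tokenizer.
#' @param labels Optional tibble with `patient_id`, `gold_label`.
#'
#' @return A tibble with one row per label group and the six mean statistics;
#'   empty corpus gives an empty tibble.
#' @export
corpus_token_stats <- function(cohort, backend = embedding_backend(),
                               labels = NULL) {
  if (inherits(cohort, "ad_cohort")) {
    labels <- cohort$patients[, c("patient_id", "gold_label")]
    documents <- cohort$documents
  } else {
    documents <- cohort
    if (is.null(labels)) abort("labels must be supplied for a plain documents tibble")
  }
  if (nrow(documents) == 0) {
    return(tibble(
      gold_label = logical(0), n_patients = integer(0),
      docs_per_patient = numeric(0), sentences_per_patient = numeric(0),
      tokens_per_patient = numeric(0), sentences_per_document = numeric(0),
      tokens_per_document = numeric(0), tokens_per_sentence = numeric(0)
    ))
  }
  sents <- segment_corpus(documents)
  sents$tokens <- vapply(sents$text,
                         function(t) tokenize_and_truncate(t, backend)$token_count,
                         numeric(1), USE.NAMES = FALSE)
  sents <- left_join(sents, labels, by = "patient_id")
  per_doc <- sents %>%
    group_by(.data$gold_label, .data$patient_id, .data$doc_id) %>%
    summarise(n_sent = n(), n_tok = sum(.data$tokens), .groups = "drop")
  per_patient <- per_doc %>%
    group_by(.data$gold_label, .data$patient_id) %>%
    summarise(n_docs = n(), n_sent = sum(.data$n_sent),
              n_tok = sum(.data$n_tok), .groups = "drop")
  per_patient %>%
    group_by(.data$gold_label) %>%
    summarise(
      n_patients = n(),
      docs_per_patient = mean(.data$n_docs),
      sentences_per_patient = mean(.data$n_sent),
      tokens_per_patient = mean(.data$n_tok),
      .groups = "drop"
    ) %>%
    left_join(
      per_doc %>%
        group_by(.data$gold_label) %>%
        summarise(sentences_per_document = mean(.data$n_sent),
                  tokens_per_document = mean(.data$n_tok), .groups = "drop"),
      by = "gold_label"
    ) %>%
    left_join(
      sents %>%
        group_by(.data$gold_label) %>%
        summarise(tokens_per_sentence = mean(.data$tokens), .groups = "drop"),
      by = "gold_label"
    )
}

#' Mean tokens per sentence by indicator category
#'
#' @param annotations Annotation tibble from [annotate_corpus()].
#' @param backend An [embedding_backend()] supplying the tokenizer.
#'
#' @return A tibble with `category` and `tokens_per_sentence` for the matched
#'   categories.
#' @export
category_token_stats <- function(annotations, backend = embedding_backend()) {
  ann <- annotations[!is.na(annotations$category), , drop = FALSE]
  if (nrow(ann) == 0) {
    return(tibble(category = integer(0), n_sentences = integer(0),
                  tokens_per_sentence = numeric(0)))
  }
  ann$tokens <- vapply(ann$text,
                       function(t) tokenize_and_truncate(t, backend)$token_count,
                       numeric(1), USE.NAMES = FALSE)
  ann %>%
    group_by(.data$category) %>%
    summarise(n_sentences = n(),
              tokens_per_sentence = mean(.data$tokens), .groups = "drop")
}
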