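#' Read and write note corpora as JSON lines
#'
#' A corpus file holds one JSON object per line with fields `patient_id`,
#' `doc_id` and `text`. Gold labels travel in a sidecar CSV with columns
#' `patient_id`, `gold_label`, `profile_bits`.
#'
#' @param documents A tibble with columns `patient_id`, `doc_id`, `text`, or an
#'   `ad_cohort` (its documents are used).
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_corpus_jsonl <- function(documents, path) {
  if (inherits(documents, "ad_cohort")) documents <- documents$documents
  need <- c("patient_id", "doc_id", "text")
  if (!all(need %in% names(documents))) {
    abort("documents must have columns patient_id, doc_id, text")
  }
  lines <- vapply(seq_len(nrow(documents)), function(i) {
    jsonlite::toJSON(
      list(patient_id = documents$patient_id[i],
           doc_id = documents$doc_id[i],
           text = documents$text[i]),
      auto_unbox = TRUE
    )
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_corpus_jsonl
#' @export
read_corpus_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  rows <- purrr::imap(lines, function(l, i) {
    obj <- tryCatch(jsonlite::fromJSON(l), error = function(e) NULL)
    if (is.null(obj) || !all(c("patient_id", "doc_id", "text") %in% names(obj))) {
      abort(paste0("malformed corpus record at line ", i, " of ", path))
    }
    tibble(patient_id = obj$patient_id, doc_id = obj$doc_id, text = obj$text)
  })
  bind_rows(rows)
}

#' Write / read the gold-label sidecar for a cohort
#'
#' @param cohort An `ad_cohort` (or its `patients` tibble).
#' @param path CSV file path.
#'
#' @return `path` invisibly for the writer; a tibble with `patient_id`,
#'   `gold_label` and `profile_bits` for the reader.
#' @export
write_cohort_labels <- function(cohort, path) {
  patients <- if (inherits(cohort, "ad_cohort")) cohort$patients else cohort
  utils::write.csv(
    patients[, c("patient_id", "gold_label", "profile_bits")],
    path, row.names = FALSE
  )
  invisible(path)
}

#' @rdname write_cohort_labels
#' @export
read_cohort_labels <- function(path) {
  out <- as_tibble(utils::read.csv(path, colClasses = c(
    patient_id = "character", gold_label = "logical", profile_bits = "character"
  )))
  out
}
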