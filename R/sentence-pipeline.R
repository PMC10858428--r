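# Sentence segmentation, category matching and assertion classification.

# Abbreviations whose periods must not end a sentence.
ad_abbreviations <- function() {
  c("Dr.", "Mr.", "Mrs.", "Ms.", "St.", "vs.", "e.g.", "i.e.",
    "b.i.d.", "t.i.d.", "q.d.", "p.r.n.")
}

protect_abbrev <- function(text) {
  for (ab in ad_abbreviations()) {
    text <- gsub(ab, gsub(".", "\uE000", ab, fixed = TRUE), text, fixed = TRUE)
  }
  text
}

restore_abbrev <- function(text) gsub("\uE000", ".", text, fixed = TRUE)

#' Split a clinical note into sentences
#'
#' Rule-based segmentation: a sentence ends at `.`, `!` or `?` followed by
#' whitespace and a capital letter or digit, or at a hard newline. Periods in a
#' small list of protected abbreviations (Dr., b.i.d., ...) never end a
#' sentence. Whitespace is trimmed; empty fragments are dropped.
#'
#' @param text A single document string (UTF-8).
#'
#' @return A character vector of sentences, in document order; empty input
#'   gives `character(0)`.
#' @export
segment_document <- function(text) {
  if (length(text) != 1) abort("segment_document expects a single string")
  if (is.na(text) || !nzchar(trimws(text))) return(character(0))
  chunks <- strsplit(protect_abbrev(text), "\n+")[[1]]
  out <- unlist(strsplit(chunks, "(?<=[.!?])[ \t]+(?=[A-Z0-9])", perl = TRUE))
  out <- trimws(restore_abbrev(out))
  out[nzchar(out)]
}

#' Split every document of a corpus into sentences
#'
#' @param documents A tibble with `patient_id`, `doc_id`, `text` (or an
#'   `ad_cohort`).
#'
#' @return A tibble with one row per sentence: `patient_id`, `doc_id`,
#'   `sent_index` (ordinal within the document) and `text`.
#' @export
segment_corpus <- function(documents) {
  if (inherits(documents, "ad_cohort")) documents <- documents$documents
  chunks <- strsplit(protect_abbrev(documents$text), "\n+")
  sents <- purrr::map(chunks, function(ch) {
    s <- unlist(strsplit(ch, "(?<=[.!?])[ \t]+(?=[A-Z0-9])", perl = TRUE))
    s <- trimws(restore_abbrev(s))
    s[nzchar(s)]
  })
  n <- lengths(sents)
  tibble(
    patient_id = rep(documents$patient_id, n),
    doc_id = rep(documents$doc_id, n),
    sent_index = unlist(purrr::map(n, seq_len), use.names = FALSE) %||% integer(0),
    text = unlist(sents, use.names = FALSE) %||% character(0)
  )
}

# Word-boundary regex for a literal lowercase phrase.
phrase_regex <- function(phrase) {
  esc <- gsub("([\\^$.|?*+()\\[\\]{}\\\\])", "\\\\\\1", phrase, perl = TRUE)
  if (grepl("^[a-z0-9]", phrase)) esc <- paste0("\\b", esc)
  if (grepl("[a-z0-9]$", phrase)) esc <- paste0(esc, "\\b")
  esc
}

#' Match a sentence against the category lexicons
#'
#' A category matches when at least one of its keywords or phrases occurs in
#' the sentence, case-insensitively and anchored at word boundaries.
#'
#' @param text A single sentence string.
#' @param lexicon An [ad_lexicon][read_lexicon()].
#'
#' @return A sorted integer vector of matching category ids (possibly empty).
#' @export
match_categories <- function(text, lexicon = default_lexicon()) {
  if (length(text) != 1) abort("match_categories expects a single sentence")
  lc <- tolower(text)
  hit <- vapply(seq_len(nrow(lexicon$patterns)), function(i) {
    grepl(phrase_regex(lexicon$patterns$pattern[i]), lc, perl = TRUE)
  }, logical(1))
  sort(unique(lexicon$patterns$category[hit]))
}

# Positions (start, end) of all word-boundary matches of lowercase `phrase`
# in each of the lowercase `texts`. Returns a list of two-column matrices.
phrase_positions <- function(phrase, texts) {
  m <- gregexpr(phrase_regex(phrase), texts, perl = TRUE)
  purrr::map(m, function(mm) {
    if (mm[1] == -1) {
      matrix(numeric(0), ncol = 2)
    } else {
      cbind(as.integer(mm), as.integer(mm) + attr(mm, "match.length") - 1L)
    }
  })
}

status_rank <- function(status) {
  c(affirmed = 0, hypothetical = 1, experiencer_other = 2, negated = 3)[status]
}

# Core scope logic: given a keyword start position, modifier trigger spans with
# status/direction, and terminator start positions, return the assertion
# status. Forward triggers scope from their end to the next terminator (or
# sentence end); backward triggers from the previous terminator (or sentence
# start) to the trigger. Precedence: negated > experiencer_other >
# hypothetical > affirmed.
resolve_status <- function(kw_start, trig, term_starts) {
  if (nrow(trig) == 0) return("affirmed")
  best <- "affirmed"
  for (i in seq_len(nrow(trig))) {
    ts <- trig$start[i]; te <- trig$end[i]
    covered <- if (trig$direction[i] == "forward") {
      nxt <- term_starts[term_starts > te]
      kw_start > te && (length(nxt) == 0 || kw_start < min(nxt))
    } else {
      prev <- term_starts[term_starts < ts]
      kw_start < ts && (length(prev) == 0 || kw_start > max(prev))
    }
    if (covered && status_rank(trig$status[i]) > status_rank(best)) {
      best <- trig$status[i]
    }
  }
  best
}

#' Classify the assertion context of a category mention
#'
#' Applies a ConText-style trigger/scope rule set to decide whether a
#' sentence's mention of a category is affirmed for the patient, negated,
#' experienced by someone other than the patient, or hypothetical.
#'
#' @param text A single sentence.
#' @param category The matched category id (must be in
#'   `match_categories(text, lexicon)`).
#' @param lexicon An [ad_lexicon][read_lexicon()].
#'
#' @return One of `"affirmed"`, `"negated"`, `"experiencer_other"`,
#'   `"hypothetical"`.
#' @export
classify_assertion <- function(text, category, lexicon = default_lexicon()) {
  if (length(text) != 1) abort("classify_assertion expects a single sentence")
  if (!category %in% match_categories(text, lexicon)) {
    abort(paste0("category ", category, " does not match this sentence"))
  }
  ann <- annotate_sentences(
    tibble(patient_id = "x", doc_id = "x", sent_index = 1L, text = text),
    lexicon
  )
  ann$status[!is.na(ann$category) & ann$category == category][1]
}

#' Annotate sentences with category matches and assertion statuses
#'
#' The workhorse of the preprocessing stage: every sentence is matched against
#' the eight category lexicons and each match receives an assertion status.
#'
#' @param sentences A sentence tibble from [segment_corpus()] (columns
#'   `patient_id`, `doc_id`, `sent_index`, `text`).
#' @param lexicon An [ad_lexicon][read_lexicon()].
#'
#' @return A tibble with one row per (sentence, matched category) pair plus one
#'   row with `category = NA` for each unmatched sentence; columns
#'   `patient_id`, `doc_id`, `sent_index`, `text`, `category` (integer),
#'   `status` (character).
#' @export
annotate_sentences <- function(sentences, lexicon = default_lexicon()) {
  n <- nrow(sentences)
  empty <- tibble(
    patient_id = character(0), doc_id = character(0), sent_index = integer(0),
    text = character(0), category = integer(0), status = character(0)
  )
  if (n == 0) return(empty)
  lc <- tolower(sentences$text)

  # category matches with earliest keyword position per (sentence, category)
  kw_start <- matrix(Inf, nrow = n, ncol = 8)
  for (i in seq_len(nrow(lexicon$patterns))) {
    k <- lexicon$patterns$category[i]
    m <- regexpr(phrase_regex(lexicon$patterns$pattern[i]), lc, perl = TRUE)
    hit <- m != -1
    if (any(hit)) {
      kw_start[hit, k] <- pmin(kw_start[hit, k], as.integer(m[hit]))
    }
  }
  match_idx <- which(is.finite(kw_start), arr.ind = TRUE)
  if (nrow(match_idx) == 0) {
    return(bind_cols(sentences, tibble(category = NA_integer_,
                                       status = NA_character_)))
  }
  matched_rows <- sort(unique(match_idx[, 1]))
  sub_lc <- lc[matched_rows]
  pos_of <- match(seq_len(n), matched_rows)

  # terminator positions per matched sentence
  term_pos <- rep(list(numeric(0)), length(matched_rows))
  for (t in lexicon$terminators) {
    pp <- phrase_positions(t, sub_lc)
    for (j in seq_along(pp)) {
      if (nrow(pp[[j]]) > 0) term_pos[[j]] <- c(term_pos[[j]], pp[[j]][, 1])
    }
  }

  # trigger spans per matched sentence
  trig <- purrr::map(seq_along(matched_rows), function(j) {
    list(start = numeric(0), end = numeric(0),
         status = character(0), direction = character(0))
  })
  for (i in seq_len(nrow(lexicon$modifiers))) {
    pp <- phrase_positions(lexicon$modifiers$trigger[i], sub_lc)
    for (j in seq_along(pp)) {
      if (nrow(pp[[j]]) > 0) {
        trig[[j]]$start <- c(trig[[j]]$start, pp[[j]][, 1])
        trig[[j]]$end <- c(trig[[j]]$end, pp[[j]][, 2])
        trig[[j]]$status <- c(trig[[j]]$status,
                              rep(lexicon$modifiers$status[i], nrow(pp[[j]])))
        trig[[j]]$direction <- c(trig[[j]]$direction,
                                 rep(lexicon$modifiers$direction[i], nrow(pp[[j]])))
      }
    }
  }

  status <- character(nrow(match_idx))
  for (r in seq_len(nrow(match_idx))) {
    s_row <- match_idx[r, 1]; k <- match_idx[r, 2]
    j <- pos_of[s_row]
    status[r] <- resolve_status(
      kw_start[s_row, k],
      as.data.frame(trig[[j]], stringsAsFactors = FALSE),
      term_pos[[j]]
    )
  }

  matched_tbl <- bind_cols(
    sentences[match_idx[, 1], , drop = FALSE],
    tibble(category = as.integer(match_idx[, 2]), status = status)
  )
  unmatched_rows <- setdiff(seq_len(n), matched_rows)
  out <- bind_rows(
    matched_tbl,
    if (length(unmatched_rows) > 0) {
      bind_cols(sentences[unmatched_rows, , drop = FALSE],
                tibble(category = NA_integer_, status = NA_character_))
    }
  )
  arrange(out, .data$patient_id, .data$doc_id, .data$sent_index, .data$category)
}

#' Segment and annotate a whole corpus
#'
#' Convenience composition of [segment_corpus()] and [annotate_sentences()].
#'
#' @param corpus An `ad_cohort`, a document tibble (`patient_id`, `doc_id`,
#'   `text`) or a path to a JSON-lines corpus file.
#' @param lexicon An [ad_lexicon][read_lexicon()].
#'
#' @return The annotation tibble of [annotate_sentences()].
#' @export
annotate_corpus <- function(corpus, lexicon = default_lexicon()) {
  if (is.character(corpus) && length(corpus) == 1) {
    corpus <- read_corpus_jsonl(corpus)
  }
  annotate_sentences(segment_corpus(corpus), lexicon)
}

#' Write sentence annotations as JSON lines
#'
#' One JSON object per sentence with its matches:
#' `{"patient_id", "doc_id", "index", "text", "matches": [{"category", "status"}]}`.
#'
#' @param annotations An annotation tibble from [annotate_corpus()].
#' @param path Output file path.
#'
#' @return `path`, invisibly.
#' @export
write_annotations_jsonl <- function(annotations, path) {
  key <- paste(annotations$patient_id, annotations$doc_id, annotations$sent_index)
  groups <- split(seq_len(nrow(annotations)), factor(key, levels = unique(key)))
  lines <- vapply(groups, function(ix) {
    first <- ix[1]
    cats <- annotations$category[ix]
    matches <- if (all(is.na(cats))) {
      list()
    } else {
      purrr::map(ix[!is.na(cats)], function(i) {
        list(category = annotations$category[i], status = annotations$status[i])
      })
    }
    jsonlite::toJSON(
      list(
        patient_id = annotations$patient_id[first],
        doc_id = annotations$doc_id[first],
        index = annotations$sent_index[first],
        text = annotations$text[first],
        matches = matches
      ),
      auto_unbox = TRUE
    )
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}
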