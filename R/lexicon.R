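#' Indicator categories
#'
#' The eight evidence categories that make up the patient vector, in their
#' fixed order: (1) direct mention of AD, (2) hay fever allergies, (3) atopic
#' allergies, (4) eczema or rashes, (5) dry or itchy skin, (6) nonasthma
#' medications related to treating AD, (7) asthma, (8) asthma medications.
#'
#' @return A tibble with columns `category` (integer 1..8) and `label`.
#' @export
indicator_categories <- function() {
  tibble(
    category = 1:8,
    label = c(
      "direct mention of AD", "hay fever allergies", "atopic allergies",
      "eczema or rashes", "dry or itchy skin", "nonasthma medications",
      "asthma", "asthma medications"
    )
  )
}

assertion_statuses <- function() {
  c("affirmed", "negated", "experiencer_other", "hypothetical")
}

#' Read a category lexicon from a directory
#'
#' A lexicon directory contains `cat1.txt` .. `cat8.txt` (one case-insensitive
#' keyword or phrase per line; `#` starts a comment), `modifiers.txt`
#' (tab-separated columns: trigger, status, direction) and `terminators.txt`
#' (one scope-terminating token per line).
#'
#' @param dir Path to a lexicon directory. Defaults to the lexicon shipped with
#'   the package.
#'
#' @return An object of class `ad_lexicon`: a list with elements `patterns`
#'   (tibble: `category`, `pattern`), `modifiers` (tibble: `trigger`, `status`,
#'   `direction`) and `terminators` (character vector).
#' @export
read_lexicon <- function(dir = default_lexicon_dir()) {
  if (!dir.exists(dir)) {
    abort(paste0("lexicon directory not found: ", dir))
  }
  read_lines <- function(path) {
    x <- readLines(path, encoding = "UTF-8", warn = FALSE)
    x <- trimws(sub("#.*$", "", x))
    x[nzchar(x)]
  }
  patterns <- purrr::map_dfr(1:8, function(k) {
    path <- file.path(dir, sprintf("cat%d.txt", k))
    if (!file.exists(path)) abort(paste0("missing lexicon file: ", path))
    pats <- read_lines(path)
    if (length(pats) == 0) abort(paste0("category ", k, " has no patterns"))
    tibble(category = k, pattern = tolower(pats))
  })
  mod_path <- file.path(dir, "modifiers.txt")
  if (!file.exists(mod_path)) abort(paste0("missing modifiers file: ", mod_path))
  mods <- strsplit(read_lines(mod_path), "\t", fixed = TRUE)
  bad <- lengths(mods) != 3
  if (any(bad)) abort("modifiers.txt lines must have 3 tab-separated fields")
  modifiers <- tibble(
    trigger = tolower(vapply(mods, `[`, "", 1)),
    status = vapply(mods, `[`, "", 2),
    direction = vapply(mods, `[`, "", 3)
  )
  if (!all(modifiers$status %in% assertion_statuses()[-1])) {
    abort("modifier status must be negated, experiencer_other or hypothetical")
  }
  if (!all(modifiers$direction %in% c("forward", "backward"))) {
    abort("modifier direction must be forward or backward")
  }
  term_path <- file.path(dir, "terminators.txt")
  if (!file.exists(term_path)) abort(paste0("missing terminators file: ", term_path))
  structure(
    list(
      patterns = patterns,
      modifiers = modifiers,
      terminators = tolower(read_lines(term_path))
    ),
    class = "ad_lexicon"
  )
}

#' Default lexicon shipped with the package
#'
#' @return The `ad_lexicon` object built from the package's default keyword,
#'   modifier and terminator files.
#' @export
default_lexicon <- function() {
  read_lexicon(default_lexicon_dir())
}

default_lexicon_dir <- function() {
  system.file("extdata", "lexicon", package = "adpheno", mustWork = TRUE)
}

#' Add a keyword pattern to a lexicon
#'
#' @param lex An `ad_lexicon`.
#' @param category Integer category id (1..8).
#' @param pattern A literal keyword or phrase (matched case-insensitively at
#'   word boundaries).
#'
#' @return The modified `ad_lexicon`.
#' @export
lexicon_add_pattern <- function(lex, category, pattern) {
  stopifnot(inherits(lex, "ad_lexicon"), category %in% 1:8)
  lex$patterns <- bind_rows(
    lex$patterns,
    tibble(category = as.integer(category), pattern = tolower(pattern))
  )
  lex
}

#' @export
print.ad_lexicon <- function(x, ...) {
  cat("<ad_lexicon>", nrow(x$patterns), "patterns across 8 categories;",
      nrow(x$modifiers), "modifier triggers;",
      length(x$terminators), "terminators\n")
  invisible(x)
}
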