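#' UK Working Party (UKWP) diagnostic rule for atopic dermatitis
#'
#' The UKWP criteria label a patient as having atopic dermatitis (AD) when the
#' mandatory criterion — an itchy skin condition — is present together with at
#' least three of five minor criteria: a history of flexural involvement, a
#' history of asthma or hay fever, a history of dry skin, onset of rash at age
#' two or younger, and visible flexural dermatitis.
#'
#' @param profile A data frame (or single-row tibble) with logical columns
#'   `itchy_skin`, `flexural_history`, `asthma_or_hayfever_history`,
#'   `dry_skin_history`, `onset_age_le_2`, `visible_flexural_dermatitis`.
#'   Multiple rows are labelled row-wise.
#'
#' @return A logical vector, one label per row of `profile`: `TRUE` when the
#'   profile satisfies the UKWP rule.
#'
#' @examples
#' ukwp_label(ukwp_profile(
#'   itchy_skin = TRUE, flexural_history = TRUE,
#'   asthma_or_hayfever_history = TRUE, dry_skin_history = TRUE
#' ))
#' @export
ukwp_label <- function(profile) {
  profile <- as_tibble(profile)
  miss <- setdiff(ukwp_flag_names(), names(profile))
  if (length(miss) > 0) {
    abort(paste0("profile is missing UKWP flags: ", paste(miss, collapse = ", ")))
  }
  flags <- profile[ukwp_flag_names()]
  if (!all(vapply(flags, is.logical, logical(1))) || anyNA(flags)) {
    abort("all six UKWP flags must be non-missing logicals")
  }
  minors <- ukwp_flag_names()[-1]
  profile$itchy_skin & rowSums(as.matrix(flags[minors])) >= 3
}

ukwp_flag_names <- function() {
  c(
    "itchy_skin", "flexural_history", "asthma_or_hayfever_history",
    "dry_skin_history", "onset_age_le_2", "visible_flexural_dermatitis"
  )
}

#' Construct a UKWP criterion profile
#'
#' @param itchy_skin,flexural_history,asthma_or_hayfever_history,dry_skin_history,onset_age_le_2,visible_flexural_dermatitis
#'   Logical flags; the first is the mandatory criterion, the remaining five are
#'   the minor criteria.
#'
#' @return A one-row tibble with the six logical flags.
#' @export
ukwp_profile <- function(itchy_skin = FALSE,
                         flexural_history = FALSE,
                         asthma_or_hayfever_history = FALSE,
                         dry_skin_history = FALSE,
                         onset_age_le_2 = FALSE,
                         visible_flexural_dermatitis = FALSE) {
  tibble(
    itchy_skin = as.logical(itchy_skin),
    flexural_history = as.logical(flexural_history),
    asthma_or_hayfever_history = as.logical(asthma_or_hayfever_history),
    dry_skin_history = as.logical(dry_skin_history),
    onset_age_le_2 = as.logical(onset_age_le_2),
    visible_flexural_dermatitis = as.logical(visible_flexural_dermatitis)
  )
}

# All 64 possible profiles, in a fixed enumeration order.
ukwp_all_profiles <- function() {
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), 6), KEEP.OUT.ATTRS = FALSE)
  names(grid) <- ukwp_flag_names()
  as_tibble(grid)
}

#' Sample UKWP profiles consistent with a target AD label
#'
#' Draws uniformly from the set of criterion profiles whose [ukwp_label()] value
#' equals `target_label` (16 of the 64 possible profiles are AD-positive).
#'
#' @param n Number of profiles to draw.
#' @param target_label Logical; the AD label the sampled profiles must satisfy.
#' @param seed Optional integer seed; when supplied, sampling is reproducible
#'   and the caller's RNG state is untouched.
#'
#' @return A tibble with `n` rows and the six UKWP flag columns.
#' @export
sample_profile <- function(n, target_label, seed = NULL) {
  pool <- ukwp_all_profiles()
  pool <- pool[ukwp_label(pool) == target_label, , drop = FALSE]
  draw <- function() pool[runif_int(n, 1L, nrow(pool)), , drop = FALSE]
  out <- if (is.null(seed)) draw() else with_seed(seed, draw())
  as_tibble(out)
}
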