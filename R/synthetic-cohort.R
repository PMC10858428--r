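#' Noise configuration for the synthetic cohort generator
#'
#' Controls how faithfully a patient's rendered notes reflect their underlying
#' UKWP criterion profile. All rates are probabilities in `[0, 1]`.
#'
#' @param miss_rate Probability that a true criterion produces no mention at
#'   all in the patient's notes.
#' @param spurious_rate Probability that an inactive indicator category still
#'   produces a non-affirmed (negated / other-experiencer / hypothetical)
#'   mention somewhere in the record.
#' @param negated_fraction,other_experiencer_fraction,hypothetical_fraction
#'   Fractions of non-guaranteed mentions rendered in each non-affirmed
#'   assertion context; their sum must not exceed 1. One mention per active
#'   category is kept affirmed (provided the three fractions sum below 1) so a
#'   true criterion remains detectable.
#' @param docs_per_patient Integer range `c(lo, hi)`: number of documents per
#'   patient.
#' @param distractor_sentences_per_doc Integer range `c(lo, hi)`: number of
#'   keyword-free filler sentences per document.
#'
#' @return A list of class `ad_noise_config`.
#' @export
noise_config <- function(miss_rate = 0,
                         spurious_rate = 0,
                         negated_fraction = 0,
                         other_experiencer_fraction = 0,
                         hypothetical_fraction = 0,
                         docs_per_patient = c(2L, 6L),
                         distractor_sentences_per_doc = c(1L, 4L)) {
  probs <- c(miss_rate, spurious_rate, negated_fraction,
             other_experiencer_fraction, hypothetical_fraction)
  if (any(probs < 0 | probs > 1)) abort("all noise rates must lie in [0, 1]")
  if (negated_fraction + other_experiencer_fraction + hypothetical_fraction > 1) {
    abort("negated + other-experiencer + hypothetical fractions must not exceed 1")
  }
  rng_ok <- function(r) length(r) == 2 && all(r == floor(r)) && r[1] <= r[2]
  if (!rng_ok(docs_per_patient) || docs_per_patient[1] < 1) {
    abort("docs_per_patient must be an integer range c(lo, hi) with lo >= 1")
  }
  if (!rng_ok(distractor_sentences_per_doc) || distractor_sentences_per_doc[1] < 0) {
    abort("distractor_sentences_per_doc must be an integer range with lo >= 0")
  }
  structure(
    list(
      miss_rate = miss_rate, spurious_rate = spurious_rate,
      negated_fraction = negated_fraction,
      other_experiencer_fraction = other_experiencer_fraction,
      hypothetical_fraction = hypothetical_fraction,
      docs_per_patient = as.integer(docs_per_patient),
      distractor_sentences_per_doc = as.integer(distractor_sentences_per_doc)
    ),
    class = "ad_noise_config"
  )
}

#' Structural parameters of the synthetic cohort
#'
#' These describe how the six UKWP criterion flags surface as the eight
#' indicator categories, independent of the noise model:
#' itchy/dry skin map to category 5; flexural involvement, visible flexural
#' dermatitis and early-onset rash to category 4; an asthma-or-hay-fever
#' history is realized per record as asthma (category 7) and/or hay fever
#' (category 2) sub-draws; asthma patients also carry asthma medications
#' (category 8); AD-positive patients carry AD-directed nonasthma medications
#' (category 6), may carry atopic-allergy comorbidity (category 3), and
#' mention the diagnosis itself (category 1) with probability `cat1_prob`.
#'
#' @param cat1_prob Probability an AD-positive record names the diagnosis
#'   directly (category 1); direct mentions are deliberately not guaranteed, as
#'   they can also occur in non-affirming contexts.
#' @param cat3_prob_ad,cat3_prob_non_ad Probability of an atopic-allergy
#'   comorbidity (category 3) for AD-positive / AD-negative patients.
#' @param asthma_sub_prob,hayfever_sub_prob Per-record probabilities that an
#'   asthma-or-hay-fever history surfaces as asthma and as hay fever (at least
#'   one is forced).
#' @param multi_category_rate Probability per document of one extra sentence
#'   carrying two categories at once.
#'
#' @return A list of class `ad_cohort_structure`.
#' @export
cohort_structure <- function(cat1_prob = 0.8,
                             cat3_prob_ad = 0.6,
                             cat3_prob_non_ad = 0.15,
                             asthma_sub_prob = 0.6,
                             hayfever_sub_prob = 0.6,
                             multi_category_rate = 0.05) {
  probs <- c(cat1_prob, cat3_prob_ad, cat3_prob_non_ad, asthma_sub_prob,
             hayfever_sub_prob, multi_category_rate)
  if (any(probs < 0 | probs > 1)) abort("all structural rates must lie in [0, 1]")
  structure(
    list(
      cat1_prob = cat1_prob, cat3_prob_ad = cat3_prob_ad,
      cat3_prob_non_ad = cat3_prob_non_ad, asthma_sub_prob = asthma_sub_prob,
      hayfever_sub_prob = hayfever_sub_prob,
      multi_category_rate = multi_category_rate
    ),
    class = "ad_cohort_structure"
  )
}

# Sentence templates. Affirmed templates contain exactly one default-lexicon
# keyword of their category and no modifier triggers or terminators.
ad_templates <- function() {
  list(
    affirmed = list(
      `1` = c("Patient carries a diagnosis of atopic dermatitis.",
              "Assessment: atopic dermatitis, currently stable.",
              "She has longstanding atopic eczema."),
      `2` = c("Patient has hay fever every spring.",
              "Reports allergic rhinitis symptoms this season.",
              "Seasonal allergies are currently well controlled."),
      `3` = c("Known peanut allergy since childhood.",
              "Patient has a documented food allergy.",
              "History of atopy noted in the chart."),
      `4` = c("Eczema noted on both arms.",
              "Erythematous rash over the forearms.",
              "Flexural involvement of the elbows observed today.",
              "Visible flexural dermatitis on examination."),
      `5` = c("Patient reports dry skin on the hands.",
              "Complains of itchy patches at night.",
              "Pruritus has worsened over the winter.",
              "Skin examination shows xerosis."),
      `6` = c("Prescribed triamcinolone cream for the skin.",
              "Continues dupilumab injections every two weeks.",
              "Applying hydrocortisone to the affected areas.",
              "Started tacrolimus ointment twice daily."),
      `7` = c("Patient has asthma since childhood.",
              "Asthma remains well controlled on the current regimen.",
              "Wheezing noted on exertion."),
      `8` = c("Uses albuterol inhaler as needed.",
              "Taking montelukast nightly for airway symptoms.",
              "Continues omalizumab injections monthly.",
              "Refilled proair hfa inhaler today.")
    ),
    # keyword surface forms slotted into non-affirmed templates
    keywords = list(
      `1` = c("atopic dermatitis", "atopic eczema"),
      `2` = c("hay fever", "allergic rhinitis"),
      `3` = c("peanut allergy", "food allergy"),
      `4` = c("eczema", "rash"),
      `5` = c("dry skin", "itching"),
      `6` = c("triamcinolone", "dupilumab"),
      `7` = c("asthma", "wheezing"),
      `8` = c("albuterol", "montelukast")
    ),
    onset = c("Rash began before age 2 per the parents.",
              "Rash has been present since age 1."),
    multi = list(
      list(cats = c(4L, 2L), text = "Eczema flares worsen during hay fever season."),
      list(cats = c(5L, 4L), text = "Itchy rash noted on both forearms."),
      list(cats = c(7L, 8L), text = "Asthma managed with albuterol as needed.")
    ),
    distractor = c(
      "Vital signs within normal limits.",
      "Patient ambulating independently.",
      "Follow up in three months.",
      "Blood pressure 120 over 80 today.",
      "Reviewed laboratory results with the patient.",
      "Patient feels well today.",
      "Immunizations are up to date.",
      "Diet and exercise counseling provided.",
      "Sleep has been adequate recently.",
      "Works as an accountant downtown."
    )
  )
}

render_nonaffirmed <- function(status, keyword) {
  switch(status,
    negated = paste0("No ", keyword, " reported today."),
    experiencer_other = paste0("Mother has ", keyword, "."),
    hypothetical = paste0("Monitor for ", keyword, " going forward.")
  )
}

# Decide which indicator categories a profile activates, with per-record
# sub-draws. Returns an integer vector of active categories plus whether the
# early-onset sentence is emitted.
active_categories <- function(profile, gold, structure) {
  active <- integer(0)
  if (gold && runif(1) < structure$cat1_prob) active <- c(active, 1L)
  if (profile$asthma_or_hayfever_history) {
    asthma <- runif(1) < structure$asthma_sub_prob
    hay <- runif(1) < structure$hayfever_sub_prob
    if (!asthma && !hay) {
      if (runif(1) < 0.5) asthma <- TRUE else hay <- TRUE
    }
    if (hay) active <- c(active, 2L)
    if (asthma) active <- c(active, 7L, 8L)
  }
  p3 <- if (gold) structure$cat3_prob_ad else structure$cat3_prob_non_ad
  if (runif(1) < p3) active <- c(active, 3L)
  if (profile$flexural_history || profile$visible_flexural_dermatitis) {
    active <- c(active, 4L)
  }
  if (profile$itchy_skin || profile$dry_skin_history) active <- c(active, 5L)
  if (gold) active <- c(active, 6L)
  list(categories = sort(unique(active)), onset = isTRUE(profile$onset_age_le_2))
}

#' Render one synthetic patient record
#'
#' Turns a UKWP criterion profile into a set of synthetic clinical-note
#' documents. Every active indicator category that survives `miss_rate` gets
#' one guaranteed affirmed sentence built from a default-lexicon keyword;
#' further mentions are spread across the patient's documents with assertion
#' contexts drawn from the noise fractions. Inactive categories may receive
#' spurious non-affirmed mentions; distractor sentences contain no category
#' keywords.
#'
#' @param profile A one-row UKWP profile (see [ukwp_profile()]).
#' @param noise An [noise_config()] object.
#' @param patient_id Identifier recorded on every document.
#' @param structure A [cohort_structure()] object.
#' @param seed Optional integer seed for reproducible rendering.
#'
#' @return A list of class `ad_patient_record`: `patient_id`, `documents`
#'   (tibble `patient_id`, `doc_id`, `text`), `gold_profile` (one-row tibble)
#'   and `gold_label`.
#' @export
render_record <- function(profile, noise = noise_config(),
                          patient_id = "P0001",
                          structure = cohort_structure(), seed = NULL) {
  if (!inherits(noise, "ad_noise_config")) abort("noise must be a noise_config()")
  run <- function() render_record_impl(profile, noise, patient_id, structure)
  if (is.null(seed)) run() else with_seed(seed, run())
}

render_record_impl <- function(profile, noise, patient_id, structure) {
  tpl <- ad_templates()
  profile <- as_tibble(profile)[ukwp_flag_names()]
  gold <- ukwp_label(profile)
  act <- active_categories(profile, gold, structure)
  cats <- act$categories
  # miss_rate: drop whole categories
  if (length(cats) > 0 && noise$miss_rate > 0) {
    cats <- cats[runif(length(cats)) >= noise$miss_rate]
  }
  n_docs <- runif_int(1, noise$docs_per_patient[1], noise$docs_per_patient[2])
  doc_sentences <- rep(list(character(0)), n_docs)

  frac <- c(noise$negated_fraction, noise$other_experiencer_fraction,
            noise$hypothetical_fraction)
  draw_status <- function() {
    u <- runif(1)
    if (u < frac[1]) "negated"
    else if (u < frac[1] + frac[2]) "experiencer_other"
    else if (u < sum(frac)) "hypothetical"
    else "affirmed"
  }
  sentence_for <- function(k, status) {
    if (status == "affirmed") {
      pool <- tpl$affirmed[[as.character(k)]]
      pool[runif_int(1, 1L, length(pool))]
    } else {
      kws <- tpl$keywords[[as.character(k)]]
      render_nonaffirmed(status, kws[runif_int(1, 1L, length(kws))])
    }
  }

  for (k in cats) {
    home <- runif_int(1, 1L, n_docs)
    home_status <- if (sum(frac) < 1) "affirmed" else draw_status()
    doc_sentences[[home]] <- c(doc_sentences[[home]], sentence_for(k, home_status))
    for (d in setdiff(seq_len(n_docs), home)) {
      doc_sentences[[d]] <- c(doc_sentences[[d]], sentence_for(k, draw_status()))
    }
  }
  if (act$onset && noise$miss_rate < 1 &&
      (noise$miss_rate == 0 || runif(1) >= noise$miss_rate)) {
    d <- runif_int(1, 1L, n_docs)
    doc_sentences[[d]] <- c(doc_sentences[[d]],
                            tpl$onset[runif_int(1, 1L, length(tpl$onset))])
  }
  # spurious non-affirmed mentions of inactive categories
  if (noise$spurious_rate > 0) {
    for (k in setdiff(1:8, cats)) {
      if (runif(1) < noise$spurious_rate) {
        d <- runif_int(1, 1L, n_docs)
        status <- c("negated", "experiencer_other", "hypothetical")[runif_int(1, 1L, 3L)]
        doc_sentences[[d]] <- c(doc_sentences[[d]], sentence_for(k, status))
      }
    }
  }
  # occasional two-category sentences, only from categories already active
  for (d in seq_len(n_docs)) {
    if (runif(1) < structure$multi_category_rate) {
      ok <- purrr::keep(tpl$multi, ~ all(.x$cats %in% cats))
      if (length(ok) > 0) {
        pick <- ok[[runif_int(1, 1L, length(ok))]]
        doc_sentences[[d]] <- c(doc_sentences[[d]], pick$text)
      }
    }
    n_dis <- runif_int(1, noise$distractor_sentences_per_doc[1],
                       noise$distractor_sentences_per_doc[2])
    if (n_dis > 0) {
      doc_sentences[[d]] <- c(
        doc_sentences[[d]],
        tpl$distractor[runif_int(n_dis, 1L, length(tpl$distractor))]
      )
    }
    # shuffle sentence order within the document
    s <- doc_sentences[[d]]
    if (length(s) > 1) doc_sentences[[d]] <- s[order(runif(length(s)))]
  }
  docs <- tibble(
    patient_id = patient_id,
    doc_id = sprintf("%s-D%02d", patient_id, seq_len(n_docs)),
    text = vapply(doc_sentences, paste, "", collapse = " ")
  )
  structure(
    list(patient_id = patient_id, documents = docs,
         gold_profile = profile, gold_label = gold),
    class = "ad_patient_record"
  )
}

#' Generate a synthetic AD cohort
#'
#' Samples UKWP criterion profiles consistent with the requested gold labels
#' and renders each patient's clinical notes. Defaults mirror the reference
#' cohort composition of 137 AD-positive and 1789 AD-negative patients.
#'
#' @param n_ad,n_non_ad Number of AD-positive / AD-negative patients.
#' @param seed Integer master seed; identical arguments give byte-identical
#'   cohorts.
#' @param noise A [noise_config()].
#' @param structure A [cohort_structure()].
#'
#' @return An object of class `ad_cohort`: a list with `documents` (tibble:
#'   `patient_id`, `doc_id`, `text`) and `patients` (tibble: `patient_id`,
#'   `gold_label`, the six UKWP flags, `profile_bits`).
#' @export
generate_cohort <- function(n_ad = 137, n_non_ad = 1789, seed = 1,
                            noise = noise_config(),
                            structure = cohort_structure()) {
  if (n_ad < 0 || n_non_ad < 0) abort("n_ad and n_non_ad must be non-negative")
  n <- n_ad + n_non_ad
  labels <- with_seed(derive_seed(seed, 1L), {
    sample(c(rep(TRUE, n_ad), rep(FALSE, n_non_ad)))
  })
  profiles <- bind_rows(
    if (n_ad > 0) sample_profile(n_ad, TRUE, seed = derive_seed(seed, 2L)),
    if (n_non_ad > 0) sample_profile(n_non_ad, FALSE, seed = derive_seed(seed, 3L))
  )
  # interleave sampled profiles in label order
  idx <- integer(n)
  idx[labels] <- seq_len(n_ad)
  idx[!labels] <- n_ad + seq_len(n_non_ad)
  profiles <- profiles[idx, , drop = FALSE]
  ids <- sprintf("P%05d", seq_len(n))
  records <- purrr::map(seq_len(n), function(i) {
    render_record(profiles[i, ], noise = noise, patient_id = ids[i],
                  structure = structure, seed = derive_seed(seed, 10L + i))
  })
  patients <- tibble(
    patient_id = ids,
    gold_label = labels
  ) %>%
    bind_cols(as_tibble(profiles)) %>%
    mutate(profile_bits = apply(as.matrix(as_tibble(profiles)), 1,
                                function(r) paste(as.integer(r), collapse = "")))
  structure(
    list(
      documents = purrr::map_dfr(records, "documents"),
      patients = patients
    ),
    class = "ad_cohort"
  )
}

#' @export
print.ad_cohort <- function(x, ...) {
  cat("<ad_cohort>", nrow(x$patients), "patients (",
      sum(x$patients$gold_label), "AD /", sum(!x$patients$gold_label),
      "non-AD ),", nrow(x$documents), "documents\n")
  invisible(x)
}

#' @export
print.ad_patient_record <- function(x, ...) {
  cat("<ad_patient_record>", x$patient_id, "-", nrow(x$documents),
      "documents, gold label:", x$gold_label, "\n")
  invisible(x)
}
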