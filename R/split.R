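#' Cohort split: balanced train, balanced test and prevalence-matched test
#'
#' Mirrors the reference study design. `floor(train_fraction * P)` of the P
#' AD-positive patients form the training positives, matched by an equal
#' seeded undersample of the negatives. The remaining positives form *both*
#' test sets: the balanced test set pairs them with an equal number of unused
#' negatives; the unbalanced test set pairs the same positives with enough
#' unused negatives to bring the positive prevalence closest to
#' `prevalence_target` (or exactly `unbalanced_negatives` when supplied). No
#' negative is reused across partitions.
#'
#' @param labels A tibble with `patient_id` and `gold_label`, or an
#'   `ad_cohort`.
#' @param train_fraction Fraction of positives assigned to training (default
#'   0.8).
#' @param unbalanced_negatives Optional explicit negative count for the
#'   unbalanced test set; overrides `prevalence_target`.
#' @param prevalence_target Target positive prevalence of the unbalanced test
#'   set (default 0.30, the approximate population prevalence of AD).
#' @param seed Integer seed; identical inputs give identical partitions.
#'
#' @return An object of class `cohort_split` with character-vector elements
#'   `train`, `test_balanced`, `test_unbalanced` plus a `membership` tibble
#'   (`patient_id`, `split`).
#' @export
split_cohort <- function(labels, train_fraction = 0.8,
                         unbalanced_negatives = NULL,
                         prevalence_target = 0.30, seed = 1) {
  if (inherits(labels, "ad_cohort")) labels <- labels$patients
  labels <- as_tibble(labels)[, c("patient_id", "gold_label")]
  pos <- labels$patient_id[labels$gold_label]
  neg <- labels$patient_id[!labels$gold_label]
  n_train_pos <- floor(train_fraction * length(pos))
  n_test_pos <- length(pos) - n_train_pos
  if (n_train_pos < 1 || n_test_pos < 1) {
    abort("not enough positive patients to form train and test sets")
  }
  n_unbal_neg <- unbalanced_negatives %||% {
    # negative count whose prevalence is closest to the target
    cand <- 0:max(0, length(neg))
    prev <- n_test_pos / (n_test_pos + cand)
    cand[which.min(abs(prev - prevalence_target))]
  }
  need_neg <- n_train_pos + n_test_pos + n_unbal_neg
  if (length(neg) < need_neg) {
    abort(paste0(
      "insufficient negative patients: need ", need_neg, " (",
      n_train_pos, " train + ", n_test_pos, " balanced test + ",
      n_unbal_neg, " unbalanced test), have ", length(neg)
    ))
  }
  with_seed(seed, {
    test_pos <- sample(pos, n_test_pos)
    train_pos <- setdiff(pos, test_pos)
    neg_perm <- sample(neg)
    train_neg <- neg_perm[seq_len(n_train_pos)]
    bal_neg <- neg_perm[n_train_pos + seq_len(n_test_pos)]
    unbal_neg <- if (n_unbal_neg > 0) {
      neg_perm[n_train_pos + n_test_pos + seq_len(n_unbal_neg)]
    } else {
      character(0)
    }
    membership <- bind_rows(
      tibble(patient_id = c(train_pos, train_neg), split = "train"),
      tibble(patient_id = c(test_pos, bal_neg), split = "test_balanced"),
      tibble(patient_id = c(test_pos, unbal_neg), split = "test_unbalanced")
    )
    structure(
      list(
        train = c(train_pos, train_neg),
        test_balanced = c(test_pos, bal_neg),
        test_unbalanced = c(test_pos, unbal_neg),
        membership = membership,
        seed = as.integer(seed)
      ),
      class = "cohort_split"
    )
  })
}

#' @export
print.cohort_split <- function(x, ...) {
  cat("<cohort_split> train", length(x$train), "- balanced test",
      length(x$test_balanced), "- unbalanced test",
      length(x$test_unbalanced), "\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.cohort_split <- function(x, ...) {
  x$membership
}
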