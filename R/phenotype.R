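#' Fit the full phenotype classifier roster and evaluate it
#'
#' Tunes and trains every requested model family on the balanced training
#' partition, adds a stacking ensemble over them, and evaluates each on the
#' balanced and prevalence-matched test partitions with the six standard
#' metrics.
#'
#' @param vectors Patient-vector tibble for the whole cohort.
#' @param labels Tibble with `patient_id`, `gold_label` (or an `ad_cohort`).
#' @param split A [cohort_split][split_cohort()].
#' @param families Character vector of families (default: all of
#'   [ad_model_families()]).
#' @param grids Named list of hyperparameter grids (default
#'   [default_grids()]).
#' @param seed Integer seed.
#' @param stacking Include the stacking ensemble (default TRUE; requires at
#'   least 2 families).
#'
#' @return An object of class `ad_phenotype_fit` with elements `models`
#'   (named list of [ad_model][tune_and_train()]), `metrics` (tibble: `model`,
#'   `test_set`, confusion counts and the six metrics) and `predictions`.
#' @export
ad_phenotype <- function(vectors, labels, split,
                         families = ad_model_families(),
                         grids = default_grids(), seed = 1,
                         stacking = TRUE) {
  if (inherits(labels, "ad_cohort")) labels <- labels$patients
  labels <- as_tibble(labels)[, c("patient_id", "gold_label")]
  pick <- function(ids) {
    v <- vectors[match(ids, vectors$patient_id), , drop = FALSE]
    if (anyNA(v$patient_id)) abort("split references patients without vectors")
    v
  }
  train_v <- pick(split$train)
  eval_sets <- list(
    test_balanced = pick(split$test_balanced),
    test_unbalanced = pick(split$test_unbalanced)
  )
  gold_of <- function(v) labels$gold_label[match(v$patient_id, labels$patient_id)]

  models <- list()
  predictions <- list()
  rows <- list()
  for (fam in families) {
    m <- tune_and_train(train_v, labels, fam, grid = grids[[fam]],
                        seed = derive_seed(seed, match(fam, ad_model_families())))
    models[[fam]] <- m
    for (set_name in names(eval_sets)) {
      ev <- eval_sets[[set_name]]
      pred <- predict(m, ev)
      predictions[[paste(fam, set_name, sep = ".")]] <-
        tibble(model = fam, test_set = set_name, patient_id = ev$patient_id,
               predicted = pred, gold = gold_of(ev))
      cc <- confusion_counts(pred, gold_of(ev))
      rows[[paste(fam, set_name)]] <- bind_cols(
        tibble(model = fam, test_set = set_name,
               TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN),
        compute_metrics(cc)
      )
    }
  }
  if (stacking && length(models) >= 2) {
    for (set_name in names(eval_sets)) {
      ev <- eval_sets[[set_name]]
      pred <- stacking_predict(models, train_v, labels, ev,
                               seed = derive_seed(seed, 55L))
      predictions[[paste("stacking", set_name, sep = ".")]] <-
        tibble(model = "stacking", test_set = set_name,
               patient_id = ev$patient_id, predicted = pred, gold = gold_of(ev))
      cc <- confusion_counts(pred, gold_of(ev))
      rows[[paste("stacking", set_name)]] <- bind_cols(
        tibble(model = "stacking", test_set = set_name,
               TP = cc$TP, TN = cc$TN, FP = cc$FP, FN = cc$FN),
        compute_metrics(cc)
      )
    }
  }
  structure(
    list(models = models, metrics = bind_rows(rows),
         predictions = bind_rows(predictions), seed = as.integer(seed)),
    class = "ad_phenotype_fit"
  )
}

#' @export
print.ad_phenotype_fit <- function(x, ...) {
  cat("<ad_phenotype_fit>", length(x$models), "model families + stacking\n")
  best <- glance(x)
  cat("best balanced-test accuracy:", sprintf("%.4f", best$accuracy),
      "(", best$model, ")\n")
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.ad_phenotype_fit <- function(x, ...) {
  x$metrics
}

#' @exportS3Method generics::glance
glance.ad_phenotype_fit <- function(x, ...) {
  bal <- x$metrics[x$metrics$test_set == "test_balanced", , drop = FALSE]
  bal[which.max(bal$accuracy), , drop = FALSE]
}

#' Plot the six evaluation metrics per model and test set
#'
#' @param object An `ad_phenotype_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.ad_phenotype_fit <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$metrics,
    c("accuracy", "precision", "recall", "f1", "npv", "specificity"),
    names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$model, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~test_set, ncol = 1) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "metric value") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a cohort's patient vectors as a heatmap
#'
#' @param vectors Patient-vector tibble.
#' @param labels Optional tibble with `patient_id`, `gold_label` used to
#'   order and facet rows.
#' @return A ggplot object.
#' @export
plot_patient_vectors <- function(vectors, labels = NULL) {
  long <- tidyr::pivot_longer(vectors, paste0("v", 1:8),
                              names_to = "element", values_to = "value")
  if (!is.null(labels)) {
    long <- left_join(long, labels[, c("patient_id", "gold_label")],
                      by = "patient_id")
  }
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$element,
                                          y = .data$patient_id,
                                          fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "vector element", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
  if (!is.null(labels)) {
    p <- p + ggplot2::facet_grid(gold_label ~ ., scales = "free_y",
                                 space = "free_y")
  }
  p
}
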