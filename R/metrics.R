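#' Confusion counts for binary phenotype predictions
#'
#' @param predicted Logical (or 0/1) vector of predicted labels; positive
#'   class is AD.
#' @param gold Logical vector of gold labels, same length.
#'
#' @return An object of class `confusion_counts`: a list with `TP`, `TN`,
#'   `FP`, `FN`.
#' @export
confusion_counts <- function(predicted, gold) {
  if (length(predicted) != length(gold)) {
    abort("predicted and gold labels must have equal length")
  }
  predicted <- as.logical(predicted)
  gold <- as.logical(gold)
  if (anyNA(predicted) || anyNA(gold)) abort("labels must be non-missing")
  structure(
    list(
      TP = sum(predicted & gold),
      TN = sum(!predicted & !gold),
      FP = sum(predicted & !gold),
      FN = sum(!predicted & gold)
    ),
    class = "confusion_counts"
  )
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat("<confusion_counts> TP", x$TP, "TN", x$TN, "FP", x$FP, "FN", x$FN, "\n")
  invisible(x)
}

#' Six evaluation metrics from confusion counts
#'
#' Accuracy `(TP+TN)/total`, precision `TP/(TP+FP)`, recall `TP/(TP+FN)`,
#' F1 `2*precision*recall/(precision+recall)`, negative predictive value
#' `TN/(TN+FN)` and specificity `TN/(TN+FP)`. A metric whose denominator is
#' zero is reported as `NA` (undefined), never as 0.
#'
#' @param counts A [confusion_counts()] object, or a list with `TP`, `TN`,
#'   `FP`, `FN`.
#'
#' @return A one-row tibble with columns `accuracy`, `precision`, `recall`,
#'   `f1`, `npv`, `specificity`.
#' @export
compute_metrics <- function(counts) {
  TP <- counts$TP; TN <- counts$TN; FP <- counts$FP; FN <- counts$FN
  if (any(c(TP, TN, FP, FN) < 0)) abort("confusion counts must be non-negative")
  total <- TP + TN + FP + FN
  if (total == 0) abort("cannot compute metrics on zero evaluated patients")
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  precision <- ratio(TP, TP + FP)
  recall <- ratio(TP, TP + FN)
  f1 <- if (is.na(precision) || is.na(recall) || precision + recall == 0) {
    NA_real_
  } else {
    2 * precision * recall / (precision + recall)
  }
  tibble(
    accuracy = (TP + TN) / total,
    precision = precision,
    recall = recall,
    f1 = f1,
    npv = ratio(TN, TN + FN),
    specificity = ratio(TN, TN + FP)
  )
}

#' @exportS3Method generics::tidy
tidy.confusion_counts <- function(x, ...) {
  tidyr::pivot_longer(compute_metrics(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}
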