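#' Rectified linear unit
#'
#' Elementwise `max(0, x)`; shape is preserved for vectors and matrices.
#'
#' @param x A numeric vector, matrix or array with finite entries.
#' @return `x` with negative entries clamped to zero.
#' @export
relu <- function(x) pmax(x, 0)

#' Softmax
#'
#' Maps a length-K real vector to a probability vector:
#' `softmax(z)_i = exp(z_i) / sum_j exp(z_j)`. Computed with the max
#' subtracted for numerical stability, which also makes the result invariant
#' to adding a constant to every entry.
#'
#' @param z A finite numeric vector.
#' @return A probability vector of the same length (positive entries summing
#'   to 1).
#' @export
softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

row_softmax <- function(z) {
  e <- exp(z - apply(z, 1, max))
  e / rowSums(e)
}

# Sentence identity key within a corpus.
sentence_key <- function(tbl) {
  paste(tbl$patient_id, tbl$doc_id, tbl$sent_index, sep = "\r")
}

#' Assemble a class-balanced sentence dataset for one indicator category
#'
#' Positives are sentences affirmed for the target category; negatives are
#' sentences affirmed in at least one *other* category and not matched (in any
#' assertion context) to the target category. The majority class is
#' undersampled (seeded) to equalize counts, and the examples are split into
#' train/test by a fixed fraction, grouped by patient so no patient
#' contributes to both sides. Each split is balanced.
#'
#' @param annotations Annotation tibble from [annotate_corpus()].
#' @param category Target category id (1..8).
#' @param backend An [embedding_backend()] used to embed the selected
#'   sentences.
#' @param seed Integer seed controlling undersampling and the patient split.
#' @param n_per_class Optional cap on examples per class (train + test
#'   combined).
#' @param train_fraction Fraction of examples assigned to the training split
#'   (by patient groups).
#' @param include_unmatched Also admit sentences matched to no category as
#'   negatives (off by default).
#'
#' @return An object of class `ad_sentence_dataset` with elements `category`,
#'   `train` and `test` (each a list with embedding matrix `x`, 0/1 label
#'   vector `y` and a `sentences` tibble), and `seed`.
#' @export
assemble_indicator_dataset <- function(annotations, category,
                                       backend = embedding_backend(),
                                       seed = 1, n_per_class = NULL,
                                       train_fraction = 0.8,
                                       include_unmatched = FALSE) {
  stopifnot(category %in% 1:8)
  ann <- annotations
  ann$key <- sentence_key(ann)
  per_sent <- ann %>%
    group_by(.data$key) %>%
    summarise(
      patient_id = .data$patient_id[1],
      text = .data$text[1],
      matched_target = any(!is.na(.data$category) & .data$category == !!category),
      affirmed_target = any(!is.na(.data$category) & .data$category == !!category &
                              .data$status == "affirmed"),
      affirmed_other = any(!is.na(.data$category) & .data$category != !!category &
                             .data$status == "affirmed"),
      any_match = any(!is.na(.data$category)),
      .groups = "drop"
    )
  pos <- per_sent %>% filter(.data$affirmed_target)
  neg <- per_sent %>%
    filter(!.data$matched_target &
             (.data$affirmed_other | (include_unmatched & !.data$any_match)))
  if (nrow(pos) == 0) {
    abort(paste0("no affirmed sentences found for category ", category))
  }
  if (nrow(neg) == 0) {
    abort(paste0("no eligible negative sentences for category ", category))
  }

  with_seed(seed, {
    # patient-grouped split, then balance within each side
    patients <- unique(c(pos$patient_id, neg$patient_id))
    patients <- sample(patients)
    counts <- table(c(pos$patient_id, neg$patient_id))[patients]
    cum <- cumsum(as.numeric(counts))
    n_train_pat <- max(1L, sum(cum <= train_fraction * sum(counts)))
    train_pat <- patients[seq_len(n_train_pat)]

    take <- function(tbl, in_train, cap) {
      sub <- tbl[(tbl$patient_id %in% train_pat) == in_train, , drop = FALSE]
      if (!is.null(cap) && nrow(sub) > cap) {
        sub <- sub[sample(nrow(sub), cap), , drop = FALSE]
      }
      sub
    }
    cap_train <- if (is.null(n_per_class)) NULL else floor(train_fraction * n_per_class)
    cap_test <- if (is.null(n_per_class)) NULL else n_per_class - cap_train

    build_split <- function(in_train, cap) {
      p <- take(pos, in_train, cap)
      q <- take(neg, in_train, cap)
      m <- min(nrow(p), nrow(q))
      if (nrow(p) > m) p <- p[sample(nrow(p), m), , drop = FALSE]
      if (nrow(q) > m) q <- q[sample(nrow(q), m), , drop = FALSE]
      sentences <- bind_rows(
        mutate(p, label = 1L),
        mutate(q, label = 0L)
      ) %>% select("key", "patient_id", "text", "label")
      list(
        x = embed_sentences(sentences$text, backend),
        y = sentences$label,
        sentences = sentences
      )
    }
    train <- build_split(TRUE, cap_train)
    test <- build_split(FALSE, cap_test)
    if (length(train$y) == 0) {
      abort(paste0("empty training split for category ", category))
    }
    structure(
      list(category = as.integer(category), train = train, test = test,
           seed = as.integer(seed), dimension = backend$dimension),
      class = "ad_sentence_dataset"
    )
  })
}

#' @export
print.ad_sentence_dataset <- function(x, ...) {
  cat("<ad_sentence_dataset> category", x$category, "- train",
      length(x$train$y), "( pos", sum(x$train$y), ") test", length(x$test$y),
      "( pos", sum(x$test$y), ")\n")
  invisible(x)
}

init_uniform <- function(nr, nc) {
  bound <- 1 / sqrt(nr)
  matrix(runif(nr * nc, -bound, bound), nrow = nr, ncol = nc)
}

#' Train an indicator MLP sentence classifier
#'
#' A two-layer perceptron — fully connected 768 x 100, ReLU, fully connected
#' 100 x 2 — trained with minibatch stochastic gradient descent (momentum) on
#' the cross-entropy loss for a fixed number of epochs. Training is
#' deterministic given the seed: initialization and shuffling draw from a
#' local RNG.
#'
#' @param ds An [ad_sentence_dataset][assemble_indicator_dataset()], or a list
#'   with `train$x` and `train$y`.
#' @param seed Integer training seed.
#' @param epochs Number of passes over the training data (default 10).
#' @param lr Learning rate (default 0.001).
#' @param momentum Momentum coefficient (default 0.9).
#' @param batch_size Minibatch size (default 16).
#' @param hidden Hidden width (default 100).
#'
#' @return An object of class `indicator_mlp` holding the weight matrices
#'   `W1` (dim x hidden), `b1`, `W2` (hidden x 2), `b2`, plus `category` and
#'   training metadata.
#' @export
train_indicator_mlp <- function(ds, seed = 1, epochs = 10, lr = 0.001,
                                momentum = 0.9, batch_size = 16, hidden = 100) {
  x <- ds$train$x
  y <- ds$train$y
  if (is.null(x) || length(y) == 0) abort("training split is empty")
  n <- nrow(x)
  d <- ncol(x)
  with_seed(seed, {
    W1 <- init_uniform(d, hidden)
    b1 <- runif(hidden, -1 / sqrt(d), 1 / sqrt(d))
    W2 <- init_uniform(hidden, 2)
    b2 <- runif(2, -1 / sqrt(hidden), 1 / sqrt(hidden))
    vW1 <- matrix(0, d, hidden); vb1 <- numeric(hidden)
    vW2 <- matrix(0, hidden, 2); vb2 <- numeric(2)
    Y <- cbind(1 - y, y) # column 1 = negative class, column 2 = positive

    for (ep in seq_len(epochs)) {
      perm <- sample(n)
      for (start in seq(1, n, by = batch_size)) {
        ix <- perm[start:min(start + batch_size - 1, n)]
        Xb <- x[ix, , drop = FALSE]
        Yb <- Y[ix, , drop = FALSE]
        m <- length(ix)
        Z1 <- sweep(Xb %*% W1, 2, b1, `+`)
        H <- relu(Z1)
        logits <- sweep(H %*% W2, 2, b2, `+`)
        P <- row_softmax(logits)
        if (!all(is.finite(P))) {
          abort(paste0("non-finite loss during training (epoch ", ep, ")"))
        }
        dlogits <- (P - Yb) / m
        gW2 <- crossprod(H, dlogits)
        gb2 <- colSums(dlogits)
        dH <- dlogits %*% t(W2)
        dH[Z1 <= 0] <- 0
        gW1 <- crossprod(Xb, dH)
        gb1 <- colSums(dH)
        vW2 <- momentum * vW2 + gW2; W2 <- W2 - lr * vW2
        vb2 <- momentum * vb2 + gb2; b2 <- b2 - lr * vb2
        vW1 <- momentum * vW1 + gW1; W1 <- W1 - lr * vW1
        vb1 <- momentum * vb1 + gb1; b1 <- b1 - lr * vb1
      }
    }
    structure(
      list(W1 = W1, b1 = b1, W2 = W2, b2 = b2,
           category = ds$category %||% NA_integer_,
           seed = as.integer(seed), dimension = d, hidden = hidden,
           epochs = epochs, lr = lr, momentum = momentum,
           batch_size = batch_size),
      class = "indicator_mlp"
    )
  })
}

#' @export
print.indicator_mlp <- function(x, ...) {
  cat("<indicator_mlp> category", x$category, "-", x$dimension, "->",
      x$hidden, "-> 2 (seed", x$seed, ")\n")
  invisible(x)
}

mlp_forward <- function(m, x) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  if (ncol(x) != m$dimension) {
    abort(paste0("embedding dimension ", ncol(x),
                 " does not match classifier input ", m$dimension))
  }
  H <- relu(sweep(x %*% m$W1, 2, m$b1, `+`))
  logits <- sweep(H %*% m$W2, 2, m$b2, `+`)
  row_softmax(logits)
}

#' Probability that a sentence affirms the classifier's category
#'
#' The softmax of the output logits, positive-class entry.
#'
#' @param m An [indicator_mlp][train_indicator_mlp()].
#' @param embedding A numeric vector of length `m$dimension`, or a matrix with
#'   that many columns (one row per sentence).
#'
#' @return A numeric vector of probabilities in `[0, 1]`.
#' @export
affirm_probability <- function(m, embedding) {
  mlp_forward(m, embedding)[, 2]
}

#' Accuracy of a sentence classifier on its held-out split
#'
#' @param m An [indicator_mlp][train_indicator_mlp()].
#' @param ds The [ad_sentence_dataset][assemble_indicator_dataset()] whose
#'   `test` split is evaluated.
#'
#' @return The fraction of test sentences whose argmax class matches the
#'   label.
#' @export
evaluate_sentence_classifier <- function(m, ds) {
  if (length(ds$test$y) == 0) abort("test split is empty")
  p <- mlp_forward(m, ds$test$x)
  pred <- as.integer(p[, 2] > p[, 1])
  mean(pred == ds$test$y)
}
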