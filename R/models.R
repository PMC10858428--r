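# Downstream phenotype classifier roster. Each family exposes fit(x, y,
# params, seed) and a prediction rule; x is the numeric patient-vector matrix
# (columns v1..v8), y a logical AD label.

#' Model families available for phenotype classification
#'
#' @return Character vector of family names: logistic regression, support
#'   vector machine, decision tree, random forest, k-nearest neighbours,
#'   extreme gradient boosting, adaptive boosting.
#' @export
ad_model_families <- function() {
  c("logistic_regression", "svm", "decision_tree", "random_forest",
    "knn", "xgboost", "adaboost")
}

#' Default hyperparameter grids
#'
#' A named list of grids, one per family; each grid is a list of parameter
#' lists tried in order (ties in CV accuracy are broken by grid order).
#'
#' @return Named list of grids.
#' @export
default_grids <- function() {
  list(
    logistic_regression = list(list()),
    svm = list(list(cost = 0.1), list(cost = 1), list(cost = 10)),
    decision_tree = list(list(cp = 0.05), list(cp = 0.01), list(cp = 0.001)),
    random_forest = list(list(mtry = 2, ntree = 300), list(mtry = 3, ntree = 300)),
    knn = list(list(k = 1), list(k = 3), list(k = 5)),
    xgboost = list(
      list(max_depth = 2, nrounds = 50, eta = 0.3),
      list(max_depth = 3, nrounds = 50, eta = 0.3)
    ),
    adaboost = list(list(n_rounds = 25, maxdepth = 1),
                    list(n_rounds = 50, maxdepth = 1))
  )
}

as_vector_matrix <- function(vectors) {
  m <- as.matrix(as_tibble(vectors)[paste0("v", 1:8)])
  storage.mode(m) <- "double"
  m
}

# ---- AdaBoost.M1 over decision stumps (no installed implementation) --------

adaboost_fit <- function(x, y, n_rounds = 50, maxdepth = 1) {
  n <- nrow(x)
  w <- rep(1 / n, n)
  yy <- ifelse(y, 1, -1)
  df <- as.data.frame(x)
  stumps <- list()
  alphas <- numeric(0)
  for (r in seq_len(n_rounds)) {
    fit <- rpart::rpart(
      yf ~ ., data = cbind(df, yf = factor(yy, levels = c(-1, 1))),
      weights = w, method = "class",
      control = rpart::rpart.control(maxdepth = maxdepth, cp = 0,
                                     minsplit = 2, xval = 0)
    )
    pred <- ifelse(predict(fit, df, type = "class") == "1", 1, -1)
    err <- sum(w[pred != yy])
    if (err >= 0.5) break
    err <- max(err, 1e-10)
    alpha <- 0.5 * log((1 - err) / err)
    stumps[[length(stumps) + 1]] <- fit
    alphas <- c(alphas, alpha)
    w <- w * exp(-alpha * yy * pred)
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  if (length(stumps) == 0) {
    # degenerate: fall back to the majority class
    maj <- mean(y) >= 0.5
    return(list(stumps = list(), alphas = numeric(0), majority = maj))
  }
  list(stumps = stumps, alphas = alphas, majority = NULL)
}

adaboost_predict <- function(model, x) {
  if (length(model$stumps) == 0) {
    return(rep(model$majority, nrow(x)))
  }
  df <- as.data.frame(x)
  score <- numeric(nrow(x))
  for (i in seq_along(model$stumps)) {
    pred <- ifelse(predict(model$stumps[[i]], df, type = "class") == "1", 1, -1)
    score <- score + model$alphas[i] * pred
  }
  score > 0
}

# ---- family registry -------------------------------------------------------

family_fit <- function(family, x, y, params, seed) {
  df <- as.data.frame(x)
  with_seed(seed, switch(family,
    logistic_regression = suppressWarnings(
      glm(yf ~ ., data = cbind(df, yf = as.integer(y)), family = binomial())
    ),
    svm = e1071::svm(x, factor(y, levels = c(FALSE, TRUE)),
                     cost = params$cost %||% 1, kernel = "radial",
                     scale = FALSE),
    decision_tree = rpart::rpart(
      yf ~ ., data = cbind(df, yf = factor(y, levels = c(FALSE, TRUE))),
      method = "class",
      control = rpart::rpart.control(cp = params$cp %||% 0.01, xval = 0)
    ),
    random_forest = randomForest::randomForest(
      x, factor(y, levels = c(FALSE, TRUE)),
      ntree = params$ntree %||% 300,
      mtry = min(params$mtry %||% 2, ncol(x))
    ),
    knn = list(train_x = x, train_y = y, k = params$k %||% 3),
    xgboost = xgboost::xgb.train(
      params = list(objective = "binary:logistic",
                    max_depth = params$max_depth %||% 2,
                    eta = params$eta %||% 0.3, nthread = 1),
      data = xgboost::xgb.DMatrix(x, label = as.numeric(y)),
      nrounds = params$nrounds %||% 50
    ),
    adaboost = adaboost_fit(x, y, n_rounds = params$n_rounds %||% 50,
                            maxdepth = params$maxdepth %||% 1),
    abort(paste0("unknown model family: ", family))
  ))
}

family_predict <- function(family, fit, x, seed = 1L) {
  df <- as.data.frame(x)
  with_seed(seed, switch(family,
    logistic_regression = suppressWarnings(
      predict(fit, df, type = "response")
    ) > 0.5,
    svm = predict(fit, x) == "TRUE",
    decision_tree = predict(fit, df, type = "class") == "TRUE",
    random_forest = predict(fit, x) == "TRUE",
    knn = as.character(class::knn(
      fit$train_x, x, factor(fit$train_y, levels = c(FALSE, TRUE)),
      k = min(fit$k, nrow(fit$train_x))
    )) == "TRUE",
    xgboost = predict(fit, xgboost::xgb.DMatrix(x)) > 0.5,
    adaboost = adaboost_predict(fit, x),
    abort(paste0("unknown model family: ", family))
  ))
}

cv_folds <- function(n, k = 5) sample(rep_len(seq_len(k), n))

#' Tune and train one phenotype classifier family
#'
#' Hyperparameters are chosen by mean 5-fold cross-validated accuracy on the
#' (balanced) training set, ties broken by grid order, and the winning
#' configuration is refit on the full training set.
#'
#' @param vectors Patient-vector tibble (columns `patient_id`, `v1`..`v8`).
#' @param labels Tibble with `patient_id`, `gold_label`.
#' @param family One of [ad_model_families()].
#' @param grid List of parameter lists; default from [default_grids()].
#' @param seed Integer seed controlling fold assignment and any stochastic
#'   fitting.
#' @param folds Number of CV folds (default 5).
#'
#' @return An object of class `ad_model`: the fitted model with its family,
#'   chosen parameters and CV accuracy table.
#' @export
tune_and_train <- function(vectors, labels, family, grid = NULL, seed = 1,
                           folds = 5) {
  family <- match.arg(family, ad_model_families())
  grid <- grid %||% default_grids()[[family]]
  if (length(grid) == 0) abort("hyperparameter grid must be non-empty")
  x <- as_vector_matrix(vectors)
  y <- labels$gold_label[match(vectors$patient_id, labels$patient_id)]
  if (anyNA(y)) abort("every patient vector needs a gold label")
  if (length(unique(y)) < 2) abort("training data contains a single class")

  fold_id <- with_seed(derive_seed(seed, 101L), cv_folds(nrow(x), folds))
  cv_acc <- vapply(seq_along(grid), function(g) {
    accs <- vapply(seq_len(folds), function(f) {
      tr <- fold_id != f
      if (length(unique(y[tr])) < 2) return(NA_real_)
      fit <- family_fit(family, x[tr, , drop = FALSE], y[tr], grid[[g]],
                        seed = derive_seed(seed, 1000L + 10L * g + f))
      pred <- family_predict(family, fit, x[!tr, , drop = FALSE],
                             seed = derive_seed(seed, 2000L + 10L * g + f))
      mean(pred == y[!tr])
    }, numeric(1))
    mean(accs, na.rm = TRUE)
  }, numeric(1))
  best <- which.max(cv_acc)
  fit <- family_fit(family, x, y, grid[[best]],
                    seed = derive_seed(seed, 3000L + best))
  structure(
    list(family = family, params = grid[[best]], fit = fit,
         cv_accuracy = tibble(config = seq_along(grid), accuracy = cv_acc),
         seed = as.integer(seed)),
    class = "ad_model"
  )
}

#' @export
print.ad_model <- function(x, ...) {
  cat("<ad_model>", x$family, "- params:",
      if (length(x$params) == 0) "(none)" else
        paste(names(x$params), unlist(x$params), sep = "=", collapse = ", "),
      "\n")
  invisible(x)
}

#' Predict AD labels from patient vectors
#'
#' @param object An [ad_model][tune_and_train()].
#' @param vectors Patient-vector tibble or numeric matrix.
#' @param ... Unused.
#' @return A logical vector of predicted labels.
#' @export
predict.ad_model <- function(object, vectors, ...) {
  x <- if (is.matrix(vectors)) vectors else as_vector_matrix(vectors)
  as.logical(family_predict(object$family, object$fit, x,
                            seed = derive_seed(object$seed, 9000L)))
}

#' Stacking ensemble prediction
#'
#' Trains a logistic-regression meta-learner on out-of-fold predictions of
#' the base families over the training set (the scikit-learn stacking
#' scheme), refits each base family on the full training set, and predicts
#' the evaluation vectors.
#'
#' @param base_models List (length >= 2) of fitted [ad_model][tune_and_train()]
#'   objects; their families and chosen parameters define the base learners.
#' @param vectors Training patient-vector tibble.
#' @param labels Tibble with `patient_id`, `gold_label`.
#' @param eval_vectors Patient-vector tibble to predict.
#' @param seed Integer seed.
#' @param folds Number of folds for the out-of-fold predictions (default 5).
#'
#' @return A logical vector of predicted labels for `eval_vectors`.
#' @export
stacking_predict <- function(base_models, vectors, labels, eval_vectors,
                             seed = 1, folds = 5) {
  if (length(base_models) < 2) abort("stacking needs at least 2 base models")
  x <- as_vector_matrix(vectors)
  y <- labels$gold_label[match(vectors$patient_id, labels$patient_id)]
  xe <- as_vector_matrix(eval_vectors)
  fold_id <- with_seed(derive_seed(seed, 77L), cv_folds(nrow(x), folds))

  oof <- matrix(NA_real_, nrow(x), length(base_models))
  for (b in seq_along(base_models)) {
    bm <- base_models[[b]]
    for (f in seq_len(folds)) {
      tr <- fold_id != f
      fit <- family_fit(bm$family, x[tr, , drop = FALSE], y[tr], bm$params,
                        seed = derive_seed(seed, 100L * b + f))
      oof[!tr, b] <- as.numeric(family_predict(
        bm$family, fit, x[!tr, , drop = FALSE],
        seed = derive_seed(seed, 5000L + 100L * b + f)
      ))
    }
  }
  meta_df <- as.data.frame(oof)
  names(meta_df) <- paste0("m", seq_along(base_models))
  meta <- suppressWarnings(
    glm(yf ~ ., data = cbind(meta_df, yf = as.integer(y)), family = binomial())
  )
  base_eval <- vapply(seq_along(base_models), function(b) {
    bm <- base_models[[b]]
    as.numeric(family_predict(bm$family, bm$fit, xe,
                              seed = derive_seed(seed, 7000L + b)))
  }, numeric(nrow(xe)))
  if (is.null(dim(base_eval))) base_eval <- matrix(base_eval, nrow = nrow(xe))
  eval_df <- as.data.frame(base_eval)
  names(eval_df) <- names(meta_df)
  suppressWarnings(predict(meta, eval_df, type = "response")) > 0.5
}
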