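# Uniform interface over the six supervised learner families used across
# the pipeline (automated filtering, wrapper feature selection, SHAP
# grouping, cluster interpretation). Implementations: ranger (random
# forest), xgboost (gradient-boosted trees), e1071 (SVM, naive Bayes),
# class/own-vote kNN, glm / nnet::multinom (logistic regression). All fits
# are deterministic given the spec seed.

learner_families <- c("random_forest", "gradient_boosted_trees", "svm",
                      "knn", "naive_bayes", "logistic_regression")

#' Specify a supervised learner
#'
#' Naive Bayes and logistic regression are available for classification
#' only. Default hyperparameters: 500 trees for random forests; 60
#' boosting rounds, `eta = 0.3`, depth 6 for gradient boosting; radial
#' kernel with probability calibration for SVM; `k = 5` for kNN.
#'
#' @param family One of `"random_forest"`, `"gradient_boosted_trees"`,
#'   `"svm"`, `"knn"`, `"naive_bayes"`, `"logistic_regression"`.
#' @param task `"classification"` or `"regression"`.
#' @param hyperparameters Named list overriding family defaults.
#' @param seed Integer seed controlling all stochastic parts of the fit.
#' @return A `learner_spec`.
#' @export
learner_spec <- function(family, task = c("classification", "regression"),
                         hyperparameters = list(), seed = 1L) {
  family <- match.arg(family, learner_families)
  task <- match.arg(task)
  if (task == "regression" &&
      family %in% c("naive_bayes", "logistic_regression"))
    stop(family, " is implemented only for binary and multiclass ",
         "classification")
  structure(list(family = family, task = task,
                 hyperparameters = hyperparameters,
                 seed = as.integer(seed)),
            class = "learner_spec")
}

lp <- function(spec, name, default) spec$hyperparameters[[name]] %||% default

as_class_factor <- function(y) {
  u <- sort(unique(y))
  factor(y, levels = u)
}

#' Fit a learner
#'
#' @param spec A [learner_spec()].
#' @param x Numeric feature matrix (or `chemgroup_features`).
#' @param y Labels: class codes for classification, numeric response for
#'   regression.
#' @return A `chemgroup_learner` exposing [predict_prob()],
#'   [predict_value()] and [learner_importance()].
#' @export
fit_learner <- function(spec, x, y) {
  stopifnot(inherits(spec, "learner_spec"))
  x <- fm_values(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("V", seq_len(ncol(x)))
  classification <- spec$task == "classification"
  yf <- if (classification) as_class_factor(y) else as.numeric(y)
  set.seed(spec$seed)
  model <- switch(spec$family,
    random_forest = ranger::ranger(
      x = x, y = yf, num.trees = lp(spec, "num_trees", 500L),
      probability = classification, importance = "impurity",
      num.threads = 1L, seed = spec$seed),
    gradient_boosted_trees = fit_xgb(spec, x, y, yf),
    svm = e1071::svm(x = x, y = yf, kernel = lp(spec, "kernel", "radial"),
                     cost = lp(spec, "cost", 1),
                     probability = classification),
    knn = list(train = x, y = yf, k = lp(spec, "k", 5L)),
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = yf),
    logistic_regression = fit_logistic(spec, x, yf))
  structure(list(spec = spec, model = model, columns = colnames(x),
                 classes = if (classification) levels(yf) else NULL),
            class = "chemgroup_learner")
}

fit_xgb <- function(spec, x, y, yf) {
  classification <- spec$task == "classification"
  n_class <- if (classification) nlevels(yf) else 0L
  params <- list(
    max_depth = lp(spec, "max_depth", 6L),
    eta = lp(spec, "eta", 0.3),
    nthread = 1L, seed = spec$seed,
    objective = if (!classification) "reg:squarederror"
                else if (n_class > 2L) "multi:softprob"
                else "binary:logistic")
  if (classification && n_class > 2L) params$num_class <- n_class
  label <- if (classification) as.integer(yf) - 1L else as.numeric(y)
  dtrain <- xgboost::xgb.DMatrix(x, label = label)
  xgboost::xgb.train(params = params, data = dtrain,
                     nrounds = lp(spec, "nrounds", 60L), verbose = 0)
}

fit_logistic <- function(spec, x, yf) {
  if (nlevels(yf) > 2L) {
    df <- data.frame(.y = yf, x, check.names = FALSE)
    nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = 300,
                   MaxNWts = 100000)
  } else {
    df <- data.frame(.y = yf, x, check.names = FALSE)
    suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
  }
}

check_columns <- function(fitted, x) {
  if (!identical(colnames(x), fitted$columns))
    stop("feature columns do not match the training columns")
  x
}

knn_votes <- function(model, x) {
  d2 <- outer(rowSums(x^2), rowSums(model$train^2), "+") -
    2 * tcrossprod(x, model$train)
  k <- min(model$k, nrow(model$train))
  t(apply(d2, 1L, function(row) {
    nn <- order(row)[seq_len(k)]
    if (is.factor(model$y)) {
      tab <- table(model$y[nn]) / k
      as.numeric(tab)
    } else {
      mean(model$y[nn])
    }
  }))
}

#' Class-probability predictions
#'
#' @param fitted A fitted `chemgroup_learner` (classification task).
#' @param x Feature matrix with the training columns in order.
#' @return `n x C` matrix of probabilities, columns named by class.
#' @export
predict_prob <- function(fitted, x) {
  stopifnot(inherits(fitted, "chemgroup_learner"),
            fitted$spec$task == "classification")
  x <- check_columns(fitted, fm_values(x))
  spec <- fitted$spec
  classes <- fitted$classes
  p <- switch(spec$family,
    random_forest = predict(fitted$model, data = x,
                            num.threads = 1L)$predictions,
    gradient_boosted_trees = {
      raw <- predict(fitted$model, xgboost::xgb.DMatrix(x))
      if (length(classes) > 2L) {
        matrix(raw, ncol = length(classes), byrow = TRUE)
      } else {
        cbind(1 - raw, raw)
      }
    },
    svm = {
      pr <- attr(predict(fitted$model, x, probability = TRUE),
                 "probabilities")
      pr[, classes, drop = FALSE]
    },
    knn = {
      v <- knn_votes(fitted$model, x)
      if (length(classes) == 1L) v <- cbind(v)
      v
    },
    naive_bayes = predict(fitted$model, as.data.frame(x), type = "raw"),
    logistic_regression = {
      df <- as.data.frame(x)
      if (length(classes) > 2L) {
        pr <- predict(fitted$model, newdata = df, type = "probs")
        if (is.null(dim(pr))) pr <- matrix(pr, nrow = 1L)
        pr
      } else {
        p1 <- predict(fitted$model, newdata = df, type = "response")
        cbind(1 - p1, p1)
      }
    })
  p <- as.matrix(p)
  colnames(p) <- classes
  rownames(p) <- NULL
  p
}

#' Point predictions
#'
#' Class codes (classification) or numeric values (regression).
#'
#' @inheritParams predict_prob
#' @return Vector of predictions.
#' @export
predict_value <- function(fitted, x) {
  stopifnot(inherits(fitted, "chemgroup_learner"))
  if (fitted$spec$task == "classification") {
    p <- predict_prob(fitted, x)
    cls <- fitted$classes[max.col(p, ties.method = "first")]
    # preserve the original label type (integer codes or strings)
    out <- utils::type.convert(cls, as.is = TRUE)
    return(out)
  }
  x <- check_columns(fitted, fm_values(x))
  switch(fitted$spec$family,
    random_forest = predict(fitted$model, data = x,
                            num.threads = 1L)$predictions,
    gradient_boosted_trees = predict(fitted$model, xgboost::xgb.DMatrix(x)),
    svm = as.numeric(predict(fitted$model, x)),
    knn = as.numeric(knn_votes(fitted$model, x)))
}

#' Feature-importance ranking
#'
#' Model-native importances for tree ensembles (impurity for random
#' forest, gain for gradient boosting), absolute coefficients for logistic
#' regression, and permutation importance (degradation of accuracy or R2
#' on the supplied data when a column is permuted) for SVM/kNN/naive
#' Bayes, which expose no native ranking.
#'
#' @param fitted A fitted `chemgroup_learner`.
#' @param x,y Data used for permutation importance (required for
#'   SVM/kNN/naive Bayes).
#' @param seed Seed for the permutations.
#' @return Named numeric vector, one entry per training column (higher is
#'   more important).
#' @export
learner_importance <- function(fitted, x = NULL, y = NULL, seed = 1L) {
  stopifnot(inherits(fitted, "chemgroup_learner"))
  spec <- fitted$spec
  cols <- fitted$columns
  imp <- switch(spec$family,
    random_forest = ranger::importance(fitted$model)[cols],
    gradient_boosted_trees = {
      tab <- xgboost::xgb.importance(model = fitted$model)
      v <- stats::setNames(rep(0, length(cols)), cols)
      v[tab$Feature] <- tab$Gain
      v
    },
    logistic_regression = {
      cf <- if (length(fitted$classes) > 2L) {
        co <- summary(fitted$model)$coefficients
        colSums(abs(co))[cols]
      } else {
        abs(stats::coef(fitted$model))[-1L]
      }
      cf[is.na(cf)] <- 0
      stats::setNames(as.numeric(cf), cols)
    },
    permutation_importance(fitted, x, y, seed))
  imp[is.na(imp)] <- 0
  imp
}

permutation_importance <- function(fitted, x, y, seed = 1L) {
  if (is.null(x) || is.null(y))
    stop("permutation importance requires x and y")
  x <- fm_values(x)
  classification <- fitted$spec$task == "classification"
  score <- function(mat) {
    pred <- predict_value(fitted, mat)
    if (classification) mean(pred == y) else r2_score(y, pred)
  }
  base <- score(x)
  set.seed(seed)
  drop <- vapply(seq_len(ncol(x)), function(j) {
    xp <- x
    xp[, j] <- sample(xp[, j])
    base - score(xp)
  }, 0)
  stats::setNames(drop, colnames(x))
}

# ------------------------------------------------------------- metrics

r2_score <- function(y, pred) {
  1 - sum((y - pred)^2) / sum((y - mean(y))^2)
}

auc_score <- function(y, prob, classes) {
  if (length(classes) == 2L) {
    as.numeric(pROC::auc(pROC::roc(
      response = factor(y, levels = classes),
      predictor = prob[, 2L], levels = classes, direction = "<",
      quiet = TRUE)))
  } else {
    # one-vs-rest macro average
    per <- vapply(seq_along(classes), function(i) {
      resp <- factor(y == classes[i], levels = c(FALSE, TRUE))
      if (nlevels(droplevels(resp)) < 2L) return(NA_real_)
      as.numeric(pROC::auc(pROC::roc(
        response = resp, predictor = prob[, i],
        levels = c(FALSE, TRUE), direction = "<", quiet = TRUE)))
    }, 0)
    mean(per, na.rm = TRUE)
  }
}

stratified_folds <- function(y, k, seed, stratify = TRUE) {
  set.seed(seed)
  n <- length(y)
  fold <- integer(n)
  if (stratify) {
    for (cls in unique(y)) {
      idx <- sample(which(y == cls))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  } else {
    fold[sample(n)] <- rep_len(seq_len(k), n)
  }
  fold
}

#' Cross-validated score of a learner
#'
#' Mean held-out metric over `k_folds` stratified (classification) or
#' plain (regression) folds; fold assignment is reproducible from `seed`.
#'
#' @param spec A [learner_spec()].
#' @param x Feature matrix.
#' @param y Labels.
#' @param metric `"accuracy"`, `"auc"` (classification) or `"r2"`
#'   (regression).
#' @param k_folds Number of folds (>= 2).
#' @param seed Fold-assignment seed.
#' @return Mean score across folds.
#' @export
cv_score <- function(spec, x, y, metric = c("accuracy", "auc", "r2"),
                     k_folds = 5L, seed = 1L) {
  metric <- match.arg(metric)
  stopifnot(k_folds >= 2L)
  classification <- spec$task == "classification"
  if (classification && metric == "r2")
    stop("metric r2 requires task = regression")
  if (!classification && metric %in% c("accuracy", "auc"))
    stop("metric ", metric, " requires task = classification")
  x <- fm_values(x)
  if (classification && min(table(y)) < k_folds)
    stop("a class has fewer members than folds; cannot stratify")
  fold <- stratified_folds(y, k_folds, seed, stratify = classification)
  classes <- if (classification) levels(as_class_factor(y)) else NULL
  scores <- vapply(seq_len(k_folds), function(f) {
    tr <- fold != f
    fit <- fit_learner(spec, x[tr, , drop = FALSE], y[tr])
    xt <- x[!tr, , drop = FALSE]
    yt <- y[!tr]
    switch(metric,
      accuracy = mean(predict_value(fit, xt) == yt),
      auc = auc_score(yt, predict_prob(fit, xt), classes),
      r2 = r2_score(yt, predict_value(fit, xt)))
  }, 0)
  mean(scores)
}

#' Holdout score (80/20 split)
#'
#' Single stratified train/test split used by the automated filter search.
#'
#' @inheritParams cv_score
#' @param train_fraction Fraction of rows used for training.
#' @return Held-out score.
#' @export
holdout_score <- function(spec, x, y, metric = c("accuracy", "auc", "r2"),
                          train_fraction = 0.8, seed = 1L) {
  metric <- match.arg(metric)
  x <- fm_values(x)
  classification <- spec$task == "classification"
  set.seed(seed)
  if (classification) {
    tr_idx <- unlist(lapply(unique(y), function(cls) {
      idx <- which(y == cls)
      sample(idx, max(1L, round(train_fraction * length(idx))))
    }))
  } else {
    tr_idx <- sample(length(y), max(1L, round(train_fraction * length(y))))
  }
  tr <- seq_along(y) %in% tr_idx
  fit <- fit_learner(spec, x[tr, , drop = FALSE], y[tr])
  xt <- x[!tr, , drop = FALSE]
  yt <- y[!tr]
  classes <- if (classification) levels(as_class_factor(y)) else NULL
  switch(metric,
    accuracy = mean(predict_value(fit, xt) == yt),
    auc = auc_score(yt, predict_prob(fit, xt), classes),
    r2 = r2_score(yt, predict_value(fit, xt)))
}

default_metric <- function(spec) {
  if (spec$task == "classification") "accuracy" else "r2"
}
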