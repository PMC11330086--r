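# The uniform learner interface: family/task validity, determinism,
# probability outputs, metrics, cross-validation.

test_that("probabilistic-only families reject regression", {
  expect_error(learner_spec("naive_bayes", "regression"),
               "only for binary and multiclass")
  expect_error(learner_spec("logistic_regression", "regression"),
               "only for binary and multiclass")
})

test_that("fits are deterministic given the seed", {
  fx <- make_labeled_features(120L, 3L, 7L, effect = 1.5, "binary",
                              seed = 8L)
  for (fam in c("random_forest", "gradient_boosted_trees", "svm")) {
    s <- learner_spec(fam, "classification", seed = 7L)
    p1 <- predict_prob(fit_learner(s, fx$x, fx$labels), fx$x)
    p2 <- predict_prob(fit_learner(s, fx$x, fx$labels), fx$x)
    expect_identical(p1, p2)
  }
})

test_that("every family separates a linearly separable 2-class blob", {
  set.seed(5)
  x <- rbind(matrix(rnorm(100, mean = 0), 50, 2),
             matrix(rnorm(100, mean = 8), 50, 2))
  colnames(x) <- c("u", "v")
  y <- rep(0:1, each = 50L)
  for (fam in chemgroup:::learner_families) {
    s <- learner_spec(fam, "classification", seed = 2L)
    fit <- suppressWarnings(fit_learner(s, x, y))
    expect_equal(mean(predict_value(fit, x) == y), 1.0)
    pr <- predict_prob(fit, x)
    expect_equal(dim(pr), c(100L, 2L))
    expect_equal(unname(rowSums(pr)), rep(1, 100L), tolerance = 1e-6)
  }
})

test_that("column mismatch with training is refused", {
  fx <- make_labeled_features(50L, 2L, 2L, effect = 1, "binary", seed = 1L)
  fit <- fit_learner(fast_logit(), fx$x, fx$labels)
  xw <- fx$x[, c(2, 1, 3, 4)]
  expect_error(predict_prob(fit, xw), "training columns")
})

test_that("metric and task compatibility is enforced", {
  fx <- make_labeled_features(60L, 2L, 2L, effect = 1, "binary", seed = 2L)
  expect_error(cv_score(small_gbt(task = "regression"), fx$x,
                        rnorm(60), metric = "auc"),
               "task = classification")
  expect_error(cv_score(fast_logit(), fx$x, fx$labels, metric = "r2"),
               "task = regression")
})

test_that("r2 is exact on perfect predictions and cv recovers strong signal", {
  y <- rnorm(50)
  expect_equal(chemgroup:::r2_score(y, y), 1.0, tolerance = 1e-12)
  fx <- make_labeled_features(250L, 3L, 3L, effect = 3, "continuous",
                              seed = 4L)
  s <- cv_score(small_gbt(task = "regression"), fx$x, fx$labels, "r2",
                k_folds = 3L, seed = 3L)
  expect_gt(s, 0.8)
})

test_that("labels independent of features give chance-level AUC", {
  set.seed(17)
  x <- matrix(rnorm(800 * 5L), 800, 5L,
              dimnames = list(NULL, paste0("v", 1:5)))
  y <- rep(0:1, each = 400L)
  auc <- cv_score(fast_logit(), x, y, "auc", k_folds = 5L, seed = 6L)
  expect_gt(auc, 0.45)
  expect_lt(auc, 0.55)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(3)
  y <- rep(c(0L, 1L), 25L)
  prob <- cbind(0, runif(50)); prob[, 1L] <- 1 - prob[, 2L]
  a1 <- chemgroup:::auc_score(y, prob, c(0L, 1L))
  prob2 <- cbind(1 - prob[, 2L]^3, prob[, 2L]^3)
  expect_equal(chemgroup:::auc_score(y, prob2, c(0L, 1L)), a1)
})

test_that("multiclass probabilities and macro AUC work across families", {
  fx <- make_labeled_features(150L, 3L, 3L, effect = 2, "multiclass",
                              seed = 9L)
  for (fam in c("gradient_boosted_trees", "naive_bayes",
                "logistic_regression")) {
    s <- learner_spec(fam, "classification", seed = 3L)
    a <- cv_score(s, fx$x, fx$labels, "auc", k_folds = 3L, seed = 2L)
    expect_gt(a, 0.55)
  }
})

test_that("stratified folds keep every class in every training fold", {
  y <- c(rep(0L, 30L), rep(1L, 6L))
  fold <- chemgroup:::stratified_folds(y, 3L, seed = 1L)
  for (f in 1:3) expect_setequal(unique(y[fold != f]), c(0L, 1L))
  expect_error(cv_score(fast_logit(),
                        matrix(rnorm(72), 36, 2,
                               dimnames = list(NULL, c("a", "b"))),
                        c(rep(0L, 34L), 1L, 1L), "accuracy", 5L),
               "fewer members than folds")
})
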