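# SHAP attribution: exactness for tree models, sampling approximation,
# SHAP-based grouping, cluster interpretation, summaries.

test_that("tree SHAP satisfies efficiency and the null-player axiom", {
  fx <- make_labeled_features(150L, 3L, 6L, effect = 2, "binary",
                              seed = 21L)
  x <- cbind(fx$x, constant = 1)
  fit <- fit_learner(small_gbt(seed = 3L), x, fx$labels)
  sh <- compute_shap(fit, x)
  margins <- predict(fit$model, xgboost::xgb.DMatrix(x),
                     outputmargin = TRUE)
  expect_lt(max(abs(rowSums(sh$values) + sh$base_values - margins)),
            1e-6)
  expect_equal(max(abs(sh$values[, "constant"])), 0)
  expect_equal(colnames(sh$values), colnames(x))
})

test_that("sampling Shapley reproduces the linear closed form", {
  # single-feature linear f(x) = 2x with the mean as background:
  # phi_i = 2 (x_i - mean(x)) exactly
  set.seed(22)
  x <- matrix(rnorm(40), ncol = 1L)
  f <- function(m) 2 * m[, 1L]
  bg <- matrix(mean(x), 1L, 1L)
  sh <- chemgroup:::sampling_shapley(f, x, bg, n_permutations = 4L,
                                     seed = 1L)
  expect_equal(sh$values[, 1L], 2 * (x[, 1L] - mean(x)),
               tolerance = 1e-12)
  # additive two-feature case: attributions match each term
  x2 <- matrix(rnorm(60), ncol = 2L)
  f2 <- function(m) 3 * m[, 1L] - m[, 2L]
  bg2 <- matrix(colMeans(x2), 1L, 2L)
  sh2 <- chemgroup:::sampling_shapley(f2, x2, bg2, n_permutations = 8L,
                                      seed = 2L)
  expect_equal(sh2$values[, 1L], 3 * (x2[, 1L] - mean(x2[, 1L])),
               tolerance = 1e-10)
  expect_equal(sh2$values[, 2L], -(x2[, 2L] - mean(x2[, 2L])),
               tolerance = 1e-10)
})

test_that("duplicated identical features share attribution symmetrically", {
  set.seed(23)
  v <- rnorm(60)
  x <- cbind(a = v, b = v)
  f <- function(m) m[, "a"] + m[, "b"]
  bg <- matrix(colMeans(x), 1L, 2L, dimnames = list(NULL, c("a", "b")))
  sh <- chemgroup:::sampling_shapley(f, x, bg, n_permutations = 50L,
                                     seed = 3L)
  expect_equal(mean(abs(sh$values[, 1L] - sh$values[, 2L])), 0,
               tolerance = 0.15)
})

test_that("non-tree families get sampling attribution with matching layout", {
  fx <- make_labeled_features(60L, 2L, 2L, effect = 2, "binary",
                              seed = 24L)
  fit <- fit_learner(fast_logit(seed = 2L), fx$x, fx$labels)
  sh <- compute_shap(fit, fx$x, n_permutations = 8L, seed = 4L)
  expect_equal(dim(sh$values), dim(fx$x))
  expect_equal(sh$method, "permutation_sampling")
  # informative columns dominate the attribution
  mabs <- colMeans(abs(sh$values))
  expect_gt(min(mabs[fx$informative]), max(mabs[c("noise_01", "noise_02")]))
})

test_that("multiclass SHAP concatenates one block per class", {
  fx <- make_labeled_features(90L, 2L, 2L, effect = 2, "multiclass",
                              seed = 25L)
  fit <- fit_learner(small_gbt(seed = 5L), fx$x, fx$labels)
  sh <- compute_shap(fit, fx$x)
  expect_equal(ncol(sh$values), ncol(fx$x) * 3L)
  expect_equal(length(sh$base_values), 3L)
  expect_true(all(grepl("\\|class", colnames(sh$values))))
})

test_that("SHAP-based grouping requires labels and flags its results", {
  fx <- make_labeled_features(80L, 2L, 4L, effect = 3, "binary",
                              seed = 26L)
  expect_error(shap_supervised_grouping(fx$x, NULL, small_gbt()),
               "labeled")
  sp <- search_space(list(param_int("n_clusters", 2L, 4L)),
                     n_trials = 6L, seed = 2L)
  g <- shap_supervised_grouping(fx$x, fx$labels, small_gbt(seed = 6L),
                                cluster_method = "kmedoids",
                                projection_method = "pca", space = sp,
                                seed = 2L)
  expect_true(g$shap_based)
  expect_equal(length(g$labels), 80L)
})

test_that("endpoint-driven SHAP grouping is purer than structure-only grouping", {
  # labels driven by 2 of 20 features; SHAP space should align clusters
  # with the endpoint better than raw-feature clustering
  fx <- make_labeled_features(150L, 2L, 18L, effect = 3, "binary",
                              seed = 27L)
  purity <- function(labels, y) {
    ids <- setdiff(unique(labels), -1L)
    w <- vapply(ids, function(cl) sum(labels == cl), 0)
    p <- vapply(ids, function(cl) {
      tab <- table(y[labels == cl])
      max(tab) / sum(tab)
    }, 0)
    sum(w * p) / sum(w)
  }
  sp <- search_space(list(param_int("n_clusters", 2L, 4L)),
                     n_trials = 6L, seed = 3L)
  g_shap <- shap_supervised_grouping(fx$x, fx$labels, small_gbt(seed = 7L),
                                     cluster_method = "kmeans",
                                     projection_method = "pca",
                                     space = sp, seed = 3L)
  g_raw <- tune_grouping(fx$x, "kmeans", "pca", space = sp,
                         projected = TRUE, seed = 3L)
  expect_gt(purity(g_shap$labels, fx$labels),
            purity(g_raw$labels, fx$labels))
})

test_that("a cluster split defined by one bit ranks that bit first", {
  set.seed(28)
  x <- matrix(rbinom(200L * 12L, 1L, 0.5), 200L, 12L)
  colnames(x) <- sprintf("bit_%02d", 1:12)
  labels <- x[, 7L]
  ci <- interpret_clusters(x, labels, top_k = 3L, seed = 2L)
  expect_equal(ci$clusters[[1L]]$ranking$descriptor[1L], "bit_07")
  expect_equal(ci$clusters[[2L]]$ranking$descriptor[1L], "bit_07")
  # direction: presence of the bit drives membership of cluster 1
  r1 <- ci$clusters[[2L]]$ranking
  expect_equal(r1$direction[1L], "positive")
  # ranking is invariant to relabeling the clusters
  ci2 <- interpret_clusters(x, 1L - labels, top_k = 3L, seed = 2L)
  expect_equal(ci2$clusters[[2L]]$ranking$descriptor[1L], "bit_07")
})

test_that("top_k larger than p returns all columns ranked", {
  set.seed(29)
  x <- matrix(rnorm(200L), 50L, 4L,
              dimnames = list(NULL, paste0("d", 1:4)))
  labels <- as.integer(x[, 1L] > 0)
  ci <- interpret_clusters(x, labels, top_k = 99L, seed = 3L)
  expect_equal(nrow(ci$clusters[[1L]]$ranking), 4L)
  expect_equal(length(ci$clusters[[1L]]$top_k), 4L)
})

test_that("interpretation refuses single clusters and warns on tiny ones", {
  x <- matrix(rnorm(40L), 20L, 2L, dimnames = list(NULL, c("a", "b")))
  expect_error(interpret_clusters(x, rep(0L, 20L)), ">= 2 clusters")
  lab <- c(rep(0L, 19L), 1L)
  expect_warning(
    try(interpret_clusters(x, lab, learner = fast_logit(), top_k = 1L),
        silent = TRUE),
    "< 2 members")
})

test_that("the template summarizer is deterministic and complete", {
  set.seed(30)
  x <- matrix(rbinom(400L, 1L, 0.5), 100L, 4L)
  colnames(x) <- paste0("bit_", 1:4)
  ci <- interpret_clusters(x, x[, 2L], top_k = 2L, seed = 4L)
  t1 <- summarize_interpretation(ci)
  t2 <- summarize_interpretation(ci)
  expect_identical(t1, t2)
  # contains every cluster's top-1 descriptor
  for (cl in ci$clusters)
    expect_true(grepl(cl$ranking$descriptor[1L], t1, fixed = TRUE))
  # endpoint description switches the phrasing branch
  t3 <- summarize_interpretation(ci, endpoint_description = "eye irritation")
  expect_true(grepl("eye irritation", t3, fixed = TRUE))
  expect_false(grepl("eye irritation", t1, fixed = TRUE))
  # external backend without a function falls back with a warning
  expect_warning(t4 <- summarize_interpretation(ci, backend = "external"),
                 "falling back")
  expect_identical(t4, t1)
  # injected external backend is used verbatim
  t5 <- summarize_interpretation(ci, backend = "external",
                                 external_fn = function(ci, ep) "custom")
  expect_identical(t5, "custom")
})
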