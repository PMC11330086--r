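# Silhouette, clustering algorithms, 2-D projections, and TPE tuning.

test_that("silhouette matches hand-evaluated values", {
  # two coincident clusters far apart: a = 0 everywhere -> 1.0
  x <- rbind(c(0, 0), c(0, 0), c(9, 9), c(9, 9))
  expect_equal(silhouette_score(x, c(0L, 0L, 1L, 1L)), 1.0)
  # {(0,0),(0,1)} vs {(10,0),(10,1)}: a = 1, b = (10 + sqrt(101)) / 2
  x2 <- rbind(c(0, 0), c(0, 1), c(10, 0), c(10, 1))
  b <- (10 + sqrt(101)) / 2
  expect_equal(silhouette_score(x2, c(0L, 0L, 1L, 1L)), (b - 1) / b,
               tolerance = 1e-12)
  expect_equal(round(silhouette_score(x2, c(0L, 0L, 1L, 1L)), 3), 0.9)
  # a single cluster is undefined, signalled as an error
  expect_error(silhouette_score(x2, rep(0L, 4L)), "undefined")
})

test_that("silhouette is invariant to cluster relabeling and ignores noise", {
  set.seed(12)
  x <- matrix(rnorm(80), 40, 2)
  lab <- sample(0:2, 40, replace = TRUE)
  s1 <- silhouette_score(x, lab)
  relab <- c(2L, 0L, 1L)[lab + 1L]
  expect_equal(silhouette_score(x, relab), s1)
  # noise points are excluded before computation
  lab2 <- lab
  lab2[1:5] <- -1L
  expect_equal(silhouette_score(x, lab2),
               silhouette_score(x[-(1:5), ], lab[-(1:5)]))
})

test_that("silhouette agrees with the brute-force double loop", {
  set.seed(33)
  for (rep in 1:15) {
    n <- sample(10:120, 1L)
    x <- matrix(rnorm(n * 3L), n, 3L)
    lab <- sample(0:3, n, replace = TRUE)
    lab[sample(n, min(3L, n))] <- -1L
    if (length(setdiff(unique(lab), -1L)) < 2L) next
    expect_equal(silhouette_score(x, lab), brute_silhouette(x, lab),
                 tolerance = 1e-9)
  }
})

test_that("partitional clusterers recover well-separated blobs exactly", {
  fx <- make_feature_blobs(90L, 2L, 4L, separation = 20, seed = 5L)
  for (method in c("kmeans", "kmedoids", "hierarchical")) {
    lab <- run_clustering(fx$x, cluster_spec(method,
                                             list(n_clusters = 2L),
                                             seed = 4L))
    expect_equal(mclust::adjustedRandIndex(lab, fx$labels), 1.0)
    expect_equal(length(unique(lab)), 2L)
  }
})

test_that("DBSCAN labels all points noise below the minimum pairwise distance", {
  set.seed(6)
  x <- matrix(runif(30, 0, 100), 15, 2)
  eps <- min(dist(x)) / 2
  lab <- run_clustering(x, cluster_spec("dbscan",
                                        list(epsilon = eps,
                                             min_samples = 2L)))
  expect_true(all(lab == -1L))
  # and recovers dense blobs with a sensible epsilon
  fx <- make_feature_blobs(100L, 2L, 2L, separation = 30, seed = 7L)
  lab2 <- run_clustering(fx$x, cluster_spec("dbscan",
                                            list(epsilon = 3,
                                                 min_samples = 4L)))
  expect_equal(mclust::adjustedRandIndex(lab2, fx$labels), 1.0)
})

test_that("HDBSCAN separates blobs and flags a far outlier as noise", {
  fx <- make_feature_blobs(60L, 3L, 3L, separation = 30, seed = 8L)
  x <- rbind(fx$x, c(500, 500, 500))
  lab <- run_clustering(x, cluster_spec("hdbscan",
                                        list(min_cluster_size = 5L)))
  expect_equal(lab[61L], -1L)
  expect_equal(mclust::adjustedRandIndex(lab[1:60], fx$labels), 1.0)
})

test_that("hierarchical clustering cut to n points gives singletons", {
  set.seed(9)
  x <- matrix(rnorm(20), 10, 2)
  lab <- run_clustering(x, cluster_spec("hierarchical",
                                        list(n_clusters = 10L)))
  expect_equal(sort(unique(lab)), 0:9)
})

test_that("PCA embedding kills the null direction of collinear input", {
  t <- seq(-3, 3, length.out = 25L)
  x <- cbind(t, 2 * t)
  emb <- project_2d(x, projection_spec("pca"))
  expect_equal(dim(emb), c(25L, 2L))
  expect_lt(var(emb[, 2L]), 1e-20)
  expect_equal(var(emb[, 1L]), var(t) * 5, tolerance = 1e-12)
})

test_that("parameter validation guards the projections", {
  x <- matrix(rnorm(30), 15, 2)
  expect_error(project_2d(x[1:2, ], projection_spec("pca")),
               "at least 3 points")
  expect_error(projection_spec("umap", list(min_dist = 1.5)), "min_dist")
  expect_error(project_2d(x, projection_spec("umap",
                                             list(n_neighbors = 50L))),
               "smaller than the number of points")
  expect_error(project_2d(x, projection_spec("tsne",
                                             list(perplexity = 10))),
               "3 \\* perplexity")
})

test_that("a one-trial tuning run returns exactly that trial", {
  fx <- make_feature_blobs(60L, 3L, 5L, separation = 10, seed = 10L)
  sp <- search_space(list(param_int("n_clusters", 3L, 3L + 1L)),
                     n_trials = 1L, seed = 6L)
  g <- tune_grouping(fx$x, "kmeans", "pca", space = sp, projected = TRUE)
  expect_equal(nrow(g$tuning_trace), 1L)
  expect_equal(g$silhouette, g$tuning_trace$.value[1L])
  expect_equal(g$config$cluster_params$n_clusters,
               g$tuning_trace$n_clusters[1L])
})

test_that("tuning recovers the planted blob count and is reproducible", {
  fx <- make_feature_blobs(150L, 3L, 6L, separation = 20, seed = 11L)
  sp <- search_space(list(param_int("n_clusters", 2L, 8L)),
                     n_trials = 12L, seed = 7L)
  g1 <- tune_grouping(fx$x, "kmeans", "pca", space = sp, projected = TRUE)
  expect_equal(length(unique(g1$labels)), 3L)
  expect_gt(g1$silhouette, 0.8)
  # best trace objective equals the returned silhouette
  expect_equal(max(g1$tuning_trace$.value), g1$silhouette)
  g2 <- tune_grouping(fx$x, "kmeans", "pca", space = sp, projected = TRUE)
  expect_identical(g1$labels, g2$labels)
  expect_identical(g1$embedding, g2$embedding)
})

test_that("non-projected tuning returns embedding labels plus full-space labels", {
  fx <- make_feature_blobs(90L, 3L, 5L, separation = 15, seed = 12L)
  sp <- search_space(list(param_int("n_clusters", 2L, 8L)),
                     n_trials = 12L, seed = 8L)
  g <- tune_grouping(fx$x, "kmeans", "pca", space = sp,
                     projected = FALSE, n_trials = 12L, seed = 8L)
  expect_equal(length(g$labels), 90L)
  expect_false(is.null(g$full_space_labels))
  expect_equal(mclust::adjustedRandIndex(g$full_space_labels, fx$labels),
               1.0)
  expect_false(g$config$projected)
})

test_that("UMAP and t-SNE embeddings are deterministic given the seed", {
  fx <- make_feature_blobs(90L, 3L, 8L, separation = 20, seed = 13L)
  # one backend call carrying repeated jobs for both methods
  u <- chemgroup:::embed_batch(fx$x, "umap",
                               list(list(min_dist = 0.1, n_neighbors = 10L),
                                    list(min_dist = 0.1, n_neighbors = 10L)),
                               list(3L, 3L))
  expect_identical(u[[1L]], u[[2L]])
  expect_equal(dim(u[[1L]]), c(90L, 2L))
  # blobs stay separated in the UMAP embedding
  emb <- u[[1L]]
  intra <- max(vapply(0:2, function(cl)
    max(dist(emb[fx$labels == cl, ])), 0))
  dmat <- as.matrix(dist(emb))
  inter <- min(vapply(0:1, function(a) min(vapply((a + 1):2, function(b)
    min(dmat[fx$labels == a, fx$labels == b]), 0)), 0))
  expect_gt(inter, intra)
  ts <- chemgroup:::embed_batch(fx$x, "tsne",
                                list(list(perplexity = 12),
                                     list(perplexity = 12)),
                                list(4L, 4L))
  expect_identical(ts[[1L]], ts[[2L]])
  expect_equal(dim(ts[[1L]]), c(90L, 2L))
})

test_that("TPE beats random search on a smooth 1-D objective", {
  f <- function(batch) vapply(batch, function(p)
    -(p$z - 0.7)^2, 0)
  sp <- search_space(list(param_uniform("z", 0, 1)), n_trials = 40L,
                     seed = 9L)
  opt <- tpe_optimize(sp, f)
  expect_equal(opt$best_params$z, 0.7, tolerance = 0.1)
  expect_equal(nrow(opt$trials), 40L)
  expect_equal(max(opt$trials$.value), opt$best_value)
})
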