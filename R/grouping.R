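# Silhouette-driven grouping with TPE hyperparameter tuning, in projected
# mode (projection and clusterer parameters tuned jointly; the objective
# is the silhouette of the clustered 2-D embedding) or non-projected mode
# (clusterer tuned on the full feature space first, then projection
# parameters tuned with the clusterer frozen, re-clustering each trial
# embedding). Degenerate trials - clustering errors, fewer than two
# clusters, or more than 50% noise - score -1 so that unpunished noise
# cannot inflate the objective.

new_grouping_result <- function(labels, embedding, silhouette, config,
                                tuning_trace, full_space_labels = NULL,
                                shap_based = FALSE) {
  structure(list(labels = as.integer(labels), embedding = embedding,
                 silhouette = silhouette, config = config,
                 tuning_trace = tuning_trace,
                 full_space_labels = full_space_labels,
                 shap_based = shap_based),
            class = "chemgroup_grouping")
}

#' @export
print.chemgroup_grouping <- function(x, ...) {
  k <- length(setdiff(unique(x$labels), -1L))
  cat("<chemgroup_grouping> ", k, " clusters, silhouette ",
      signif(x$silhouette, 3),
      if (x$shap_based) " (SHAP-based)" else "", "\n", sep = "")
  invisible(x)
}

# default, configurable search ranges (k 2-25, min_dist 0.01-0.25,
# n_neighbors 2-50, 50 trials) mirroring the case-study settings
cluster_param_space <- function(method, n) {
  switch(method,
    kmeans = ,
    kmedoids = list(param_int("n_clusters", 2L, min(25L, n - 1L))),
    hierarchical = list(
      param_int("n_clusters", 2L, min(25L, n - 1L)),
      param_choice("linkage", c("single", "complete", "average")),
      param_choice("metric", c("euclidean", "manhattan"))),
    dbscan = list(param_uniform("epsilon_quantile", 0.01, 0.5),
                  param_int("min_samples", 2L, 15L)),
    hdbscan = list(param_int("min_cluster_size", 2L, min(25L, n - 1L))))
}

projection_param_space <- function(method, n) {
  switch(method,
    pca = list(),
    umap = list(param_uniform("min_dist", 0.01, 0.25),
                param_int("n_neighbors", 2L, min(50L, n - 1L))),
    tsne = list(param_uniform("perplexity", 5,
                              max(6, min(50, (n - 1) / 3)))))
}

#' Default joint search space for tuned grouping
#'
#' @param cluster_method,projection_method Method names as in
#'   [cluster_spec()] / [projection_spec()].
#' @param n Number of observations (used to cap ranges).
#' @param projected Include projection parameters (projected mode)?
#' @param n_trials,seed Passed to [search_space()].
#' @return A `tpe_space`.
#' @export
default_grouping_space <- function(cluster_method, projection_method, n,
                                   projected = TRUE, n_trials = 50L,
                                   seed = 1L) {
  params <- cluster_param_space(cluster_method, n)
  if (projected)
    params <- c(params, projection_param_space(projection_method, n))
  search_space(params, n_trials = n_trials, seed = seed)
}

split_trial_params <- function(params, cluster_method, projection_method,
                               x = NULL) {
  cl_names <- vapply(cluster_param_space(cluster_method, 10^6), `[[`, "",
                     "name")
  pr_names <- vapply(projection_param_space(projection_method, 10^6),
                     `[[`, "", "name")
  cl <- params[intersect(names(params), cl_names)]
  pr <- params[intersect(names(params), pr_names)]
  # DBSCAN's epsilon is searched on the quantile scale of the pairwise
  # distances so one range fits any embedding scale
  if (!is.null(cl$epsilon_quantile) && !is.null(x)) {
    d <- stats::dist(x)
    cl$epsilon <- max(stats::quantile(d, cl$epsilon_quantile),
                      .Machine$double.eps)
    cl$epsilon_quantile <- NULL
  }
  list(cluster = cl, projection = pr)
}

evaluate_partition <- function(points, labels) {
  ids <- setdiff(unique(labels), -1L)
  if (length(ids) < 2L) return(-1)
  if (mean(labels == -1L) > 0.5) return(-1)
  tryCatch(silhouette_score(points, labels), error = function(e) -1)
}

#' Tune a grouping with TPE
#'
#' In projected mode each trial samples projection and clusterer
#' parameters jointly, embeds the data, clusters the embedding, and
#' scores the silhouette of the embedding. In non-projected mode the
#' clusterer is tuned first on the full feature matrix, then the
#' projection is tuned with the clusterer frozen, re-clustering each
#' trial's embedding; the returned labels come from the best stage-2
#' embedding, and the tuned full-space labels are kept alongside.
#'
#' @param fm Feature matrix.
#' @param cluster_method One of the [cluster_spec()] methods.
#' @param projection_method One of the [projection_spec()] methods.
#' @param space A [search_space()]; defaults to
#'   [default_grouping_space()].
#' @param projected Tune jointly on the 2-D embedding (default) or in
#'   two stages.
#' @param n_trials,seed Used when `space` is not supplied; `seed` also
#'   derives every per-trial seed.
#' @param batch_size Trials proposed per TPE update (UMAP/t-SNE trials
#'   are embedded together per batch).
#' @return A `chemgroup_grouping` with labels, embedding, silhouette,
#'   winning configuration, and the full tuning trace.
#' @export
tune_grouping <- function(fm, cluster_method = "kmeans",
                          projection_method = "umap", space = NULL,
                          projected = TRUE, n_trials = 50L, seed = 1L,
                          batch_size = NULL) {
  x <- fm_values(fm)
  n <- nrow(x)
  bump_counter("tuning_runs")
  if (is.null(batch_size))
    batch_size <- if (projection_method == "pca") 1L else 8L
  store <- new.env(parent = emptyenv())
  store$trials <- list()

  eval_projected <- function(batch) {
    split <- lapply(batch, split_trial_params, cluster_method,
                    projection_method)
    seeds <- lapply(batch, `[[`, ".seed")
    embeddings <- embed_batch(x, projection_method,
                              lapply(split, `[[`, "projection"), seeds)
    vapply(seq_along(batch), function(i) {
      emb <- embeddings[[i]]
      res <- tryCatch({
        # epsilon is resolved on the embedding actually clustered
        cl <- split_trial_params(batch[[i]], cluster_method,
                                 projection_method, emb)$cluster
        labels <- run_clustering(emb, cluster_spec(cluster_method, cl,
                                                   seed = seeds[[i]]))
        list(labels = labels,
             value = evaluate_partition(emb, labels), emb = emb)
      }, error = function(e) list(labels = NULL, value = -1, emb = emb))
      store$trials[[length(store$trials) + 1L]] <- res
      res$value
    }, 0)
  }

  if (projected) {
    if (is.null(space))
      space <- default_grouping_space(cluster_method, projection_method,
                                      n, TRUE, n_trials, seed)
    opt <- tpe_optimize(space, eval_projected, batch_size = batch_size)
    if (opt$best_value <= -1)
      stop("every tuning trial was degenerate; inspect the trace")
    best <- store$trials[[opt$best_index]]
    cfg <- split_trial_params(opt$best_params, cluster_method,
                              projection_method, best$emb)
    return(new_grouping_result(
      best$labels, best$emb, opt$best_value,
      list(cluster_method = cluster_method,
           projection_method = projection_method,
           cluster_params = cfg$cluster, projection_params = cfg$projection,
           seed = opt$best_params$.seed, projected = TRUE),
      opt$trials))
  }

  # ---- non-projected: stage 1 tunes the clusterer in full space
  space1 <- if (!is.null(space)) {
    cl_names <- vapply(cluster_param_space(cluster_method, 10^6), `[[`,
                       "", "name")
    pars <- space$params[intersect(names(space$params), cl_names)]
    if (length(pars) == 0L) pars <- cluster_param_space(cluster_method, n)
    search_space(unname(pars), n_trials = space$n_trials,
                 seed = space$seed)
  } else {
    search_space(cluster_param_space(cluster_method, n),
                 n_trials = n_trials, seed = seed)
  }
  eval_full <- function(batch) {
    vapply(batch, function(params) {
      res <- tryCatch({
        cl <- split_trial_params(params, cluster_method,
                                 projection_method, x)$cluster
        labels <- run_clustering(x, cluster_spec(cluster_method, cl,
                                                 seed = params$.seed))
        list(labels = labels, value = evaluate_partition(x, labels))
      }, error = function(e) list(labels = NULL, value = -1))
      store$trials[[length(store$trials) + 1L]] <- res
      res$value
    }, 0)
  }
  opt1 <- tpe_optimize(space1, eval_full, batch_size = 1L)
  if (opt1$best_value <= -1)
    stop("every stage-1 tuning trial was degenerate; inspect the trace")
  full_labels <- store$trials[[opt1$best_index]]$labels
  frozen <- split_trial_params(opt1$best_params, cluster_method,
                               projection_method, x)$cluster

  # ---- stage 2: tune the projection, clusterer frozen
  store$trials <- list()
  space2 <- search_space(projection_param_space(projection_method, n),
                         n_trials = n_trials, seed = seed + 1L)
  if (length(space2$params) == 0L)
    space2 <- search_space(list(param_uniform(".dummy", 0, 1)),
                           n_trials = 1L, seed = seed + 1L)
  eval_proj2 <- function(batch) {
    seeds <- lapply(batch, `[[`, ".seed")
    pr <- lapply(batch, function(params)
      split_trial_params(params, cluster_method, projection_method)$projection)
    embeddings <- embed_batch(x, projection_method, pr, seeds)
    vapply(seq_along(batch), function(i) {
      emb <- embeddings[[i]]
      res <- tryCatch({
        cl <- frozen
        labels <- run_clustering(emb, cluster_spec(cluster_method, cl,
                                                   seed = seeds[[i]]))
        list(labels = labels, value = evaluate_partition(emb, labels),
             emb = emb)
      }, error = function(e) list(labels = NULL, value = -1, emb = emb))
      store$trials[[length(store$trials) + 1L]] <- res
      res$value
    }, 0)
  }
  opt2 <- tpe_optimize(space2, eval_proj2, batch_size = batch_size)
  if (opt2$best_value <= -1)
    stop("every stage-2 tuning trial was degenerate; inspect the trace")
  best <- store$trials[[opt2$best_index]]
  pr_params <- split_trial_params(opt2$best_params, cluster_method,
                                  projection_method)$projection
  new_grouping_result(
    best$labels, best$emb, opt2$best_value,
    list(cluster_method = cluster_method,
         projection_method = projection_method,
         cluster_params = frozen, projection_params = pr_params,
         seed = opt2$best_params$.seed, projected = FALSE),
    rbind_fill(opt1$trials, opt2$trials),
    full_space_labels = full_labels)
}

# row-bind trace frames with different columns
rbind_fill <- function(a, b) {
  cols <- union(names(a), names(b))
  for (m in setdiff(cols, names(a))) a[[m]] <- NA
  for (m in setdiff(cols, names(b))) b[[m]] <- NA
  rbind(a[cols], b[cols])
}
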