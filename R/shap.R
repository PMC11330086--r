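# SHAP attribution and its two uses in the workflow: endpoint-specific
# (supervised) grouping on the SHAP matrix, and one-vs-rest SHAP
# interpretation of any clustering. Gradient-boosted trees get exact
# tree-path attribution (xgboost predcontrib); every other family gets a
# permutation-sampling approximation with a fixed background and seed.
# For binary tasks the positive-class block is used; multiclass problems
# concatenate per-class blocks (n x p*C) before clustering.

new_shap_matrix <- function(values, base_values, learner_spec, classes,
                            method) {
  structure(list(values = values, base_values = base_values,
                 learner_spec = learner_spec, classes = classes,
                 method = method),
            class = "chemgroup_shap")
}

#' @export
print.chemgroup_shap <- function(x, ...) {
  cat("<chemgroup_shap> ", nrow(x$values), " x ", ncol(x$values),
      " (", x$method, ")\n", sep = "")
  invisible(x)
}

#' Compute SHAP values for a fitted learner
#'
#' Tree ensembles fitted by `gradient_boosted_trees` use exact tree-path
#' attribution on the margin scale: each row of values plus the base
#' value reproduces the model margin to numerical precision. All other
#' families use permutation-sampling Shapley values of the predicted
#' probability (positive class / per class) or regression output against
#' a background sample: per permutation, features are switched one at a
#' time from a background row to the explained row, and successive
#' prediction differences are the feature contributions.
#'
#' @param fitted A fitted `chemgroup_learner`.
#' @param fm Feature matrix with the training columns.
#' @param background Background rows for the sampling approximation
#'   (default: the data itself, subsampled to `max_background`).
#' @param n_permutations Permutations for the sampling approximation.
#' @param max_background Background subsample cap.
#' @param seed Sampling seed.
#' @return A `chemgroup_shap` whose columns are the descriptors (binary /
#'   regression) or descriptor-by-class blocks named
#'   `"<descriptor>|class<k>"` (multiclass).
#' @export
compute_shap <- function(fitted, fm, background = NULL,
                         n_permutations = 32L, max_background = 50L,
                         seed = 1L) {
  stopifnot(inherits(fitted, "chemgroup_learner"))
  x <- check_columns(fitted, fm_values(fm))
  spec <- fitted$spec
  classes <- fitted$classes
  multi <- !is.null(classes) && length(classes) > 2L

  if (spec$family == "gradient_boosted_trees") {
    contrib <- predict(fitted$model, xgboost::xgb.DMatrix(x),
                       predcontrib = TRUE)
    if (multi) {
      # (n, class, p+1) array -> concatenated class blocks
      blocks <- lapply(seq_along(classes), function(ci) {
        m <- contrib[, ci, , drop = TRUE]
        if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
        m
      })
      base_values <- vapply(blocks, function(b) b[1L, ncol(b)], 0)
      vals <- do.call(cbind, lapply(blocks, function(b)
        b[, -ncol(b), drop = FALSE]))
      colnames(vals) <- unlist(lapply(seq_along(classes), function(ci)
        paste0(fitted$columns, "|class", classes[ci])))
    } else {
      base_values <- contrib[1L, ncol(contrib)]
      vals <- contrib[, -ncol(contrib), drop = FALSE]
      colnames(vals) <- fitted$columns
    }
    return(new_shap_matrix(vals, base_values, spec, classes, "tree_exact"))
  }

  set.seed(seed)
  if (is.null(background)) {
    idx <- if (nrow(x) > max_background)
      sample.int(nrow(x), max_background) else seq_len(nrow(x))
    background <- x[idx, , drop = FALSE]
  }
  if (is.null(classes)) {
    f <- function(m) predict_value(fitted, m)
    sh <- sampling_shapley(f, x, background, n_permutations, seed)
    colnames(sh$values) <- fitted$columns
    return(new_shap_matrix(sh$values, sh$base, spec, NULL,
                           "permutation_sampling"))
  }
  out_blocks <- list()
  bases <- numeric(0)
  class_cols <- if (length(classes) == 2L) 2L else seq_along(classes)
  for (ci in class_cols) {
    f <- local({
      ci_ <- ci
      function(m) {
        colnames(m) <- fitted$columns
        predict_prob(fitted, m)[, ci_]
      }
    })
    sh <- sampling_shapley(f, x, background, n_permutations,
                           seed + ci)
    out_blocks[[length(out_blocks) + 1L]] <- sh$values
    bases <- c(bases, sh$base)
  }
  vals <- do.call(cbind, out_blocks)
  colnames(vals) <- if (length(classes) == 2L) fitted$columns else
    unlist(lapply(classes, function(cl) paste0(fitted$columns, "|class",
                                               cl)))
  new_shap_matrix(vals, bases, spec, classes, "permutation_sampling")
}

# Permutation-sampling Shapley values of f over rows of x.
# Per permutation: start from a background row, switch features to the
# explained row one at a time in permuted order; successive prediction
# differences telescope, so per-row attributions sum exactly to
# f(x) - mean_z f(z) for the sampled backgrounds.
sampling_shapley <- function(f, x, background, n_permutations, seed) {
  n <- nrow(x)
  p <- ncol(x)
  set.seed(seed)
  phi <- matrix(0, n, p)
  base_acc <- 0
  for (m in seq_len(n_permutations)) {
    perm <- sample.int(p)
    z_idx <- sample.int(nrow(background), n, replace = TRUE)
    cur <- background[z_idx, , drop = FALSE]
    prev_pred <- f(cur)
    base_acc <- base_acc + mean(prev_pred)
    for (j in perm) {
      cur[, j] <- x[, j]
      pred <- f(cur)
      phi[, j] <- phi[, j] + (pred - prev_pred)
      prev_pred <- pred
    }
  }
  list(values = phi / n_permutations, base = base_acc / n_permutations)
}

#' Endpoint-specific (SHAP-based) supervised grouping
#'
#' Fits a learner on the labeled descriptors, computes the SHAP matrix,
#' and feeds it - in place of the raw descriptors - to [tune_grouping()],
#' so compounds are grouped by how similarly their descriptors drive the
#' model's output rather than by structure alone.
#'
#' @param fm Feature matrix.
#' @param labels Labels (required).
#' @param learner A [learner_spec()].
#' @param cluster_method,projection_method,space,projected,n_trials,seed
#'   Passed to [tune_grouping()].
#' @param ... Further arguments to [compute_shap()].
#' @return A `chemgroup_grouping` with `shap_based = TRUE`.
#' @export
shap_supervised_grouping <- function(fm, labels, learner,
                                     cluster_method = "kmedoids",
                                     projection_method = "umap",
                                     space = NULL, projected = TRUE,
                                     n_trials = 50L, seed = 1L, ...) {
  if (is.null(labels) || all(is.na(labels)))
    stop("SHAP-based grouping requires a labeled dataset")
  fitted <- fit_learner(learner, fm, labels)
  shap <- compute_shap(fitted, fm, seed = seed, ...)
  res <- tune_grouping(shap$values, cluster_method, projection_method,
                       space = space, projected = projected,
                       n_trials = n_trials, seed = seed)
  res$shap_based <- TRUE
  res$config$learner <- unclass(learner)
  res
}

#' SHAP interpretation of a clustering
#'
#' Fits a classifier with the descriptors as independent variables and
#' the cluster labels as dependent variable (noise points excluded),
#' computes per-class SHAP values, and ranks each cluster's descriptors
#' by the mean absolute SHAP of that cluster's members in its
#' one-vs-rest attribution block. Positive signed means denote a
#' positive association of the descriptor with membership.
#'
#' @param fm Feature matrix.
#' @param cluster_labels Integer cluster ids (`-1` = noise).
#' @param learner A classification [learner_spec()]; defaults to
#'   gradient-boosted trees for exact attribution.
#' @param top_k Descriptors reported per cluster (capped at p).
#' @param seed Seed for sampling attribution if needed.
#' @return A `chemgroup_interpretation`: per cluster a ranking
#'   data.frame (`descriptor`, `mean_abs_shap`, `direction`) and the
#'   per-point SHAP values of the `top_k` descriptors.
#' @export
interpret_clusters <- function(fm, cluster_labels, learner = NULL,
                               top_k = 5L, seed = 1L) {
  x <- fm_values(fm)
  keep <- cluster_labels != -1L
  x <- x[keep, , drop = FALSE]
  y <- cluster_labels[keep]
  ids <- sort(unique(y))
  if (length(ids) < 2L) stop("interpretation requires >= 2 clusters")
  small <- ids[vapply(ids, function(cl) sum(y == cl) < 2L, TRUE)]
  if (length(small))
    warning("clusters with < 2 members: ",
            paste(small, collapse = ", "))
  if (is.null(learner))
    learner <- learner_spec("gradient_boosted_trees", "classification",
                            seed = seed)
  top_k <- min(top_k, ncol(x))
  fitted <- fit_learner(learner, x, y)
  shap <- compute_shap(fitted, x, seed = seed)

  block_for <- function(cl) {
    if (length(ids) == 2L) {
      # positive-class block; the other cluster is its mirror image
      v <- shap$values
      if (cl == ids[1L]) -v else v
    } else {
      cols <- grepl(paste0("\\|class", cl, "$"), colnames(shap$values))
      v <- shap$values[, cols, drop = FALSE]
      colnames(v) <- sub("\\|class.*$", "", colnames(v))
      v
    }
  }
  per_cluster <- lapply(ids, function(cl) {
    block <- block_for(cl)
    members <- y == cl
    mabs <- colMeans(abs(block[members, , drop = FALSE]))
    msign <- colMeans(block[members, , drop = FALSE])
    ord <- order(mabs, decreasing = TRUE)
    ranking <- data.frame(descriptor = colnames(block)[ord],
                          mean_abs_shap = unname(mabs[ord]),
                          direction = ifelse(msign[ord] >= 0,
                                             "positive", "negative"),
                          stringsAsFactors = FALSE)
    top <- ranking$descriptor[seq_len(top_k)]
    dist_df <- do.call(rbind, lapply(top, function(dsc) {
      data.frame(descriptor = dsc,
                 shap = block[members, dsc],
                 feature_value = x[members, dsc],
                 stringsAsFactors = FALSE)
    }))
    list(cluster = cl, ranking = ranking, top_k = top,
         distributions = dist_df)
  })
  names(per_cluster) <- paste0("cluster_", ids)
  structure(list(clusters = per_cluster, top_k = top_k,
                 learner = unclass(learner),
                 shap_method = shap$method),
            class = "chemgroup_interpretation")
}

#' @export
print.chemgroup_interpretation <- function(x, ...) {
  cat("<chemgroup_interpretation> ", length(x$clusters),
      " clusters, top ", x$top_k, " descriptors each\n", sep = "")
  invisible(x)
}

#' Natural-language summary of a cluster interpretation
#'
#' The `template` backend is fully deterministic: it names each
#' cluster's top descriptors and their direction of association, and
#' restates the endpoint description when one is given. The `external`
#' backend is an injection point with the same signature (a function
#' `(interpretation, endpoint_description) -> character`), e.g. for a
#' remote language model; if no function is supplied it falls back to
#' the template with a warning.
#'
#' @param ci A `chemgroup_interpretation`.
#' @param backend `"template"` or `"external"`.
#' @param endpoint_description Optional short description of the studied
#'   endpoint.
#' @param external_fn Summarizer function for the external backend.
#' @return A single character string.
#' @export
summarize_interpretation <- function(ci, backend = c("template", "external"),
                                     endpoint_description = NULL,
                                     external_fn = NULL) {
  backend <- match.arg(backend)
  stopifnot(inherits(ci, "chemgroup_interpretation"))
  if (backend == "external") {
    if (is.function(external_fn))
      return(external_fn(ci, endpoint_description))
    warning("external summarizer unavailable; falling back to template")
  }
  header <- if (is.null(endpoint_description) ||
                !nzchar(endpoint_description)) {
    "Grouping interpretation (descriptor attribution summary)."
  } else {
    paste0("Grouping interpretation for the endpoint: ",
           endpoint_description, ".")
  }
  body <- vapply(ci$clusters, function(cl) {
    lead <- cl$ranking[seq_along(cl$top_k), ]
    phrases <- paste0(lead$descriptor, " (", lead$direction, ")")
    paste0("Cluster ", cl$cluster, " is characterized by ",
           paste(phrases, collapse = ", "),
           "; descriptors are ranked by mean absolute SHAP value among ",
           "the cluster's compounds.")
  }, "")
  paste(c(header, body), collapse = "\n")
}
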