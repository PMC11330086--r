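# 2-D projections for visualization and projected clustering. PCA runs in
# R (prcomp, with a deterministic sign convention); UMAP and t-SNE are
# delegated to the bundled Python helper, batched so that a tuning run
# pays the interpreter start-up once per proposal batch.

#' Projection specification
#'
#' @param method `"pca"`, `"umap"`, or `"tsne"`.
#' @param params `umap`: `min_dist` in (0, 1), `n_neighbors >= 2`;
#'   `tsne`: `perplexity`; `pca` has no parameters (2 leading components).
#' @param seed Seed for the stochastic methods.
#' @return A `projection_spec`.
#' @export
projection_spec <- function(method = c("pca", "umap", "tsne"),
                            params = list(), seed = 1L) {
  method <- match.arg(method)
  if (!is.null(params$min_dist) &&
      (params$min_dist <= 0 || params$min_dist >= 1))
    stop("min_dist must be in (0, 1)")
  if (!is.null(params$n_neighbors) && params$n_neighbors < 2)
    stop("n_neighbors must be >= 2")
  structure(list(method = method, params = params, seed = as.integer(seed)),
            class = "projection_spec")
}

pca_embed <- function(x) {
  pc <- stats::prcomp(x, center = TRUE, scale. = FALSE, rank. = 2L)
  emb <- pc$x[, seq_len(min(2L, ncol(pc$x))), drop = FALSE]
  if (ncol(emb) < 2L) emb <- cbind(emb, 0)
  # deterministic sign: largest-magnitude loading of each axis positive
  for (j in 1:2) {
    if (j <= ncol(pc$rotation)) {
      load <- pc$rotation[, j]
      if (load[which.max(abs(load))] < 0) emb[, j] <- -emb[, j]
    }
  }
  dimnames(emb) <- NULL
  emb
}

embed_batch <- function(x, method, params_list, seeds) {
  if (method == "pca") {
    emb <- pca_embed(x)
    return(replicate(length(params_list), emb, simplify = FALSE))
  }
  jobs <- lapply(seq_along(params_list), function(i)
    list(method = method, params = params_list[[i]],
         seed = seeds[[i]]))
  res <- run_chemtools("embed", list(X = unname(as.matrix(x)), jobs = jobs))
  lapply(res$embeddings, function(e)
    do.call(rbind, lapply(e, function(row) as.numeric(unlist(row)))))
}

#' Project points to 2-D
#'
#' Deterministic given the spec seed; the PCA embedding is the two
#' leading principal axes.
#'
#' @param fm Feature matrix (n >= 3; t-SNE additionally requires
#'   `n > 3 * perplexity`).
#' @param spec A [projection_spec()].
#' @return `n x 2` coordinate matrix.
#' @export
project_2d <- function(fm, spec) {
  stopifnot(inherits(spec, "projection_spec"))
  x <- fm_values(fm)
  n <- nrow(x)
  if (n < 3L) stop("projection requires at least 3 points")
  bump_counter("projection_runs")
  if (spec$method == "umap" && !is.null(spec$params$n_neighbors) &&
      spec$params$n_neighbors >= n)
    stop("n_neighbors must be smaller than the number of points")
  if (spec$method == "tsne") {
    perp <- spec$params$perplexity %||% 30
    if (n <= 3 * perp)
      stop("t-SNE requires n > 3 * perplexity")
  }
  embed_batch(x, spec$method, list(spec$params), list(spec$seed))[[1L]]
}
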