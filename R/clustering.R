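# Clustering algorithms and the silhouette objective. k-means and
# hierarchical clustering come from stats, k-medoids from cluster::pam;
# DBSCAN and HDBSCAN are implemented here (no R implementation is
# available among the package's dependencies). Cluster ids are 0-based
# integers with -1 denoting noise, matching the workflow's conventions.

#' Clustering specification
#'
#' @param method `"kmeans"`, `"kmedoids"`, `"hierarchical"`, `"dbscan"`,
#'   or `"hdbscan"`.
#' @param params Method parameters: `n_clusters` (k-means, k-medoids,
#'   hierarchical), `linkage` (`"single"`, `"complete"`, `"average"`) and
#'   `metric` (`"euclidean"`, `"manhattan"`) for hierarchical, `epsilon`
#'   and `min_samples` for DBSCAN, `min_cluster_size` for HDBSCAN.
#' @param seed Seed for stochastic methods (k-means restarts).
#' @return A `cluster_spec`.
#' @export
cluster_spec <- function(method = c("kmeans", "kmedoids", "hierarchical",
                                    "dbscan", "hdbscan"),
                         params = list(), seed = 1L) {
  method <- match.arg(method)
  if (!is.null(params$n_clusters) && params$n_clusters < 2L)
    stop("n_clusters must be >= 2")
  if (!is.null(params$epsilon) && params$epsilon <= 0)
    stop("epsilon must be > 0")
  structure(list(method = method, params = params, seed = as.integer(seed)),
            class = "cluster_spec")
}

#' Cluster a point matrix
#'
#' k-means and k-medoids produce exactly `n_clusters` clusters;
#' hierarchical clustering cuts its dendrogram (computed on a euclidean
#' or manhattan distance matrix with the chosen linkage) into
#' `n_clusters`; DBSCAN and HDBSCAN may label points as noise (`-1`).
#' Medoids are dataset points.
#'
#' @param points Numeric matrix (rows are observations).
#' @param spec A [cluster_spec()].
#' @return Integer vector of 0-based cluster ids, `-1` for noise.
#' @export
run_clustering <- function(points, spec) {
  stopifnot(inherits(spec, "cluster_spec"))
  x <- fm_values(points)
  n <- nrow(x)
  bump_counter("clustering_runs")
  p <- spec$params
  labels <- switch(spec$method,
    kmeans = {
      k <- p$n_clusters %||% stop("kmeans requires n_clusters")
      if (k > n) stop("n_clusters exceeds the number of points")
      set.seed(spec$seed)
      stats::kmeans(x, centers = k, nstart = 10L, iter.max = 100L)$cluster - 1L
    },
    kmedoids = {
      k <- p$n_clusters %||% stop("kmedoids requires n_clusters")
      if (k > n) stop("n_clusters exceeds the number of points")
      cluster::pam(x, k = k, pamonce = 5, cluster.only = TRUE) - 1L
    },
    hierarchical = {
      k <- p$n_clusters %||% stop("hierarchical requires n_clusters")
      metric <- match.arg(p$metric %||% "euclidean",
                          c("euclidean", "manhattan"))
      linkage <- match.arg(p$linkage %||% "average",
                           c("single", "complete", "average"))
      hc <- stats::hclust(stats::dist(x, method = metric), method = linkage)
      stats::cutree(hc, k = k) - 1L
    },
    dbscan = dbscan_labels(x, p$epsilon %||% stop("dbscan requires epsilon"),
                           p$min_samples %||% 5L),
    hdbscan = hdbscan_labels(x, p$min_cluster_size %||% 5L))
  as.integer(labels)
}

# ------------------------------------------------------------------ DBSCAN

dbscan_labels <- function(x, eps, min_samples) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  neighbors <- lapply(seq_len(n), function(i) which(d[i, ] <= eps))
  core <- vapply(neighbors, length, 0L) >= min_samples
  labels <- rep(-2L, n)  # -2 unvisited, -1 noise
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L || !core[i]) next
    cl <- cl + 1L
    labels[i] <- cl
    frontier <- setdiff(neighbors[[i]], i)
    while (length(frontier) > 0L) {
      j <- frontier[1L]
      frontier <- frontier[-1L]
      if (labels[j] == -2L || labels[j] == -1L) {
        newly <- labels[j] == -2L
        labels[j] <- cl
        if (core[j] && newly)
          frontier <- union(frontier, setdiff(neighbors[[j]], j))
      }
    }
  }
  labels[labels == -2L] <- -1L
  labels
}

# ----------------------------------------------------------------- HDBSCAN

# Minimal faithful HDBSCAN: mutual-reachability distances, minimum
# spanning tree, cluster hierarchy condensed by min_cluster_size, and
# excess-of-mass cluster extraction.
hdbscan_labels <- function(x, min_cluster_size, min_samples = NULL) {
  n <- nrow(x)
  min_cluster_size <- max(2L, as.integer(min_cluster_size))
  min_samples <- as.integer(min_samples %||% min_cluster_size)
  d <- as.matrix(stats::dist(x))
  k <- min(min_samples, n - 1L)
  # k-th nearest neighbor distance; sorted row includes the 0 self-distance
  core <- apply(d, 1L, function(row) sort(row)[k + 1L])
  mreach <- pmax(d, outer(core, rep(1, n)), outer(rep(1, n), core))
  diag(mreach) <- 0

  # Prim's MST on the mutual-reachability graph
  in_tree <- logical(n)
  in_tree[1L] <- TRUE
  best_w <- mreach[1L, ]
  best_from <- rep(1L, n)
  edges <- matrix(0, n - 1L, 3L)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best_w[cand])]
    edges[e, ] <- c(best_from[j], j, best_w[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & mreach[j, ] < best_w
    best_from[upd] <- j
    best_w[upd] <- mreach[j, upd]
  }
  edges <- edges[order(edges[, 3L]), , drop = FALSE]

  # single-linkage hierarchy via union-find, recording merge heights
  parent <- seq_len(2L * n - 1L)
  size <- c(rep(1L, n), rep(0L, n - 1L))
  birth <- numeric(2L * n - 1L)  # lambda at which each node forms
  children <- vector("list", 2L * n - 1L)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  nxt <- n
  heights <- numeric(n - 1L)
  for (e in seq_len(n - 1L)) {
    a <- find(edges[e, 1L])
    b <- find(edges[e, 2L])
    nxt <- nxt + 1L
    parent[a] <- nxt
    parent[b] <- nxt
    size[nxt] <- size[a] + size[b]
    children[[nxt]] <- c(a, b)
    heights[nxt - n] <- edges[e, 3L]
  }

  root <- 2L * n - 1L
  leaves_of <- function(node) {
    if (node <= n) return(node)
    unlist(lapply(children[[node]], leaves_of))
  }
  lambda_of <- function(node) {
    h <- if (node <= n) NA_real_ else heights[node - n]
    if (!is.na(h) && h > 0) 1 / h else Inf
  }
  # lambda at which each point falls out of its cluster: the height of
  # its immediate merge in the single-linkage hierarchy
  exit_height <- numeric(n)
  fill_exit <- function(node, current_h) {
    if (node <= n) {
      exit_height[node] <<- current_h
      return(invisible(NULL))
    }
    h <- heights[node - n]
    for (kk in children[[node]]) fill_exit(kk, h)
  }
  fill_exit(root, heights[root - n])
  exit_lambda <- ifelse(exit_height > 0, 1 / exit_height, Inf)

  # condensed tree: a cluster persists down a chain of merges while only
  # one side keeps >= min_cluster_size points (the small side falls out);
  # a node where both sides are big is a real split into two child
  # clusters; a chain that dissolves entirely is a condensed leaf cluster
  condense <- function(node_top, birth_lambda) {
    node <- node_top
    repeat {
      if (node <= n)
        return(list(top = node_top, birth = birth_lambda, cap = Inf,
                    children = list()))
      kids <- children[[node]]
      big <- kids[size[kids] >= min_cluster_size]
      if (length(big) == 2L) {
        lam <- lambda_of(node)
        return(list(top = node_top, birth = birth_lambda, cap = lam,
                    children = list(condense(big[1L], lam),
                                    condense(big[2L], lam))))
      } else if (length(big) == 1L) {
        node <- big
      } else {
        return(list(top = node_top, birth = birth_lambda, cap = Inf,
                    children = list()))
      }
    }
  }
  tree <- condense(root, 0)

  # excess-of-mass: stability(C) = sum over members of
  # (min(lambda_exit, lambda_split) - lambda_birth); a cluster is kept
  # when it is more stable than the sum of its descendants
  stability <- function(cl) {
    pts <- leaves_of(cl$top)
    lam <- pmin(exit_lambda[pts], cl$cap)
    sum(lam[is.finite(lam)] - cl$birth)
  }
  select <- function(cl) {
    if (length(cl$children) == 0L)
      return(list(total = stability(cl), chosen = list(cl)))
    ch <- lapply(cl$children, select)
    child_total <- sum(vapply(ch, `[[`, 0, "total"))
    own <- stability(cl)
    if (own > child_total)
      list(total = own, chosen = list(cl))
    else
      list(total = child_total,
           chosen = do.call(c, lapply(ch, `[[`, "chosen")))
  }

  if (length(tree$children) == 0L)
    return(rep(0L, n))  # no split of sufficient mass: one cluster
  # the root itself is never selected, mirroring the usual
  # single-cluster exclusion; selection starts at its children
  chosen <- do.call(c, lapply(tree$children, function(ch)
    select(ch)$chosen))
  labels <- rep(-1L, n)
  for (ci in seq_along(chosen))
    labels[leaves_of(chosen[[ci]]$top)] <- ci - 1L
  labels
}

# -------------------------------------------------------------- silhouette

#' Silhouette score
#'
#' Mean over points of `(b - a) / max(a, b)` where `a` is the mean
#' distance to the other members of the point's cluster (0 for singleton
#' clusters by convention) and `b` the minimum over other clusters of the
#' mean distance to that cluster's members. Euclidean metric. Noise
#' points (`label == -1`) are excluded before computation.
#'
#' @param points Numeric matrix.
#' @param labels Integer cluster ids, `-1` for noise.
#' @return Mean silhouette in \[-1, 1\].
#' @export
silhouette_score <- function(points, labels) {
  x <- fm_values(points)
  keep <- labels != -1L
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  ids <- unique(labels)
  if (length(ids) < 2L)
    stop("silhouette undefined: fewer than 2 clusters",
         call. = FALSE)
  d <- as.matrix(stats::dist(x))
  n <- nrow(x)
  # mean distance from every point to every cluster
  cluster_mean <- vapply(ids, function(cl) {
    members <- labels == cl
    rowSums(d[, members, drop = FALSE]) / sum(members)
  }, numeric(n))
  si <- vapply(seq_len(n), function(i) {
    own <- match(labels[i], ids)
    m <- sum(labels == labels[i])
    if (m == 1L) a <- 0
    else a <- cluster_mean[i, own] * m / (m - 1L)  # exclude self
    b <- min(cluster_mean[i, -own])
    if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }, 0)
  mean(si)
}
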