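# Tree-structured Parzen Estimator (TPE) hyperparameter search. After a
# random start-up phase, trials are split by objective value into a "good"
# top fraction and a "bad" remainder; Parzen (kernel) density estimates
# l(x) and g(x) are built per dimension over the two sets, candidate draws
# come from l, and the candidate maximizing l(x)/g(x) is proposed. Batched
# proposals (several draws from the same densities) let expensive
# objectives such as UMAP trials be evaluated together.

#' Hyperparameter search-space constructors
#'
#' `param_uniform` is a continuous range, `param_int` an integer range,
#' `param_choice` a categorical set. `search_space` bundles parameters
#' with a trial budget and seed.
#'
#' @param name Parameter name.
#' @param low,high Inclusive range bounds (`low < high`).
#' @param values Vector of categorical choices.
#' @param ... `tpe_param` objects.
#' @param n_trials Total number of trials (>= 1).
#' @param seed Master seed; per-trial seeds are derived from it.
#' @return `search_space` returns a `tpe_space`; the `param_*` helpers
#'   return `tpe_param` objects.
#' @export
param_uniform <- function(name, low, high) {
  stopifnot(low < high)
  structure(list(name = name, type = "uniform", low = low, high = high),
            class = "tpe_param")
}

#' @rdname param_uniform
#' @export
param_int <- function(name, low, high) {
  stopifnot(low < high)
  structure(list(name = name, type = "int", low = as.integer(low),
                 high = as.integer(high)), class = "tpe_param")
}

#' @rdname param_uniform
#' @export
param_choice <- function(name, values) {
  stopifnot(length(values) >= 1L)
  structure(list(name = name, type = "choice", values = values),
            class = "tpe_param")
}

#' @rdname param_uniform
#' @export
search_space <- function(..., n_trials = 50L, seed = 1L) {
  params <- list(...)
  if (length(params) == 1L && !inherits(params[[1L]], "tpe_param"))
    params <- params[[1L]]
  stopifnot(all(vapply(params, inherits, TRUE, "tpe_param")),
            n_trials >= 1L)
  names(params) <- vapply(params, `[[`, "", "name")
  structure(list(params = params, n_trials = as.integer(n_trials),
                 seed = as.integer(seed)), class = "tpe_space")
}

random_draw <- function(par) {
  switch(par$type,
    uniform = stats::runif(1L, par$low, par$high),
    int = sample(seq.int(par$low, par$high), 1L),
    choice = par$values[[sample.int(length(par$values), 1L)]])
}

# Parzen mixture density over observations, with a flat prior component
parzen_density <- function(obs, par, x) {
  width <- par$high - par$low
  bw <- max(1.06 * stats::sd(obs) * length(obs)^-0.2, width / 20,
            na.rm = TRUE)
  if (!is.finite(bw) || bw <= 0) bw <- width / 20
  prior <- 1 / width
  dens <- vapply(x, function(xi)
    mean(stats::dnorm(xi, mean = obs, sd = bw)), 0)
  (dens * length(obs) + prior) / (length(obs) + 1)
}

propose_one <- function(par, good_vals, bad_vals, n_candidates) {
  if (par$type == "choice") {
    k <- length(par$values)
    key <- vapply(par$values, function(v) paste0(v), "")
    gw <- (tabulate(match(vapply(good_vals, paste0, ""), key), k) + 1)
    bw <- (tabulate(match(vapply(bad_vals, paste0, ""), key), k) + 1)
    ratio <- (gw / sum(gw)) / (bw / sum(bw))
    idx <- sample.int(k, n_candidates, replace = TRUE, prob = gw)
    return(par$values[[idx[which.max(ratio[idx])]]])
  }
  good <- as.numeric(unlist(good_vals))
  bad <- as.numeric(unlist(bad_vals))
  width <- par$high - par$low
  bw <- max(1.06 * stats::sd(good) * length(good)^-0.2, width / 20,
            na.rm = TRUE)
  if (!is.finite(bw) || bw <= 0) bw <- width / 20
  centers <- good[sample.int(length(good), n_candidates, replace = TRUE)]
  cand <- stats::rnorm(n_candidates, centers, bw)
  cand <- pmin(pmax(cand, par$low), par$high)
  if (par$type == "int") cand <- round(cand)
  score <- parzen_density(good, par, cand) / parzen_density(bad, par, cand)
  out <- cand[which.max(score)]
  if (par$type == "int") out <- as.integer(out)
  out
}

tpe_propose <- function(space, history_params, history_values,
                        n_startup = 10L, gamma = 0.25,
                        n_candidates = 24L) {
  n <- length(history_values)
  draw <- list()
  if (n < n_startup) {
    for (par in space$params) draw[[par$name]] <- random_draw(par)
    return(draw)
  }
  ord <- order(history_values, decreasing = TRUE)
  n_good <- max(2L, ceiling(gamma * n))
  good_idx <- ord[seq_len(n_good)]
  bad_idx <- ord[-seq_len(n_good)]
  if (length(bad_idx) == 0L) bad_idx <- good_idx
  for (par in space$params) {
    gv <- lapply(history_params[good_idx], `[[`, par$name)
    bv <- lapply(history_params[bad_idx], `[[`, par$name)
    draw[[par$name]] <- propose_one(par, gv, bv, n_candidates)
  }
  draw
}

trial_seed <- function(master, i) {
  as.integer((as.double(master) * 1009 + i * 7919) %% 2147483647)
}

#' Run a TPE optimization
#'
#' Maximizes `objective_batch` over the space. The objective receives a
#' list of parameter sets (each a named list that also carries a derived
#' `.seed`) and returns one numeric value per set; degenerate trials
#' should be scored `-1` rather than raising.
#'
#' @param space A [search_space()].
#' @param objective_batch Function `list-of-params -> numeric vector`.
#' @param batch_size Number of proposals evaluated per density update.
#' @param n_startup Random trials before density-based proposals start.
#' @return List with `best_params`, `best_value`, `best_index`, and the
#'   complete `trials` data.frame (one row per trial, in evaluation
#'   order).
#' @export
tpe_optimize <- function(space, objective_batch, batch_size = 1L,
                         n_startup = 10L) {
  stopifnot(inherits(space, "tpe_space"))
  set.seed(space$seed)
  params_hist <- list()
  values_hist <- numeric(0)
  while (length(values_hist) < space$n_trials) {
    m <- min(batch_size, space$n_trials - length(values_hist))
    batch <- vector("list", m)
    for (j in seq_len(m)) {
      prop <- tpe_propose(space, params_hist, values_hist, n_startup)
      prop$.seed <- trial_seed(space$seed, length(values_hist) + j)
      batch[[j]] <- prop
    }
    vals <- objective_batch(batch)
    stopifnot(length(vals) == m)
    params_hist <- c(params_hist, batch)
    values_hist <- c(values_hist, vals)
  }
  best <- which.max(values_hist)
  rows <- lapply(seq_along(params_hist), function(i) {
    p <- params_hist[[i]]
    p$.value <- values_hist[i]
    as.data.frame(p, stringsAsFactors = FALSE)
  })
  list(best_params = params_hist[[best]], best_value = values_hist[best],
       best_index = best, trials = do.call(rbind, rows))
}
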