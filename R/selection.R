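# Supervised feature selection wrappers: recursive feature elimination
# (drop the 20% least important columns per iteration), a genetic
# algorithm over bit masks (tournament selection, uniform crossover,
# per-bit mutation), and simulated annealing (add/replace/remove moves
# with Metropolis acceptance and geometric cooling). All three score
# candidate subsets by cross-validated accuracy/AUC (classification) or
# R-squared (regression) and return the best subset ever seen.

new_selection_result <- function(selected, method, score_trace, final_score,
                                 metric) {
  stopifnot(length(selected) >= 1L)
  structure(list(selected_columns = selected, method = method,
                 score_trace = score_trace, final_score = final_score,
                 metric = metric),
            class = "chemgroup_selection")
}

#' @export
print.chemgroup_selection <- function(x, ...) {
  cat("<chemgroup_selection> ", x$method, ": ", length(x$selected_columns),
      " columns, ", x$metric, " = ", signif(x$final_score, 4), "\n", sep = "")
  invisible(x)
}

selection_metric <- function(learner) {
  if (learner$task == "classification") "auc" else "r2"
}

# memoising subset scorer shared by GA and SA
make_subset_scorer <- function(x, labels, learner, metric, cv_folds, seed) {
  cache <- new.env(parent = emptyenv())
  function(cols) {
    key <- paste(sort(cols), collapse = "\r")
    hit <- get0(key, envir = cache)
    if (!is.null(hit)) return(hit)
    s <- cv_score(learner, x[, cols, drop = FALSE], labels, metric,
                  k_folds = cv_folds, seed = seed)
    assign(key, s, envir = cache)
    s
  }
}

#' Recursive feature elimination
#'
#' Starting from all columns, each iteration refits the learner, ranks
#' columns by [learner_importance()], and drops the
#' `max(1, floor(0.2 * p))` least important ones (the ranking is refreshed
#' every iteration). The subset with the highest cross-validated AUC
#' (classification) or R-squared (regression) along the elimination path
#' is returned.
#'
#' @param fm Feature matrix.
#' @param labels Labels.
#' @param learner A [learner_spec()].
#' @param cv_folds Folds for the per-step score.
#' @param seed Seed for fold assignment and permutation importances.
#' @return A `chemgroup_selection` with the elimination trace
#'   (`step`, `n_columns`, `score`).
#' @export
rfe_select <- function(fm, labels, learner, cv_folds = 5L, seed = 1L) {
  x <- fm_values(fm)
  metric <- selection_metric(learner)
  cols <- colnames(x)
  if (length(cols) == 1L) {
    s <- cv_score(learner, x, labels, metric, k_folds = cv_folds,
                  seed = seed)
    return(new_selection_result(cols, "rfe",
                                data.frame(step = 1L, n_columns = 1L,
                                           score = s), s, metric))
  }
  trace <- list()
  best_cols <- cols
  best_score <- -Inf
  step <- 0L
  current <- cols
  repeat {
    step <- step + 1L
    xs <- x[, current, drop = FALSE]
    s <- cv_score(learner, xs, labels, metric, k_folds = cv_folds,
                  seed = seed)
    trace[[step]] <- data.frame(step = step, n_columns = length(current),
                                score = s)
    if (s > best_score) {
      best_score <- s
      best_cols <- current
    }
    if (length(current) == 1L) break
    fit <- fit_learner(learner, xs, labels)
    imp <- learner_importance(fit, xs, labels, seed = seed)
    n_drop <- max(1L, floor(0.2 * length(current)))
    current <- current[order(imp[current], decreasing = TRUE)]
    current <- current[seq_len(length(current) - n_drop)]
    current <- current[order(match(current, cols))]
  }
  new_selection_result(best_cols, "rfe", do.call(rbind, trace),
                       best_score, metric)
}

#' Genetic-algorithm configuration
#'
#' @param population_size Members per generation.
#' @param crossover_proba Probability a selected pair is recombined.
#' @param mutation_prob Per-bit mutation probability.
#' @param n_generations Number of generations (0 scores only the random
#'   initial population).
#' @param tournament_size Members per selection tournament.
#' @param cv_folds Folds for the fitness score.
#' @param seed Seed for the whole evolution.
#' @return A `ga_config`.
#' @export
ga_config <- function(population_size = 50L, crossover_proba = 0.5,
                      mutation_prob = 0.2, n_generations = 40L,
                      tournament_size = 3L, cv_folds = 5L, seed = 1L) {
  stopifnot(crossover_proba >= 0, crossover_proba <= 1,
            mutation_prob >= 0, mutation_prob <= 1,
            population_size >= 1L, tournament_size >= 1L, cv_folds >= 2L)
  structure(list(population_size = as.integer(population_size),
                 crossover_proba = crossover_proba,
                 mutation_prob = mutation_prob,
                 n_generations = as.integer(n_generations),
                 tournament_size = as.integer(tournament_size),
                 cv_folds = as.integer(cv_folds), seed = as.integer(seed)),
            class = "ga_config")
}

#' Genetic-algorithm feature selection
#'
#' Evolves a population of column bit-masks scored by cross-validated
#' accuracy-type fitness. Tournament selection picks parents, uniform
#' crossover recombines them with probability `crossover_proba`, each bit
#' mutates with probability `mutation_prob`, and the best-ever member is
#' kept (elitism), so the best-score trace is non-decreasing.
#'
#' @param fm Feature matrix.
#' @param labels Labels.
#' @param learner A [learner_spec()].
#' @param cfg A [ga_config()].
#' @return A `chemgroup_selection`; the trace holds the best-ever score
#'   per generation.
#' @export
ga_select <- function(fm, labels, learner, cfg = ga_config()) {
  stopifnot(inherits(cfg, "ga_config"))
  x <- fm_values(fm)
  p <- ncol(x)
  cols <- colnames(x)
  if (cfg$population_size < cfg$tournament_size)
    stop("population smaller than tournament size")
  metric <- selection_metric(learner)
  scorer <- make_subset_scorer(x, labels, learner, metric, cfg$cv_folds,
                               cfg$seed)
  set.seed(cfg$seed)
  random_mask <- function() {
    m <- stats::runif(p) < 0.5
    if (!any(m)) m[sample.int(p, 1L)] <- TRUE
    m
  }
  pop <- replicate(cfg$population_size, random_mask(), simplify = FALSE)
  fitness <- vapply(pop, function(m) scorer(cols[m]), 0)
  best_i <- which.max(fitness)
  best_mask <- pop[[best_i]]
  best_score <- fitness[best_i]
  trace <- data.frame(step = 0L, score = best_score)

  tournament <- function() {
    cand <- sample.int(cfg$population_size, cfg$tournament_size)
    cand[which.max(fitness[cand])]
  }
  gen <- 0L
  while (gen < cfg$n_generations) {
    gen <- gen + 1L
    newpop <- vector("list", cfg$population_size)
    for (i in seq_len(cfg$population_size)) {
      a <- pop[[tournament()]]
      if (stats::runif(1) < cfg$crossover_proba) {
        b <- pop[[tournament()]]
        take <- stats::runif(p) < 0.5
        child <- ifelse(take, a, b)
      } else {
        child <- a
      }
      flip <- stats::runif(p) < cfg$mutation_prob
      child <- xor(child, flip)
      if (!any(child)) child[sample.int(p, 1L)] <- TRUE
      newpop[[i]] <- child
    }
    pop <- newpop
    fitness <- vapply(pop, function(m) scorer(cols[m]), 0)
    gen_best <- which.max(fitness)
    if (fitness[gen_best] > best_score) {
      best_score <- fitness[gen_best]
      best_mask <- pop[[gen_best]]
    }
    trace <- rbind(trace, data.frame(step = gen, score = best_score))
  }
  new_selection_result(cols[best_mask], "ga", trace, best_score, metric)
}

#' Simulated-annealing configuration
#'
#' Defaults follow the published schedule: a random initial subset of 50%
#' of the columns, 3-fold cross-validated scoring, geometric cooling by
#' 0.95 per iteration, and termination after 50 iterations or once the
#' temperature drops below 0.01.
#'
#' @param init_fraction Fraction of columns in the initial subset.
#' @param cv_folds Folds for the score.
#' @param cooling_factor Geometric cooling factor in (0, 1).
#' @param max_iterations Iteration cap.
#' @param min_temperature Temperature floor.
#' @param initial_temperature Starting temperature.
#' @param seed Seed.
#' @return An `sa_config`.
#' @export
sa_config <- function(init_fraction = 0.5, cv_folds = 3L,
                      cooling_factor = 0.95, max_iterations = 50L,
                      min_temperature = 0.01, initial_temperature = 1.0,
                      seed = 1L) {
  stopifnot(cooling_factor > 0, cooling_factor < 1,
            init_fraction > 0, init_fraction <= 1)
  structure(list(init_fraction = init_fraction,
                 cv_folds = as.integer(cv_folds),
                 cooling_factor = cooling_factor,
                 max_iterations = as.integer(max_iterations),
                 min_temperature = min_temperature,
                 initial_temperature = initial_temperature,
                 seed = as.integer(seed)),
            class = "sa_config")
}

#' Simulated-annealing feature selection
#'
#' Starts from `ceiling(init_fraction * p)` random columns. Each iteration
#' proposes one move — add, replace, or remove a column, chosen uniformly
#' among the feasible moves — and scores it by cross-validation. Improved
#' scores are always accepted; worse ones with Metropolis probability
#' `exp((s_new - s_cur) / T)`. The temperature cools geometrically
#' (`T <- cooling_factor * T`) and the run stops at `max_iterations` or
#' when `T < min_temperature`. The best-ever subset is returned.
#'
#' @param fm Feature matrix with at least two columns.
#' @param labels Labels.
#' @param learner A [learner_spec()].
#' @param cfg An [sa_config()].
#' @return A `chemgroup_selection` with the per-iteration trace
#'   (`step`, `score`, `temperature`, `accepted`).
#' @export
sa_select <- function(fm, labels, learner, cfg = sa_config()) {
  stopifnot(inherits(cfg, "sa_config"))
  x <- fm_values(fm)
  p <- ncol(x)
  stopifnot(p >= 2L)
  cols <- colnames(x)
  metric <- selection_metric(learner)
  scorer <- make_subset_scorer(x, labels, learner, metric, cfg$cv_folds,
                               cfg$seed)
  set.seed(cfg$seed)
  current <- sample(cols, ceiling(cfg$init_fraction * p))
  cur_score <- scorer(current)
  best <- current
  best_score <- cur_score
  temp <- cfg$initial_temperature
  trace <- data.frame(step = 0L, score = cur_score, temperature = temp,
                      n_columns = length(current), accepted = TRUE)
  iter <- 0L
  while (iter < cfg$max_iterations && temp >= cfg$min_temperature) {
    iter <- iter + 1L
    outside <- setdiff(cols, current)
    moves <- c(if (length(outside) > 0L) "add",
               if (length(outside) > 0L && length(current) > 0L) "replace",
               if (length(current) > 1L) "remove")
    move <- sample(moves, 1L)
    proposal <- switch(move,
      add = c(current, sample(outside, 1L)),
      replace = c(setdiff(current, sample(current, 1L)),
                  sample(outside, 1L)),
      remove = setdiff(current, sample(current, 1L)))
    new_score <- scorer(proposal)
    accept <- new_score > cur_score ||
      stats::runif(1) < exp((new_score - cur_score) / temp)
    if (accept) {
      current <- proposal
      cur_score <- new_score
      if (cur_score > best_score) {
        best_score <- cur_score
        best <- current
      }
    }
    trace <- rbind(trace, data.frame(step = iter, score = cur_score,
                                     temperature = temp,
                                     n_columns = length(current),
                                     accepted = accept))
    temp <- cfg$cooling_factor * temp
  }
  new_selection_result(sort(best), "sa", trace, best_score, metric)
}
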