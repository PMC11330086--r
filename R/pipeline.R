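# End-to-end orchestration: one call runs input -> standardization ->
# descriptors -> filtering -> feature selection -> (SHAP-based or
# structure-based) tuned grouping -> interpretation, recording every
# option, seed, and stage result in the run manifest.

#' Pipeline configuration
#'
#' Assembles the per-stage options of a grouping run. Every argument has
#' the workflow's default; anything supplied is validated lightly here
#' and fully by the stage functions.
#'
#' @param descriptor List: `type` (`"fingerprint"` or `"descriptor"`),
#'   `family`/`radius`/`n_bits` for fingerprints, `set_name` and
#'   `scaling` (`"none"`, `"minmax"`, `"zscore"`, `"decimal"`) for
#'   continuous descriptors.
#' @param standardize Apply structure standardization (default `TRUE`).
#' @param filter List: `kind` (`"variance"`, `"correlation"`, `"none"`),
#'   `mode` (`"manual"` or `"auto"`), `threshold` (manual), `grid` and
#'   `cv_mode` (auto).
#' @param selection List: `method` (`"none"`, `"manual"`, `"rfe"`,
#'   `"ga"`, `"sa"`), `columns` (manual), `ga`/`sa` config lists,
#'   `cv_folds`.
#' @param learner List: `family`, `hyperparameters` for the supervised
#'   learner used by automated stages (default gradient-boosted trees).
#' @param grouping List: `mode` (`"unsupervised"` or `"shap"`),
#'   `cluster_method`, `projection_method`, `projected`, `n_trials`,
#'   and `k_range` (bounds of the tuned cluster count, default 2-25).
#' @param interpret List: `enabled`, `top_k`, `endpoint_description`.
#' @return A `chemgroup_config` list.
#' @export
grouping_config <- function(descriptor = list(), standardize = TRUE,
                            filter = list(), selection = list(),
                            learner = list(), grouping = list(),
                            interpret = list()) {
  cfg <- list(
    descriptor = utils::modifyList(
      list(type = "fingerprint", family = "morgan", radius = 3L,
           n_bits = 2048L, set_name = "compact", scaling = "minmax"),
      descriptor),
    standardize = isTRUE(standardize),
    filter = utils::modifyList(
      list(kind = "variance", mode = "manual", threshold = 0.05,
           grid = seq(0, 0.1, by = 0.01), cv_mode = "holdout_80_20"),
      filter),
    selection = utils::modifyList(
      list(method = "none", columns = NULL, cv_folds = 5L,
           ga = list(), sa = list()), selection),
    learner = utils::modifyList(
      list(family = "gradient_boosted_trees", hyperparameters = list()),
      learner),
    grouping = utils::modifyList(
      list(mode = "unsupervised", cluster_method = "kmeans",
           projection_method = "umap", projected = TRUE, n_trials = 50L,
           k_range = c(2L, 25L)),
      grouping),
    interpret = utils::modifyList(
      list(enabled = TRUE, top_k = 5L, endpoint_description = NULL),
      interpret))
  structure(cfg, class = "chemgroup_config")
}

pipeline_task <- function(ds) {
  if (ds$label_kind == "continuous") "regression" else "classification"
}

# tuning space for a pipeline run: the default ranges with the cluster
# count clamped to the configured k_range (and to n - 1)
pipeline_space <- function(gcfg, n, seed) {
  params <- cluster_param_space(gcfg$cluster_method, n)
  if (!is.null(gcfg$k_range)) {
    params <- lapply(params, function(p) {
      if (identical(p$name, "n_clusters"))
        param_int("n_clusters", max(2L, gcfg$k_range[1L]),
                  max(3L, min(gcfg$k_range[2L], n - 1L)))
      else p
    })
  }
  if (isTRUE(gcfg$projected))
    params <- c(params,
                projection_param_space(gcfg$projection_method, n))
  search_space(unname(params), n_trials = gcfg$n_trials, seed = seed)
}

#' Run the full grouping pipeline
#'
#' @param ds A `chemgroup_dataset` (from [read_dataset()] or a fixture
#'   generator).
#' @param config A [grouping_config()].
#' @param seed Master seed; stage seeds are derived from it and recorded
#'   in the manifest.
#' @return A `chemgroup_run`: the populated manifest plus the in-memory
#'   dataset, feature matrix, grouping, and interpretation.
#' @export
run_grouping_pipeline <- function(ds, config = grouping_config(),
                                  seed = 1L) {
  stopifnot(inherits(ds, "chemgroup_dataset"),
            inherits(config, "chemgroup_config"))
  seed <- as.integer(seed)
  manifest <- new_manifest(
    input = list(name = ds$meta$path %||% "in-memory",
                 format = ds$meta$format %||% "dataset",
                 label_kind = ds$label_kind,
                 label_column = ds$label_column,
                 label_map = ds$label_map),
    seed = seed)
  manifest$options <- unclass(config)

  chk <- integrity_check(ds)
  ds <- chk$dataset
  manifest <- manifest_set_stage(manifest, "integrity", list(
    n_retained = nrow(ds$records),
    removed = as.list(chk$removed)))

  if (config$standardize) {
    std <- standardize_dataset(ds)
    ds <- std$dataset
    manifest <- manifest_set_stage(manifest, "standardize", list(
      n_retained = nrow(ds$records),
      removed = as.list(std$removed),
      tautomer_scheme = ds$meta$standardization$tautomer_scheme,
      rdkit_version = ds$meta$standardization$rdkit_version))
  }
  manifest <- manifest_set_stage(manifest, "dataset", list(
    record_id = ds$records$record_id,
    smiles = ds$records$structure_text,
    label = ds$records$label))

  dcfg <- config$descriptor
  fm <- if (identical(dcfg$type, "fingerprint")) {
    compute_fingerprints(ds, fingerprint_spec(dcfg$family, dcfg$radius,
                                              dcfg$n_bits))
  } else {
    out <- compute_descriptors(ds, dcfg$set_name)
    if (!identical(dcfg$scaling, "none"))
      out <- scale_features(out, dcfg$scaling)
    out
  }
  manifest <- manifest_set_stage(manifest, "descriptors", list(
    config = dcfg, n_columns = ncol(fm$values),
    backend_version = fm$meta$rdkit_version,
    dropped_nonfinite = fm$meta$dropped_nonfinite,
    scaling = fm$scaling))

  labels <- ds$records$label
  labeled <- ds$label_kind != "none"
  task <- pipeline_task(ds)
  lrn <- if (labeled)
    learner_spec(config$learner$family, task,
                 config$learner$hyperparameters, seed = seed)

  fcfg <- config$filter
  if (!identical(fcfg$kind, "none")) {
    flt <- if (identical(fcfg$mode, "auto")) {
      if (!labeled)
        stop("automated threshold search requires a labeled dataset")
      auto_threshold_search(fm, labels, lrn, fcfg$kind, fcfg$grid,
                            fcfg$cv_mode, seed = seed)
    } else {
      switch(fcfg$kind,
             variance = variance_filter(fm, fcfg$threshold),
             correlation = correlation_filter(fm, fcfg$threshold))
    }
    fm <- apply_filter(fm, flt)
    manifest <- manifest_set_stage(manifest, "filter", list(
      kind = fcfg$kind, mode = fcfg$mode, threshold = flt$threshold,
      kept_columns = flt$kept_columns,
      n_removed = length(flt$removed_columns),
      search_trace = if (!is.null(flt$search_trace))
        as.list(flt$search_trace)))
  }

  scfg <- config$selection
  if (!identical(scfg$method, "none")) {
    sel <- switch(scfg$method,
      manual = {
        cols <- intersect(scfg$columns, colnames(fm$values))
        if (length(cols) == 0L) stop("manual selection kept no columns")
        new_selection_result(cols, "manual",
                             data.frame(step = 0L, score = NA_real_),
                             NA_real_, "none")
      },
      rfe = rfe_select(fm, labels, lrn, scfg$cv_folds, seed = seed),
      ga = ga_select(fm, labels, lrn,
                     do.call(ga_config, utils::modifyList(
                       list(seed = seed, cv_folds = scfg$cv_folds),
                       scfg$ga))),
      sa = sa_select(fm, labels, lrn,
                     do.call(sa_config, utils::modifyList(
                       list(seed = seed, cv_folds = scfg$cv_folds),
                       scfg$sa))))
    if (scfg$method != "manual" && !labeled)
      stop("supervised feature selection requires a labeled dataset")
    fm <- fm_replace(fm, fm_values(fm)[, sel$selected_columns,
                                       drop = FALSE])
    manifest <- manifest_set_stage(manifest, "selection", list(
      method = scfg$method, selected_columns = sel$selected_columns,
      final_score = sel$final_score, metric = sel$metric))
  }

  # final feature matrix kept in the manifest so the report bundle (and
  # view mode) can be rendered without recomputation
  manifest <- manifest_set_stage(manifest, "features", list(
    column_names = colnames(fm_values(fm)),
    values = unname(fm_values(fm))))

  gcfg <- config$grouping
  gspace <- pipeline_space(gcfg, nrow(fm_values(fm)), seed)
  grouping <- if (identical(gcfg$mode, "shap")) {
    if (!labeled) stop("SHAP-based grouping requires a labeled dataset")
    shap_supervised_grouping(fm, labels, lrn,
                             cluster_method = gcfg$cluster_method,
                             projection_method = gcfg$projection_method,
                             space = gspace, projected = gcfg$projected,
                             n_trials = gcfg$n_trials, seed = seed)
  } else {
    tune_grouping(fm, gcfg$cluster_method, gcfg$projection_method,
                  space = gspace, projected = gcfg$projected,
                  n_trials = gcfg$n_trials, seed = seed)
  }
  manifest <- manifest_set_stage(manifest, "grouping", list(
    mode = gcfg$mode, config = grouping$config,
    labels = grouping$labels, embedding = grouping$embedding,
    silhouette = grouping$silhouette,
    full_space_labels = grouping$full_space_labels,
    tuning_trace = as.list(grouping$tuning_trace)))

  interpretation <- NULL
  icfg <- config$interpret
  n_clusters <- length(setdiff(unique(grouping$labels), -1L))
  if (isTRUE(icfg$enabled) && n_clusters >= 2L) {
    interpretation <- interpret_clusters(
      fm, grouping$labels,
      learner_spec(config$learner$family, "classification",
                   config$learner$hyperparameters, seed = seed),
      top_k = icfg$top_k, seed = seed)
    summary_text <- summarize_interpretation(
      interpretation, endpoint_description = icfg$endpoint_description)
    manifest <- manifest_set_stage(manifest, "interpretation", list(
      top_k = icfg$top_k,
      rankings = lapply(interpretation$clusters, function(cl)
        as.list(cl$ranking)),
      summary_text = summary_text))
  }

  structure(list(manifest = manifest, dataset = ds, features = fm,
                 grouping = grouping, interpretation = interpretation),
            class = "chemgroup_run")
}

#' @export
print.chemgroup_run <- function(x, ...) {
  cat("<chemgroup_run>\n")
  print(x$grouping)
  invisible(x)
}
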