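# Report bundle and the three running modes over the manifest. The
# bundle is rendered from the manifest alone, so "view past results"
# performs zero recomputation; floats are written with 6 significant
# digits and stable ordering so re-rendering the same manifest is
# byte-identical.

format_numeric_df <- function(df) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]]))
      df[[j]] <- formatC(df[[j]], digits = 6, format = "g")
  }
  df
}

flatten_options <- function(x, prefix = "") {
  out <- list()
  for (nm in names(x)) {
    key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
    v <- x[[nm]]
    if (is.list(v)) {
      out <- c(out, flatten_options(v, key))
    } else {
      out[[key]] <- paste(format(v, digits = 6), collapse = ";")
    }
  }
  out
}

#' Write the downloadable report bundle
#'
#' Renders every output of a finished run from its manifest: the
#' manifest JSON itself, a parameters CSV, the grouping-results CSV
#' (record id, SMILES, 2-D coordinates, cluster), the descriptors CSV,
#' the removed-rows CSV, scatter and SHAP summary figures (SVG), a
#' Markdown summary, and an index CSV with a checksum per file.
#' Re-running on the same manifest overwrites identically.
#'
#' @param manifest A `chemgroup_manifest` with completed stages.
#' @param outdir Output directory (created if needed).
#' @param figures Render SVG figures (default `TRUE`).
#' @return Invisibly, the bundle index data.frame.
#' @export
write_results <- function(manifest, outdir, figures = TRUE) {
  stopifnot(inherits(manifest, "chemgroup_manifest"))
  st <- manifest$stages
  if (is.null(st$grouping)) stop("manifest has no grouping stage")
  if (!dir.exists(outdir) && !dir.create(outdir, recursive = TRUE))
    stop("cannot create output directory: ", outdir)
  files <- character(0)

  path <- file.path(outdir, "manifest.json")
  save_manifest(manifest, path)
  files <- c(files, "manifest.json")

  pars <- flatten_options(manifest$options)
  pars_df <- data.frame(parameter = names(pars),
                        value = unlist(pars, use.names = FALSE),
                        stringsAsFactors = FALSE)
  utils::write.csv(pars_df, file.path(outdir, "parameters.csv"),
                   row.names = FALSE)
  files <- c(files, "parameters.csv")

  emb <- st$grouping$embedding
  grp <- data.frame(record_id = unlist(st$dataset$record_id),
                    SMILES = unlist(st$dataset$smiles),
                    x = emb[, 1L], y = emb[, 2L],
                    cluster = unlist(st$grouping$labels),
                    stringsAsFactors = FALSE)
  if (!is.null(st$dataset$label) &&
      !all(is.na(unlist(st$dataset$label))))
    grp$label <- unlist(st$dataset$label)
  utils::write.csv(format_numeric_df(grp),
                   file.path(outdir, "grouping_results.csv"),
                   row.names = FALSE, quote = FALSE)
  files <- c(files, "grouping_results.csv")

  if (!is.null(st$features)) {
    feat <- as.data.frame(st$features$values)
    names(feat) <- unlist(st$features$column_names)
    feat <- cbind(record_id = unlist(st$dataset$record_id), feat)
    utils::write.csv(format_numeric_df(feat),
                     file.path(outdir, "descriptors.csv"),
                     row.names = FALSE, quote = FALSE)
    files <- c(files, "descriptors.csv")
  }

  removed <- data.frame(source_index = integer(0), reason = character(0))
  for (stage in c("integrity", "standardize")) {
    r <- st[[stage]]$removed
    if (!is.null(r) && length(r$source_index))
      removed <- rbind(removed,
                       data.frame(source_index = unlist(r$source_index),
                                  reason = unlist(r$reason)))
  }
  removed <- removed[order(removed$source_index), , drop = FALSE]
  utils::write.csv(removed, file.path(outdir, "removed_rows.csv"),
                   row.names = FALSE)
  files <- c(files, "removed_rows.csv")

  if (figures) {
    files <- c(files, render_scatter_svg(st, outdir))
    if (!is.null(st$interpretation))
      files <- c(files, render_shap_summary_svg(st, outdir))
  }

  summary_lines <- c(
    "# Grouping run summary", "",
    paste0("- input: ", manifest$input$name, " (",
           manifest$input$format, ", labels: ",
           manifest$input$label_kind, ")"),
    paste0("- retained records: ", length(unlist(st$dataset$record_id))),
    paste0("- grouping mode: ", st$grouping$mode, ", clusterer: ",
           st$grouping$config$cluster_method, ", projection: ",
           st$grouping$config$projection_method),
    paste0("- clusters: ",
           length(setdiff(unique(unlist(st$grouping$labels)), -1L)),
           ", silhouette: ",
           formatC(st$grouping$silhouette, digits = 6, format = "g")))
  if (!is.null(st$interpretation$summary_text))
    summary_lines <- c(summary_lines, "",
                       unlist(strsplit(st$interpretation$summary_text,
                                       "\n")))
  writeLines(summary_lines, file.path(outdir, "summary.md"))
  files <- c(files, "summary.md")

  index <- data.frame(
    file = files,
    md5 = unname(tools::md5sum(file.path(outdir, files))),
    stringsAsFactors = FALSE)
  utils::write.csv(index, file.path(outdir, "index.csv"),
                   row.names = FALSE)
  invisible(index)
}

render_scatter_svg <- function(st, outdir) {
  emb <- st$grouping$embedding
  df <- data.frame(x = emb[, 1L], y = emb[, 2L],
                   cluster = factor(unlist(st$grouping$labels)))
  lab <- unlist(st$dataset$label)
  shaped <- !is.null(lab) && !all(is.na(lab)) &&
    length(unique(lab[!is.na(lab)])) <= 6
  if (shaped) df$label <- factor(lab)
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                         colour = .data$cluster)) +
    (if (shaped) ggplot2::geom_point(ggplot2::aes(shape = .data$label),
                                     size = 2)
     else ggplot2::geom_point(size = 2)) +
    ggplot2::labs(x = "dim 1", y = "dim 2") +
    ggplot2::theme_minimal()
  path <- file.path(outdir, "scatter.svg")
  grDevices::svg(path, width = 7, height = 5)
  print(gp)
  grDevices::dev.off()
  "scatter.svg"
}

render_shap_summary_svg <- function(st, outdir) {
  ranks <- st$interpretation$rankings
  dfs <- lapply(names(ranks), function(nm) {
    r <- ranks[[nm]]
    k <- min(st$interpretation$top_k %||% 5L,
             length(unlist(r$descriptor)))
    data.frame(cluster = nm,
               descriptor = unlist(r$descriptor)[seq_len(k)],
               mean_abs_shap = unlist(r$mean_abs_shap)[seq_len(k)],
               direction = unlist(r$direction)[seq_len(k)],
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, dfs)
  gp <- ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_abs_shap,
    y = stats::reorder(.data$descriptor, .data$mean_abs_shap),
    fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~cluster, scales = "free_y") +
    ggplot2::labs(x = "mean |SHAP|", y = NULL) +
    ggplot2::theme_minimal()
  path <- file.path(outdir, "shap_summary.svg")
  grDevices::svg(path, width = 8, height = 6)
  print(gp)
  grDevices::dev.off()
  "shap_summary.svg"
}

#' Replay or view a past run
#'
#' `mode = "view"` re-renders nothing and recomputes nothing: it simply
#' validates the manifest and returns it for [write_results()]. `mode =
#' "rerun"` applies all stored options, selected thresholds/columns, and
#' tuned hyperparameters (search stages are skipped in favor of their
#' stored outcomes) to a new dataset with the stored seeds, and returns
#' the manifest of the new run.
#'
#' @param manifest A `chemgroup_manifest`.
#' @param new_dataset A `chemgroup_dataset` (required for rerun mode).
#' @param mode `"rerun"` or `"view"`.
#' @return A `chemgroup_manifest` (for view, the input manifest; for
#'   rerun, the manifest of the re-executed run).
#' @export
replay_from_manifest <- function(manifest, new_dataset = NULL,
                                 mode = c("rerun", "view")) {
  mode <- match.arg(mode)
  stopifnot(inherits(manifest, "chemgroup_manifest"))
  st <- manifest$stages
  if (mode == "view") {
    if (is.null(st$grouping))
      stop("manifest has no stored grouping results to view")
    return(manifest)
  }
  if (is.null(new_dataset))
    stop("rerun mode requires a dataset")
  stopifnot(inherits(new_dataset, "chemgroup_dataset"))
  opts <- manifest$options
  supervised <- !identical(manifest$input$label_kind, "none") &&
    (identical(opts$filter$mode, "auto") ||
     !opts$selection$method %in% c("none", "manual") ||
     identical(opts$grouping$mode, "shap"))
  if (supervised && new_dataset$label_kind == "none")
    stop("manifest records a supervised run but the dataset is unlabeled")

  cfg <- grouping_config(
    descriptor = opts$descriptor,
    standardize = isTRUE(opts$standardize),
    filter = utils::modifyList(opts$filter, list(
      mode = "manual",
      threshold = st$filter$threshold %||% opts$filter$threshold)),
    selection = if (!is.null(st$selection)) list(
      method = "manual",
      columns = unlist(st$selection$selected_columns)) else
        list(method = "none"),
    learner = opts$learner,
    grouping = opts$grouping,
    interpret = opts$interpret)
  if (is.null(st$filter)) cfg$filter$kind <- "none"

  run <- replay_run(new_dataset, cfg, manifest)
  run$manifest
}

# rerun without re-searching: fixed filter/selection via cfg, and the
# stored grouping hyperparameters applied directly (no tuning)
replay_run <- function(ds, cfg, manifest) {
  gst <- manifest$stages$grouping
  gcfg_params <- gst$config
  seed <- manifest$seed
  chk <- integrity_check(ds)
  ds <- chk$dataset
  if (isTRUE(cfg$standardize)) ds <- standardize_dataset(ds)$dataset

  dcfg <- cfg$descriptor
  fm <- if (identical(dcfg$type, "fingerprint")) {
    compute_fingerprints(ds, fingerprint_spec(dcfg$family, dcfg$radius,
                                              dcfg$n_bits))
  } else {
    out <- compute_descriptors(ds, dcfg$set_name)
    if (!identical(dcfg$scaling, "none"))
      out <- scale_features(out, dcfg$scaling)
    out
  }
  if (!identical(cfg$filter$kind, "none")) {
    flt <- switch(cfg$filter$kind,
                  variance = variance_filter(fm, cfg$filter$threshold),
                  correlation = correlation_filter(fm,
                                                   cfg$filter$threshold))
    fm <- apply_filter(fm, flt)
  }
  if (identical(cfg$selection$method, "manual")) {
    cols <- intersect(cfg$selection$columns, colnames(fm_values(fm)))
    fm <- fm_replace(fm, fm_values(fm)[, cols, drop = FALSE])
  }

  x <- fm_values(fm)
  if (identical(manifest$options$grouping$mode, "shap")) {
    lrn <- learner_spec(cfg$learner$family, pipeline_task(ds),
                        cfg$learner$hyperparameters, seed = seed)
    fitted <- fit_learner(lrn, x, ds$records$label)
    x <- compute_shap(fitted, x, seed = seed)$values
  }
  trial_seed <- gcfg_params$seed %||% seed
  pr_params <- gcfg_params$projection_params
  if (length(pr_params) == 0L) pr_params <- list()
  emb <- project_2d(x, projection_spec(gcfg_params$projection_method,
                                       pr_params, seed = trial_seed))
  # final labels always come from the 2-D embedding (in non-projected
  # tuning, the returned labels are the stage-2 embedding clustering)
  points <- emb
  labels <- run_clustering(points, cluster_spec(
    gcfg_params$cluster_method, gcfg_params$cluster_params,
    seed = trial_seed))
  sil <- tryCatch(silhouette_score(points, labels), error = function(e)
    NA_real_)

  m2 <- new_manifest(input = manifest$input, seed = seed)
  m2$options <- manifest$options
  m2$options$replayed <- TRUE
  m2 <- manifest_set_stage(m2, "dataset", list(
    record_id = ds$records$record_id,
    smiles = ds$records$structure_text,
    label = ds$records$label))
  m2 <- manifest_set_stage(m2, "features", list(
    column_names = colnames(fm_values(fm)),
    values = unname(fm_values(fm))))
  m2 <- manifest_set_stage(m2, "grouping", list(
    mode = manifest$options$grouping$mode, config = gcfg_params,
    labels = as.integer(labels), embedding = emb, silhouette = sil))
  list(manifest = m2, dataset = ds, features = fm,
       labels = labels, embedding = emb)
}
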