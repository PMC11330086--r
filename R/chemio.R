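# Dataset input, integrity checking, exploratory summaries, and the run
# manifest. A dataset is a data.frame of molecule records plus label
# metadata; the manifest is a schema-versioned JSON document capturing every
# option, seed, and stage result of a run so it can be replayed or viewed
# without recomputation.

MANIFEST_SCHEMA_VERSION <- 1L

new_dataset <- function(records, label_kind = "none", label_column = NULL,
                        label_map = NULL, meta = list()) {
  stopifnot(is.data.frame(records))
  structure(list(records = records, label_kind = label_kind,
                 label_column = label_column, label_map = label_map,
                 removed = NULL, meta = meta),
            class = "chemgroup_dataset")
}

#' @export
print.chemgroup_dataset <- function(x, ...) {
  cat("<chemgroup_dataset> ", nrow(x$records), " records, labels: ",
      x$label_kind, "\n", sep = "")
  invisible(x)
}

label_kinds <- c("none", "binary", "multiclass", "continuous")

coerce_labels <- function(values, label_kind, label_column = "label") {
  values <- as.character(values)
  values[!is.na(values) & !nzchar(trimws(values))] <- NA_character_
  if (label_kind == "continuous") {
    out <- suppressWarnings(as.numeric(values))
    bad <- !is.na(values) & is.na(out)
    if (any(bad)) stop("label column '", label_column,
                       "' has values not coercible to continuous")
    return(list(labels = out, map = NULL))
  }
  lev <- sort(unique(values[!is.na(values)]))
  if (label_kind == "binary") {
    if (length(lev) > 2) stop("binary label column '", label_column,
                              "' has ", length(lev), " distinct values")
    if (all(lev %in% c("0", "1"))) lev <- c("0", "1")
    map <- stats::setNames(seq_along(lev) - 1L, lev)
    out <- unname(map[values])
    return(list(labels = as.integer(out), map = as.list(map)))
  }
  if (label_kind == "multiclass") {
    map <- stats::setNames(seq_along(lev) - 1L, lev)
    return(list(labels = as.integer(unname(map[values])),
                map = as.list(map)))
  }
  list(labels = rep(NA_integer_, length(values)), map = NULL)
}

#' Read a chemical dataset
#'
#' Reads structures (and optionally activity labels) from SDF, SMILES
#' (one structure per line, optional tab-separated identifier), CSV, or
#' XLSX. CSV/XLSX files must contain a SMILES column, found by exact
#' case-insensitive name match (`"SMILES"`) or named via `smiles_column`;
#' silent guessing of other columns is deliberately not attempted. Each
#' input record becomes one molecule record whose parse status is assigned
#' by attempting to parse the structure with RDKit.
#'
#' @param path Input file.
#' @param format One of `"sdf"`, `"smiles"`, `"csv"`, `"xlsx"`, or
#'   `"auto"` (from the file extension).
#' @param label_column Name of the label column (CSV/XLSX) or SDF property;
#'   required when `label_kind != "none"`.
#' @param label_kind `"none"`, `"binary"`, `"multiclass"`, or
#'   `"continuous"`. Binary labels may be `{0,1}` or any two distinct
#'   strings, which are mapped to 0/1 by sorted order (the mapping is kept
#'   with the dataset and recorded in the run manifest).
#' @param smiles_column Explicit structure column for CSV/XLSX when no
#'   column is named `SMILES`.
#' @return A `chemgroup_dataset` with one record per input row; records
#'   that failed to parse are retained with `parse_ok = FALSE` until
#'   [integrity_check()] removes them.
#' @export
read_dataset <- function(path, format = "auto", label_column = NULL,
                         label_kind = "none", smiles_column = NULL) {
  label_kind <- match.arg(label_kind, label_kinds)
  if (!file.exists(path)) stop("input file not found: ", path)
  if (label_kind != "none" && is.null(label_column))
    stop("label_column is required when label_kind != 'none'")
  if (identical(format, "auto")) {
    format <- switch(tolower(tools::file_ext(path)),
                     sdf = "sdf", smi = "smiles", smiles = "smiles",
                     txt = "smiles", csv = "csv", xlsx = "xlsx",
                     stop("cannot infer format from extension: ", path))
  }
  format <- match.arg(format, c("sdf", "smiles", "csv", "xlsx"))

  raw_labels <- NULL
  meta <- list(path = basename(path), format = format)

  if (format == "sdf") {
    res <- run_chemtools("parse_sdf",
                         list(path = normalizePath(path),
                              label_property = label_column))
    if (length(res$records) == 0) stop("empty file: ", path)
    recs <- res$records
    smiles <- vapply(recs, function(r) r$smiles %||% NA_character_, "")
    parse_ok <- vapply(recs, function(r) isTRUE(r$parse_ok), TRUE)
    raw_labels <- vapply(recs, function(r) {
      v <- r$label
      if (is.null(v)) NA_character_ else as.character(v)
    }, "")
    meta$rdkit_version <- res$rdkit_version
  } else {
    if (format == "smiles") {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      if (length(lines) == 0) stop("empty file: ", path)
      parts <- strsplit(lines, "\t", fixed = TRUE)
      input_smiles <- vapply(parts, `[[`, "", 1L)
      if (!is.null(label_column))
        stop("the SMILES line format carries no label column; ",
             "use CSV, XLSX or SDF for labeled data")
    } else {
      tab <- if (format == "csv") {
        utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
      } else {
        if (!requireNamespace("readxl", quietly = TRUE))
          stop("reading xlsx requires the readxl package")
        as.data.frame(readxl::read_xlsx(path), check.names = FALSE)
      }
      if (nrow(tab) == 0) stop("empty file: ", path)
      smi_col <- smiles_column
      if (is.null(smi_col)) {
        hit <- which(tolower(names(tab)) == "smiles")
        if (length(hit) == 0)
          stop("no structure column: no column named 'SMILES' in ", path,
               "; pass smiles_column explicitly")
        smi_col <- names(tab)[hit[1L]]
      } else if (!smi_col %in% names(tab)) {
        stop("no structure column: '", smi_col, "' not present in ", path)
      }
      input_smiles <- as.character(tab[[smi_col]])
      if (!is.null(label_column)) {
        if (!label_column %in% names(tab))
          stop("label column '", label_column, "' not present in ", path)
        raw_labels <- as.character(tab[[label_column]])
      }
    }
    input_smiles[is.na(input_smiles)] <- ""
    res <- run_chemtools("parse_smiles", list(smiles = as.list(input_smiles)))
    recs <- res$records
    smiles <- vapply(recs, function(r) r$smiles %||% NA_character_, "")
    parse_ok <- vapply(recs, function(r) isTRUE(r$parse_ok), TRUE)
    meta$rdkit_version <- res$rdkit_version
  }

  n <- length(smiles)
  lab <- if (label_kind == "none") {
    list(labels = rep(NA, n), map = NULL)
  } else {
    coerce_labels(raw_labels, label_kind, label_column)
  }
  records <- data.frame(
    record_id = sprintf("rec_%05d", seq_len(n) - 1L),
    source_index = seq_len(n) - 1L,
    structure_text = smiles,
    label = lab$labels,
    parse_ok = parse_ok,
    stringsAsFactors = FALSE)
  new_dataset(records, label_kind = label_kind, label_column = label_column,
              label_map = lab$map, meta = meta)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Remove unreadable structures and missing values
#'
#' Retains only records whose structure parsed and (for labeled datasets)
#' whose label is present; every removal is enumerated with a reason. No
#' imputation is performed.
#'
#' @param ds A `chemgroup_dataset`.
#' @return A list with `dataset` (cleaned, removal report attached) and
#'   `removed`, a data.frame of `(source_index, reason)` rows where reason
#'   is `unreadable_structure` or `missing_value`.
#' @export
integrity_check <- function(ds) {
  stopifnot(inherits(ds, "chemgroup_dataset"))
  rec <- ds$records
  unreadable <- !rec$parse_ok | is.na(rec$structure_text)
  missing <- !unreadable & ds$label_kind != "none" & is.na(rec$label)
  removed <- data.frame(
    source_index = c(rec$source_index[unreadable], rec$source_index[missing]),
    reason = c(rep("unreadable_structure", sum(unreadable)),
               rep("missing_value", sum(missing))),
    stringsAsFactors = FALSE)
  removed <- removed[order(removed$source_index), , drop = FALSE]
  rownames(removed) <- NULL
  keep <- !unreadable & !missing
  if (!any(keep)) stop("empty dataset after integrity check")
  out <- ds
  out$records <- rec[keep, , drop = FALSE]
  rownames(out$records) <- NULL
  out$removed <- removed
  list(dataset = out, removed = removed)
}

#' Exploratory summary of a checked dataset
#'
#' Counts retained/removed records and tabulates labels: class counts for
#' binary/multiclass labels, Sturges-binned histogram counts for continuous
#' labels.
#'
#' @param ds A `chemgroup_dataset`, normally after [integrity_check()].
#' @return A list of class `chemgroup_summary`.
#' @export
summarize_dataset <- function(ds) {
  stopifnot(inherits(ds, "chemgroup_dataset"))
  removed <- ds$removed
  n_unreadable <- if (is.null(removed)) 0L else
    sum(removed$reason == "unreadable_structure")
  n_missing <- if (is.null(removed)) 0L else
    sum(removed$reason == "missing_value")
  out <- list(n_retained = nrow(ds$records), n_unreadable = n_unreadable,
              n_missing = n_missing, label_kind = ds$label_kind)
  if (ds$label_kind %in% c("binary", "multiclass")) {
    counts <- table(ds$records$label)
    out$class_counts <- stats::setNames(as.integer(counts), names(counts))
  } else if (ds$label_kind == "continuous") {
    h <- graphics::hist(ds$records$label, breaks = "Sturges", plot = FALSE)
    out$histogram <- list(breaks = h$breaks, counts = h$counts)
  }
  structure(out, class = "chemgroup_summary")
}

#' @export
print.chemgroup_summary <- function(x, ...) {
  cat("<chemgroup_summary> retained:", x$n_retained,
      " unreadable:", x$n_unreadable, " missing:", x$n_missing, "\n")
  if (!is.null(x$class_counts)) {
    cat("  class counts:",
        paste(names(x$class_counts), x$class_counts, sep = ":",
              collapse = "  "), "\n")
  }
  invisible(x)
}

# ------------------------------------------------------------- manifests

#' Create an empty run manifest
#'
#' The manifest is the complete machine-readable record of a run: input
#' descriptor, every chosen option and hyperparameter per stage, all
#' seeds, and stage results. It round-trips losslessly through
#' [save_manifest()] / [load_manifest()] and is sufficient to replay a run
#' ([replay_from_manifest()]) or re-render its outputs without
#' recomputation.
#'
#' @param input Named list describing the input (name, format, label
#'   settings).
#' @param seed Master seed of the run.
#' @return A `chemgroup_manifest`.
#' @export
new_manifest <- function(input = list(), seed = 1L) {
  structure(list(schema_version = MANIFEST_SCHEMA_VERSION,
                 input = input,
                 seed = as.integer(seed),
                 options = list(),
                 stages = list()),
            class = "chemgroup_manifest")
}

manifest_set_stage <- function(m, name, value) {
  m$stages[[name]] <- value
  m
}

#' @export
print.chemgroup_manifest <- function(x, ...) {
  cat("<chemgroup_manifest> schema", x$schema_version, "- stages:",
      paste(names(x$stages), collapse = ", "), "\n")
  invisible(x)
}

#' Save / load a run manifest
#'
#' Manifests are stored as a single schema-versioned JSON document.
#' `load_manifest(save_manifest(m))` reproduces `m` field by field.
#'
#' @param m A `chemgroup_manifest`.
#' @param path File path of the manifest JSON.
#' @return `save_manifest` returns `path` invisibly; `load_manifest`
#'   returns the manifest.
#' @export
save_manifest <- function(m, path) {
  stopifnot(inherits(m, "chemgroup_manifest"))
  jsonlite::write_json(canonicalize_manifest(unclass(m)), path,
                       auto_unbox = TRUE, digits = NA, null = "null",
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname save_manifest
#' @export
load_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest file not found: ", path)
  m <- tryCatch(
    jsonlite::read_json(path, simplifyVector = TRUE,
                        simplifyDataFrame = FALSE, simplifyMatrix = TRUE),
    error = function(e) stop("malformed manifest file: ",
                             conditionMessage(e), call. = FALSE))
  if (is.null(m$schema_version) ||
      m$schema_version != MANIFEST_SCHEMA_VERSION)
    stop("version-incompatible manifest (schema ",
         m$schema_version %||% "missing", ", expected ",
         MANIFEST_SCHEMA_VERSION, ")")
  m <- canonicalize_manifest(m)
  structure(m, class = "chemgroup_manifest")
}

# JSON has one number type and one empty-array form; canonicalizing
# integers to double and zero-length vectors to empty lists before
# comparison/serialization makes the round trip exact.
canonicalize_manifest <- function(x) {
  if (is.list(x)) return(lapply(x, canonicalize_manifest))
  if (length(x) == 0L && !is.null(x)) return(list())
  if (is.integer(x)) {
    y <- as.double(x)
    attributes(y) <- attributes(x)
    return(y)
  }
  x
}

# ---------------------------------------------------- recomputation counters

the_counters <- new.env(parent = emptyenv())

bump_counter <- function(name) {
  cur <- get0(name, envir = the_counters, ifnotfound = 0L)
  assign(name, cur + 1L, envir = the_counters)
  invisible(NULL)
}

#' Computation-stage counters
#'
#' Counts of expensive computations (descriptor calculation, clustering,
#' projection, tuning) since the last reset. Used to assert that the
#' manifest "view" mode performs zero recomputation.
#'
#' @return Named integer vector of counts.
#' @export
counter_snapshot <- function() {
  nm <- ls(the_counters)
  stats::setNames(vapply(nm, get, 0L, envir = the_counters), nm)
}

#' @rdname counter_snapshot
#' @export
reset_counters <- function() {
  rm(list = ls(the_counters), envir = the_counters)
  invisible(NULL)
}
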