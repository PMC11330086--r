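# Feature matrices: binary fingerprints (Morgan, FeatMorgan, MACCS) and
# continuous 2-D descriptor sets, plus the three scaling methods
# (min-max, z-score, decimal scaling). Scaling parameters are stored with
# the matrix so the identical transform can be applied to new data.

new_feature_matrix <- function(values, kind, scaling = NULL, meta = list()) {
  stopifnot(is.matrix(values))
  structure(list(values = values, kind = kind,
                 scaling = scaling %||% list(method = "none"),
                 meta = meta),
            class = "chemgroup_features")
}

#' @export
print.chemgroup_features <- function(x, ...) {
  cat("<chemgroup_features> ", nrow(x$values), " x ", ncol(x$values), " ",
      x$kind, " (scaling: ", x$scaling$method, ")\n", sep = "")
  invisible(x)
}

# accept either a chemgroup_features object or a plain numeric matrix
fm_values <- function(fm) {
  if (inherits(fm, "chemgroup_features")) fm$values
  else if (is.matrix(fm)) fm
  else stop("expected a feature matrix")
}

fm_replace <- function(fm, values) {
  if (inherits(fm, "chemgroup_features")) {
    fm$values <- values
    fm
  } else values
}

#' Fingerprint specification
#'
#' @param family `"morgan"`, `"feat_morgan"` (circular fingerprint with
#'   pharmacophoric feature invariants), or `"maccs"` (166 keys).
#' @param radius Circular-fingerprint radius (ignored for MACCS).
#' @param n_bits Bit-vector width (ignored for MACCS).
#' @return A `fingerprint_spec` list.
#' @export
fingerprint_spec <- function(family = c("morgan", "feat_morgan", "maccs"),
                             radius = 3L, n_bits = 2048L) {
  family <- match.arg(family)
  stopifnot(radius >= 0, n_bits >= 1)
  structure(list(family = family, radius = as.integer(radius),
                 n_bits = as.integer(n_bits)), class = "fingerprint_spec")
}

#' Compute binary fingerprints
#'
#' One row per retained record; Morgan/FeatMorgan width is `n_bits`, MACCS
#' width is the fixed 166 informative keys (the placeholder implementation
#' bit 0 is stripped). Identical structures give identical rows. Records
#' that fail fingerprinting are dropped and listed in the result metadata.
#'
#' @param ds A standardized `chemgroup_dataset`.
#' @param spec A [fingerprint_spec()].
#' @return A binary `chemgroup_features` matrix.
#' @export
compute_fingerprints <- function(ds, spec = fingerprint_spec()) {
  stopifnot(inherits(ds, "chemgroup_dataset"),
            inherits(spec, "fingerprint_spec"))
  bump_counter("descriptor_computations")
  res <- run_chemtools("fingerprints",
                       list(smiles = as.list(ds$records$structure_text),
                            family = spec$family, radius = spec$radius,
                            n_bits = spec$n_bits))
  bits <- res$bits
  failed <- as.integer(unlist(res$failed))
  ok <- vapply(bits, function(b) !is.null(b), TRUE)
  rows <- lapply(bits[ok], function(b)
    as.integer(strsplit(b, "", fixed = TRUE)[[1L]]))
  values <- do.call(rbind, rows)
  width <- if (spec$family == "maccs") 166L else spec$n_bits
  stopifnot(ncol(values) == width)
  colnames(values) <- if (spec$family == "maccs") {
    sprintf("maccs_%03d", seq_len(width))
  } else {
    sprintf("bit_%04d", seq_len(width) - 1L)
  }
  rownames(values) <- ds$records$record_id[ok]
  new_feature_matrix(values, kind = "binary",
                     meta = list(spec = unclass(spec),
                                 failed_records =
                                   ds$records$record_id[failed + 1L],
                                 rdkit_version = res$rdkit_version))
}

descriptor_set_names <- c(compact = "compact", compact_119 = "compact",
                          extended = "extended", extended_1613 = "extended")

#' Compute continuous 2-D descriptors
#'
#' Computes the pinned 119-descriptor compact set (`"compact"`) or the
#' complete RDKit 2-D descriptor collection (`"extended"`). Columns
#' containing any non-finite or missing value across the dataset are
#' dropped; the drop list and the backend version are recorded in the
#' result metadata (descriptor counts are version-sensitive, so the
#' version is also copied into run manifests).
#'
#' @param ds A standardized `chemgroup_dataset`.
#' @param set_name `"compact"` or `"extended"` (aliases `compact_119`,
#'   `extended_1613` are accepted).
#' @return A continuous `chemgroup_features` matrix.
#' @export
compute_descriptors <- function(ds, set_name = "compact") {
  stopifnot(inherits(ds, "chemgroup_dataset"))
  if (!set_name %in% names(descriptor_set_names))
    stop("unknown descriptor set: ", set_name)
  set <- descriptor_set_names[[set_name]]
  bump_counter("descriptor_computations")
  res <- run_chemtools("descriptors",
                       list(smiles = as.list(ds$records$structure_text),
                            set = set))
  names_ <- as.character(unlist(res$names))
  ok <- vapply(res$values, function(v) !is.null(v), TRUE)
  rows <- lapply(res$values[ok], function(row)
    vapply(row, function(v) if (is.null(v)) NA_real_ else as.numeric(v),
           0))
  values <- do.call(rbind, rows)
  colnames(values) <- names_
  rownames(values) <- ds$records$record_id[ok]
  bad <- apply(values, 2L, function(col) any(!is.finite(col)))
  dropped <- colnames(values)[bad]
  values <- values[, !bad, drop = FALSE]
  new_feature_matrix(values, kind = "continuous",
                     meta = list(set = set,
                                 dropped_nonfinite = dropped,
                                 failed_records =
                                   ds$records$record_id[!ok],
                                 rdkit_version = res$rdkit_version))
}

#' Scale a continuous feature matrix
#'
#' * `minmax` maps each column linearly onto \[0, 1\].
#' * `zscore` centers each column to mean 0 and scales to sd 1.
#' * `decimal` divides each column by `10^j` with the smallest integer
#'   `j >= 0` such that the maximum absolute value is at most 1.
#'
#' Constant columns map to all zeros under `minmax`/`zscore` (they carry no
#' information and are removed by the variance filter anyway). Binary
#' matrices pass through unchanged with a warning. The per-column
#' parameters are stored in `$scaling` so the identical transform can be
#' replayed on new data with [apply_scaling()].
#'
#' @param fm A `chemgroup_features` matrix (or plain matrix).
#' @param method `"minmax"`, `"zscore"`, or `"decimal"`.
#' @return The scaled feature matrix with scaling provenance.
#' @export
scale_features <- function(fm, method = c("minmax", "zscore", "decimal")) {
  method <- match.arg(method)
  if (inherits(fm, "chemgroup_features") && fm$kind == "binary") {
    warning("binary fingerprint matrix passed through unscaled")
    return(fm)
  }
  x <- fm_values(fm)
  params <- switch(method,
    minmax = list(min = apply(x, 2L, min), max = apply(x, 2L, max)),
    zscore = list(mean = colMeans(x), sd = apply(x, 2L, stats::sd)),
    decimal = {
      # smallest integer j >= 0 with max|x| / 10^j <= 1
      maxabs <- apply(abs(x), 2L, max)
      j <- ifelse(maxabs <= 1, 0, ceiling(log10(maxabs)))
      list(j = as.integer(j))
    })
  out <- apply_scaling_matrix(x, method, params)
  res <- fm_replace(fm, out)
  if (inherits(res, "chemgroup_features"))
    res$scaling <- list(method = method, params = lapply(params, unname),
                        param_names = colnames(x))
  res
}

apply_scaling_matrix <- function(x, method, params) {
  out <- switch(method,
    minmax = {
      rng <- params$max - params$min
      rng[rng == 0] <- 1  # constant columns -> 0 after centering at min
      sweep(sweep(x, 2L, params$min, "-"), 2L, rng, "/")
    },
    zscore = {
      sd <- params$sd
      bad <- !is.finite(sd) | sd == 0
      centered <- sweep(x, 2L, params$mean, "-")
      sd[bad] <- 1
      out <- sweep(centered, 2L, sd, "/")
      out[, bad] <- 0
      out
    },
    decimal = sweep(x, 2L, 10^params$j, "/"))
  out
}

#' Apply stored scaling parameters to new data
#'
#' @param fm Feature matrix with the training columns in order.
#' @param scaling The `$scaling` element of a previously scaled matrix.
#' @return Scaled matrix.
#' @export
apply_scaling <- function(fm, scaling) {
  x <- fm_values(fm)
  if (identical(scaling$method, "none")) return(fm)
  stopifnot(identical(colnames(x), scaling$param_names))
  out <- apply_scaling_matrix(x, scaling$method, scaling$params)
  fm_replace(fm, out)
}

#' Export a feature matrix as CSV
#'
#' Writes the matrix with the record id as first column, matching the
#' downloadable "molecular descriptors" table of a report bundle.
#'
#' @param fm Feature matrix.
#' @param path Output CSV path.
#' @export
write_features_csv <- function(fm, path) {
  x <- fm_values(fm)
  df <- data.frame(record_id = rownames(x) %||% seq_len(nrow(x)), x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(format_numeric_df(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}
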