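# Synthetic-data generators. They emulate the three data shapes the
# pipeline consumes: separable feature blobs (clustering/tuning),
# labeled feature tables with a small planted informative subset among
# noise columns (filters/selection/SHAP), and scaffold-family SMILES
# sets with salts, stereocenters and duplicates (standardization and
# end-to-end runs). All generators are pure functions of their
# arguments and seed.

#' Gaussian feature blobs
#'
#' `k` unit-variance Gaussian blobs in `p` dimensions whose centers are
#' pairwise `separation` standard deviations apart (a scaled simplex on
#' the first `k` axes).
#'
#' @param n Total points (split as evenly as possible).
#' @param k Number of blobs (`n >= k >= 2`, `p >= k`).
#' @param p Dimensions.
#' @param separation Center separation in standard deviations.
#' @param seed Seed.
#' @return List with `x` (n x p matrix) and `labels` (0-based blob ids).
#' @export
make_feature_blobs <- function(n, k, p, separation, seed = 1L) {
  stopifnot(n >= k, k >= 2, p >= k)
  set.seed(seed)
  centers <- matrix(0, k, p)
  for (i in seq_len(k)) centers[i, i] <- separation / sqrt(2)
  labels <- rep(seq_len(k) - 1L, length.out = n)
  labels <- sort(labels)
  x <- centers[labels + 1L, , drop = FALSE] +
    matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- sprintf("f_%02d", seq_len(p))
  list(x = x, labels = as.integer(labels))
}

#' Labeled feature table with planted informative columns
#'
#' Labels are generated from the informative columns only: a logistic
#' model (binary), a softmax over three classes (multiclass), or a
#' linear model with unit Gaussian noise (continuous), with coefficient
#' magnitude `effect`. Noise columns are independent standard normals.
#'
#' @param n Rows.
#' @param p_informative,p_noise Informative / noise column counts.
#' @param effect Coefficient magnitude on the informative columns.
#' @param label_kind `"binary"`, `"multiclass"`, or `"continuous"`.
#' @param seed Seed.
#' @return List with `x` (columns `inf_*` then `noise_*`), `labels`, and
#'   `informative` (the informative column names).
#' @export
make_labeled_features <- function(n, p_informative, p_noise, effect,
                                  label_kind = "binary", seed = 1L) {
  stopifnot(n >= 1, p_informative >= 1, p_noise >= 0)
  label_kind <- match.arg(label_kind,
                          c("binary", "multiclass", "continuous"))
  set.seed(seed)
  p <- p_informative + p_noise
  x <- matrix(stats::rnorm(n * p), n, p)
  colnames(x) <- c(sprintf("inf_%02d", seq_len(p_informative)),
                   if (p_noise > 0) sprintf("noise_%02d", seq_len(p_noise)))
  xi <- x[, seq_len(p_informative), drop = FALSE]
  labels <- switch(label_kind,
    binary = {
      beta <- rep(effect, p_informative)
      pr <- stats::plogis(drop(xi %*% beta))
      as.integer(stats::runif(n) < pr)
    },
    multiclass = {
      beta <- matrix(stats::rnorm(p_informative * 3L, sd = 1), ncol = 3L)
      beta <- sign(beta) * effect
      eta <- xi %*% beta
      pr <- exp(eta - apply(eta, 1L, max))
      pr <- pr / rowSums(pr)
      vapply(seq_len(n), function(i)
        sample.int(3L, 1L, prob = pr[i, ]) - 1L, 0L)
    },
    continuous = {
      beta <- rep(effect, p_informative)
      drop(xi %*% beta) + stats::rnorm(n)
    })
  list(x = x, labels = labels,
       informative = colnames(x)[seq_len(p_informative)])
}

# scaffold cores and substituent decorations; string templates guarantee
# chemical validity without a generative model
fixture_scaffolds <- c(benzene = "c1ccccc1", cyclohexane = "C1CCCCC1",
                       pyridine = "c1ccncc1", furan = "c1ccoc1",
                       piperidine = "C1CCNCC1",
                       naphthalene = "c1ccc2ccccc2c1")
fixture_prefixes <- c("", "C", "CC", "CCC", "CCCC", "OC", "OCC", "NC",
                      "NCC", "ClC", "O=C(O)C", "C(C)C")
fixture_suffixes <- c("", "C", "CC", "O", "N", "Cl", "Br", "CO", "CCO",
                      "C(=O)O", "C#N", "C(F)(F)F")

#' Scaffold-family SMILES dataset
#'
#' Enumerates valid SMILES by decorating per-family ring scaffolds with
#' substituent prefixes/suffixes, then injects counterion-bearing
#' (`.Cl`) variants and exact duplicates at the requested fractions. The
#' family id is attached as a multiclass label.
#'
#' @param n_families Number of scaffold families (max 6).
#' @param n_per_family Structures per family before duplicate injection.
#' @param salt_fraction Fraction of records carrying a counterion.
#' @param duplicate_fraction Fraction of records duplicated verbatim.
#' @param seed Seed.
#' @return A `chemgroup_dataset` with `label_kind = "multiclass"`.
#' @export
make_smiles_families <- function(n_families = 3L, n_per_family = 20L,
                                 salt_fraction = 0.1,
                                 duplicate_fraction = 0, seed = 1L) {
  stopifnot(n_families >= 1L, n_families <= length(fixture_scaffolds),
            salt_fraction >= 0, salt_fraction <= 1,
            duplicate_fraction >= 0, duplicate_fraction <= 1)
  set.seed(seed)
  combos <- expand.grid(prefix = fixture_prefixes,
                        suffix = fixture_suffixes,
                        stringsAsFactors = FALSE)
  if (n_per_family > nrow(combos))
    stop("requested count exceeds enumerable decorations (",
         nrow(combos), " per family)")
  smiles <- character(0)
  family <- integer(0)
  for (fam in seq_len(n_families)) {
    core <- fixture_scaffolds[[fam]]
    pick <- combos[sample.int(nrow(combos), n_per_family), , drop = FALSE]
    smi <- paste0(pick$prefix, core, pick$suffix)
    smiles <- c(smiles, smi)
    family <- c(family, rep(fam - 1L, n_per_family))
  }
  n <- length(smiles)
  n_salt <- floor(salt_fraction * n)
  if (n_salt > 0) {
    idx <- sample.int(n, n_salt)
    smiles[idx] <- paste0(smiles[idx], ".Cl")
  }
  n_dup <- floor(duplicate_fraction * n)
  if (n_dup > 0) {
    idx <- sample.int(n, n_dup)
    smiles <- c(smiles, smiles[idx])
    family <- c(family, family[idx])
  }
  m <- length(smiles)
  records <- data.frame(
    record_id = sprintf("rec_%05d", seq_len(m) - 1L),
    source_index = seq_len(m) - 1L,
    structure_text = smiles,
    label = as.integer(family),
    parse_ok = TRUE,
    stringsAsFactors = FALSE)
  new_dataset(records, label_kind = "multiclass", label_column = "family",
              label_map = as.list(stats::setNames(
                seq_len(n_families) - 1L,
                as.character(seq_len(n_families) - 1L))),
              meta = list(generator = "make_smiles_families",
                          salt_fraction = salt_fraction,
                          duplicate_fraction = duplicate_fraction,
                          seed = seed))
}

#' Write a dataset as a CSV demo input
#'
#' Writes `SMILES` (and the label column when present) so generated
#' fixtures double as command-line demo inputs.
#'
#' @param ds A `chemgroup_dataset`.
#' @param path Output CSV path.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(inherits(ds, "chemgroup_dataset"))
  df <- data.frame(SMILES = ds$records$structure_text,
                   stringsAsFactors = FALSE)
  if (ds$label_kind != "none") {
    col <- ds$label_column %||% "label"
    df[[col]] <- ds$records$label
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
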