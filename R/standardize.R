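# QSAR-ready-style structure standardization. The rule chain, applied in a
# fixed order before any descriptor calculation:
#   1. largest-organic-fragment selection (salt / counterion removal)
#   2. charge neutralization where chemically valid (balanced zwitterions
#      such as nitro groups are left alone)
#   3. nitro-group normalization to the charge-separated canonical form
#   4. tautomer canonicalization (RDKit MolStandardize canonical tautomer)
#   5. stereochemistry removal
#   6. valence check
#   7. canonical SMILES
# Exact duplicates (identical canonical SMILES) are then collapsed; labeled
# duplicates with conflicting labels are removed entirely.

#' Standardize a single structure
#'
#' @param structure_text A SMILES string (or, with `is_molblock = TRUE`, an
#'   SDF mol-block).
#' @param is_molblock Whether `structure_text` is a mol-block.
#' @return A list with `canonical_smiles` (or `NULL` on failure),
#'   `applied_rules` (ordered character vector of rule names), `failed`,
#'   and `reason`.
#' @export
standardize_structure <- function(structure_text, is_molblock = FALSE) {
  res <- run_chemtools("standardize",
                       list(structures = list(structure_text),
                            is_molblock = is_molblock))
  r <- res$results[[1L]]
  list(canonical_smiles = r$canonical_smiles %||% NULL,
       applied_rules = as.character(unlist(r$applied_rules)),
       failed = !isTRUE(r$ok),
       reason = r$reason %||% NULL)
}

#' Standardize a dataset and collapse duplicates
#'
#' Applies [standardize_structure()] to every retained record, replaces
#' structures by their standardized canonical SMILES, collapses exact
#' duplicates to a single record, and—when labels are present—removes all
#' copies of duplicates whose labels conflict (reason
#' `conflicting_duplicate`). Records that fail standardization are removed
#' with reason `unreadable_structure`.
#'
#' @param ds An integrity-checked `chemgroup_dataset`.
#' @param verbose_log If `TRUE`, a per-record rule-application log is
#'   attached as attribute `"rule_log"` of the result.
#' @return A list with `dataset`, `removed` (removal report), and
#'   `rule_log` (data.frame of record id and applied rules).
#' @export
standardize_dataset <- function(ds, verbose_log = FALSE) {
  stopifnot(inherits(ds, "chemgroup_dataset"))
  rec <- orig_rec <- ds$records
  if (nrow(rec) == 0) stop("empty dataset")
  res <- run_chemtools("standardize",
                       list(structures = as.list(rec$structure_text),
                            is_molblock = FALSE))
  out <- res$results
  ok <- vapply(out, function(r) isTRUE(r$ok), TRUE)
  canon <- vapply(out, function(r) r$canonical_smiles %||% NA_character_, "")
  rules <- vapply(out, function(r)
    paste(unlist(r$applied_rules), collapse = ";"), "")

  removed <- data.frame(source_index = rec$source_index[!ok],
                        reason = rep("unreadable_structure", sum(!ok)),
                        stringsAsFactors = FALSE)
  rec <- rec[ok, , drop = FALSE]
  canon_ok <- canon[ok]
  rec$structure_text <- canon_ok

  labeled <- ds$label_kind != "none"
  # order-independent duplicate handling: group by canonical SMILES
  groups <- split(seq_len(nrow(rec)), rec$structure_text)
  keep <- logical(nrow(rec))
  conflict_idx <- integer(0)
  for (g in groups) {
    if (labeled && length(unique(rec$label[g])) > 1L) {
      conflict_idx <- c(conflict_idx, g)
    } else {
      keep[g[which.min(rec$source_index[g])]] <- TRUE
    }
  }
  if (length(conflict_idx)) {
    removed <- rbind(removed, data.frame(
      source_index = rec$source_index[conflict_idx],
      reason = "conflicting_duplicate", stringsAsFactors = FALSE))
  }
  removed <- removed[order(removed$source_index), , drop = FALSE]
  rownames(removed) <- NULL
  rec_out <- rec[keep, , drop = FALSE]
  rec_out <- rec_out[order(rec_out$source_index), , drop = FALSE]
  rownames(rec_out) <- NULL
  if (nrow(rec_out) == 0) stop("empty dataset after standardization")

  new_ds <- ds
  new_ds$records <- rec_out
  new_ds$removed <- rbind(ds$removed, removed)
  new_ds$meta$standardization <- list(
    tautomer_scheme = res$tautomer_scheme,
    rdkit_version = res$rdkit_version)
  rule_log <- data.frame(record_id = orig_rec$record_id,
                         applied_rules = rules, stringsAsFactors = FALSE)
  list(dataset = new_ds, removed = removed,
       rule_log = if (verbose_log) rule_log else NULL)
}
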