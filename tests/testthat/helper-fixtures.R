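# Shared fixture builders. Everything is generated in code; no binary
# fixtures are stored.

molblock <- function(title, atoms, bonds = NULL) {
  n_at <- length(atoms)
  n_bd <- if (is.null(bonds)) 0L else length(bonds)
  atom_lines <- vapply(atoms, function(sym)
    sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
            sym), "")
  bond_lines <- if (n_bd > 0) vapply(bonds, function(b)
    sprintf("%3d%3d%3d  0", b[1], b[2], b[3]), "") else character(0)
  paste(c(title, "  chemgroup-test 2D", "",
          sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n_at, n_bd),
          atom_lines, bond_lines, "M  END"),
        collapse = "\n")
}

# small SDF: ethanol, methane, benzene-free simple molecules with an
# optional label property and optionally one corrupt mol-block
write_test_sdf <- function(path, labels = NULL, include_corrupt = FALSE) {
  blocks <- c(
    molblock("ethanol", c("C", "C", "O"),
             list(c(1L, 2L, 1L), c(2L, 3L, 1L))),
    molblock("methane", "C"),
    molblock("methanol", c("C", "O"), list(c(1L, 2L, 1L))))
  entries <- character(0)
  for (i in seq_along(blocks)) {
    e <- blocks[i]
    if (!is.null(labels) && !is.na(labels[i]))
      e <- paste0(e, "\n>  <Outcome>\n", labels[i], "\n")
    entries <- c(entries, e)
  }
  if (include_corrupt)
    entries <- c(entries, "broken\nnot a molblock at all\nM  END")
  writeLines(paste0(entries, collapse = "\n$$$$\n"), path)
  cat("\n$$$$\n", file = path, append = TRUE)
  path
}

write_test_smiles <- function(path, smiles, ids = NULL) {
  lines <- if (is.null(ids)) smiles else paste(smiles, ids, sep = "\t")
  writeLines(lines, path)
  path
}

# independent double-loop silhouette used as the oracle in several tests
brute_silhouette <- function(x, labels) {
  keep <- labels != -1L
  x <- x[keep, , drop = FALSE]
  labels <- labels[keep]
  n <- nrow(x)
  s <- numeric(n)
  for (i in seq_len(n)) {
    di <- sqrt(colSums((t(x) - x[i, ])^2))
    same <- which(labels == labels[i] & seq_len(n) != i)
    a <- if (length(same) == 0L) 0 else mean(di[same])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(di[labels == cl]), 0))
    s[i] <- if (a == 0 && b == 0) 0 else (b - a) / max(a, b)
  }
  mean(s)
}

fast_logit <- function(seed = 1L)
  learner_spec("logistic_regression", "classification", seed = seed)

small_gbt <- function(seed = 1L, task = "classification")
  learner_spec("gradient_boosted_trees", task,
               list(nrounds = 30L, eta = 0.1), seed = seed)

# path where the published eye-irritation/corrosion case-study SDF is
# expected when available; the case-study checks run against it
case_study_sdf <- function() {
  system.file("extdata", "eye_irritation_case_study.sdf",
              package = "chemgroup")
}

require_case_study <- function() {
  p <- case_study_sdf()
  if (!nzchar(p) || !file.exists(p))
    stop("case-study SDF (eye_irritation_case_study.sdf) is not bundled; ",
         "place the published dataset under inst/extdata to run the ",
         "case-study checks")
  p
}
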