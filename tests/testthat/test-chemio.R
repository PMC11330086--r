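# Dataset input, integrity checking, summaries, manifest persistence.

test_that("SDF reading flags corrupt mol-blocks and keeps parse order", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_test_sdf(path, include_corrupt = TRUE)
  ds <- read_dataset(path, format = "sdf")
  expect_s3_class(ds, "chemgroup_dataset")
  expect_equal(nrow(ds$records), 4L)
  expect_equal(sum(ds$records$parse_ok), 3L)
  expect_false(ds$records$parse_ok[4L])
  expect_equal(ds$records$source_index, 0:3)
  # reading the same file twice is byte-identical
  ds2 <- read_dataset(path, format = "sdf")
  expect_identical(ds$records, ds2$records)
})

test_that("SDF labels are read from the named property and coerced", {
  path <- withr::local_tempfile(fileext = ".sdf")
  write_test_sdf(path, labels = c(0, 1, 1))
  ds <- read_dataset(path, format = "sdf", label_column = "Outcome",
                     label_kind = "binary")
  expect_equal(ds$records$label, c(0L, 1L, 1L))
})

test_that("CSV requires an identifiable SMILES column", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("structure,act", "CCO,1"), path)
  expect_error(read_dataset(path, format = "csv"), "no structure column")
  ds <- read_dataset(path, format = "csv", smiles_column = "structure",
                     label_column = "act", label_kind = "binary")
  expect_equal(nrow(ds$records), 1L)
  # case-insensitive exact match works without the flag
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("Smiles,act", "CCO,pos", "CC,neg", "C,pos"), path2)
  ds2 <- read_dataset(path2, format = "csv", label_column = "act",
                      label_kind = "binary")
  # two distinct strings map to 0/1 by sorted order: neg < pos
  expect_equal(ds2$records$label, c(1L, 0L, 1L))
  expect_equal(ds2$label_map, list(neg = 0L, pos = 1L))
})

test_that("integrity check removes unreadables and missing labels with reasons", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES,act", "CCO,1", "not_a_smiles,0", "CC,", "CCC,0"),
             path)
  ds <- read_dataset(path, format = "csv", label_column = "act",
                     label_kind = "binary")
  out <- integrity_check(ds)
  expect_equal(nrow(out$dataset$records), 2L)
  expect_equal(out$removed$reason,
               c("unreadable_structure", "missing_value"))
  # conservation: retained + removed = input
  expect_equal(nrow(out$dataset$records) + nrow(out$removed),
               nrow(ds$records))
  # clean dataset passes through identically with an empty report
  clean <- integrity_check(out$dataset)
  expect_equal(clean$dataset$records, out$dataset$records)
  expect_equal(nrow(clean$removed), 0L)
})

test_that("all records removed raises a structured error", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("SMILES", "xxx", "yyy"), path)
  ds <- read_dataset(path, format = "csv")
  expect_error(integrity_check(ds), "empty dataset after integrity check")
})

test_that("exploratory summary counts classes and removals exactly", {
  path <- withr::local_tempfile(fileext = ".csv")
  smis <- c(rep("CCO", 3L), rep("CCC", 3L), rep("CCN", 2L), "CCOC", "CCCC")
  writeLines(c("SMILES,act",
               paste0(smis, ",", c(rep(0, 6), rep(1, 4)))), path)
  ds <- integrity_check(read_dataset(path, format = "csv",
                                     label_column = "act",
                                     label_kind = "binary"))$dataset
  s <- summarize_dataset(ds)
  expect_equal(s$n_retained, 10L)
  expect_equal(s$class_counts, c("0" = 6L, "1" = 4L))
  # unlabeled dataset: retained count only
  ds2 <- integrity_check(read_dataset(path, format = "csv"))$dataset
  s2 <- summarize_dataset(ds2)
  expect_null(s2$class_counts)
  expect_equal(s2$n_retained, 10L)
})

test_that("SMILES line format reads one structure per line with ids", {
  path <- withr::local_tempfile(fileext = ".smi")
  write_test_smiles(path, c("CCO", "CC", "C1CCCCC1"), c("a", "b", "c"))
  ds <- read_dataset(path, format = "smiles")
  expect_equal(nrow(ds$records), 3L)
  expect_true(all(ds$records$parse_ok))
  expect_error(read_dataset(path, format = "smiles",
                            label_column = "x", label_kind = "binary"),
               "no label column")
})

test_that("manifest round-trips losslessly and rejects bad files", {
  m <- new_manifest(input = list(name = "x.sdf", format = "sdf",
                                 label_kind = "binary"), seed = 42L)
  m$options <- list(alpha = 0.5, grid = c(0, 0.01, 0.02), flag = TRUE)
  m <- chemgroup:::manifest_set_stage(m, "grouping", list(
    labels = c(0L, 1L, 1L, -1L),
    embedding = matrix(c(1.5, -2.25, 0.125, 3, 4, 5), ncol = 2L),
    silhouette = 0.63,
    config = list(cluster_method = "kmeans",
                  cluster_params = list(n_clusters = 3L))))
  path <- withr::local_tempfile(fileext = ".json")
  save_manifest(m, path)
  m2 <- load_manifest(path)
  expect_equal(unclass(m2),
               chemgroup:::canonicalize_manifest(unclass(m)))
  # truncated file -> structured error, no partial state
  writeLines(substr(paste(readLines(path), collapse = ""), 1, 40), path)
  expect_error(load_manifest(path), "malformed manifest")
  # wrong schema version refused
  path2 <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(schema_version = 99), path2,
                       auto_unbox = TRUE)
  expect_error(load_manifest(path2), "version-incompatible")
})
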