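# Fingerprints, continuous descriptors, and the three scaling methods.

test_that("fingerprint families have the right widths and are deterministic", {
  smis <- c("C", "CCO", "CCO", "c1ccccc1C(=O)O", "C1CCNCC1")
  records <- data.frame(record_id = sprintf("rec_%05d", seq_along(smis)),
                        source_index = seq_along(smis) - 1L,
                        structure_text = smis, label = NA,
                        parse_ok = TRUE, stringsAsFactors = FALSE)
  ds <- chemgroup:::new_dataset(records)
  fp <- compute_fingerprints(ds, fingerprint_spec("morgan", 3L, 512L))
  expect_equal(dim(fp$values), c(5L, 512L))
  expect_true(all(fp$values %in% c(0L, 1L)))
  # identical structures give identical bit rows
  expect_equal(fp$values[2L, ], fp$values[3L, ])
  # methane and ethanol differ (Tanimoto < 1)
  expect_true(any(fp$values[1L, ] != fp$values[2L, ]))
  # MACCS is the fixed 166 informative keys
  mk <- compute_fingerprints(ds, fingerprint_spec("maccs"))
  expect_equal(ncol(mk$values), 166L)
  # FeatMorgan uses different invariants than Morgan at equal settings
  fm2 <- compute_fingerprints(ds, fingerprint_spec("feat_morgan", 3L, 512L))
  expect_false(identical(fp$values, fm2$values))
  # row order follows record order: a permuted dataset permutes rows only
  ds_rev <- ds
  ds_rev$records <- ds$records[5:1, , drop = FALSE]
  fp_rev <- compute_fingerprints(ds_rev, fingerprint_spec("morgan", 3L, 512L))
  expect_equal(unname(fp_rev$values), unname(fp$values[5:1, ]))
})

test_that("continuous descriptor sets have pinned sizes and finite values", {
  smis <- c("CCO", "c1ccccc1", "CC(=O)O", "C1CCCCC1N")
  records <- data.frame(record_id = sprintf("rec_%05d", seq_along(smis)),
                        source_index = seq_along(smis) - 1L,
                        structure_text = smis, label = NA,
                        parse_ok = TRUE, stringsAsFactors = FALSE)
  ds <- chemgroup:::new_dataset(records)
  compact <- compute_descriptors(ds, "compact")
  expect_equal(ncol(compact$values) +
                 length(compact$meta$dropped_nonfinite), 119L)
  expect_true(all(is.finite(compact$values)))
  # duplicate structures give identical rows
  ds$records$structure_text[4L] <- "CCO"
  d2 <- compute_descriptors(ds, "compact_119")
  expect_equal(unname(d2$values[1L, ]), unname(d2$values[4L, ]))
  # the extended alias resolves and is a superset of descriptors
  ext <- compute_descriptors(ds, "extended_1613")
  expect_gt(ncol(ext$values), ncol(compact$values))
  expect_error(compute_descriptors(ds, "padel"), "unknown descriptor set")
})

test_that("scaling contracts hold exactly and parameters replay on new data", {
  set.seed(7)
  x <- cbind(a = c(0, 5, 10), b = c(345, -12, 101), c = c(0.5, -0.25, 0.1),
             d = c(2, 2, 2), e = rnorm(3))
  # minmax: [0,5,10] -> [0,0.5,1]; all columns in [0,1]; constant -> 0
  mm <- scale_features(x, "minmax")
  expect_equal(mm[, "a"], c(0, 0.5, 1))
  expect_true(all(mm >= 0 & mm <= 1))
  expect_equal(mm[, "d"], c(0, 0, 0))
  # zscore: mean 0, sd 1 within 1e-9 for non-constant columns
  zs <- scale_features(x, "zscore")
  expect_lt(max(abs(colMeans(zs))), 1e-9)
  expect_lt(max(abs(apply(zs[, c("a", "b", "c", "e")], 2, sd) - 1)), 1e-9)
  expect_equal(zs[, "d"], c(0, 0, 0))
  # decimal: [345,-12] -> j=3 -> [0.345,-0.012]; [0.5,-0.25] unchanged
  dc <- scale_features(x, "decimal")
  expect_equal(dc[, "b"], c(0.345, -0.012, 0.101))
  expect_equal(dc[, "c"], x[, "c"])
  expect_true(max(abs(dc)) <= 1)
})

test_that("stored scaling parameters reproduce the transform exactly", {
  set.seed(11)
  x <- matrix(rnorm(60, sd = 40), 12, 5,
              dimnames = list(NULL, paste0("v", 1:5)))
  fm <- chemgroup:::new_feature_matrix(x, "continuous")
  for (method in c("minmax", "zscore", "decimal")) {
    scaled <- scale_features(fm, method)
    replay <- apply_scaling(fm, scaled$scaling)
    expect_identical(replay$values, scaled$values)
  }
})

test_that("binary matrices pass through scaling with a warning", {
  fm <- chemgroup:::new_feature_matrix(
    matrix(rbinom(20, 1, 0.5), 4, 5,
           dimnames = list(NULL, paste0("b", 1:5))), "binary")
  expect_warning(out <- scale_features(fm, "minmax"), "unscaled")
  expect_identical(out$values, fm$values)
})
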