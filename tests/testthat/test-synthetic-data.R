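# Generator: ground-truth structure, dataset arithmetic, determinism,
# modality partition, serialization round trip.

test_that("ground truth has unit-norm, spatially distinct maps with the signature loadings", {
  cfg <- smallConfig(seed = 7L)
  truth <- makeGroundTruth(cfg)
  M <- componentMaps(truth)
  L <- loadingMatrix(truth)

  expect_equal(unname(sqrt(rowSums(M^2))), rep(1, nrow(M)), tolerance = 1e-12)
  cc <- cor(t(M))
  expect_lt(max(abs(cc[upper.tri(cc)])), 0.3)

  # action signature: verbs and implied actions load identically
  expect_identical(L["verb", "action_signature"],
                   L["implied_action", "action_signature"])
  expect_identical(L["noun", "action_signature"], 0)
  expect_identical(L["object", "action_signature"], 0)
  # object signature: common activation for objects and nouns, common
  # decrease for actions and verbs
  expect_identical(L["noun", "object_signature"], L["object", "object_signature"])
  expect_identical(L["verb", "object_signature"], L["implied_action", "object_signature"])
  expect_identical(L["verb", "object_signature"], -L["noun", "object_signature"])
  expect_gt(L["noun", "object_signature"], 0)

  # zero-amplitude case zeroes the action column
  truth0 <- makeGroundTruth(smallConfig(seed = 7L, actionEffect = 0))
  expect_identical(unname(loadingMatrix(truth0)[, "action_signature"]),
                   rep(0, 4))

  # bitwise determinism
  expect_identical(truth, makeGroundTruth(smallConfig(seed = 7L)))
  expect_false(identical(componentMaps(truth),
                         componentMaps(makeGroundTruth(smallConfig(seed = 8L)))))
})

test_that("ground truth rejects impossible worlds", {
  expect_error(makeGroundTruth(smallConfig(gridShape = c(5L, 5L, 5L))),
               "200 voxels")
  expect_error(makeGroundTruth(smallConfig(nTrueComponents = 2L)), ">= 3")
  expect_error(simulateDataset(smallConfig(gridShape = c(12L, 12L, 10L)),
                               makeGroundTruth(smallConfig())),
               "does not match")
})

test_that("simulated datasets have the design counts and balanced labels", {
  cfg <- smallConfig(seed = 3L)
  ds <- simulateDataset(cfg, makeGroundTruth(cfg))

  expect_s4_class(ds, "ActivityDataset")
  expect_identical(nMaps(ds), 8L * 12L * 4L)
  expect_identical(length(unique(trialIds(ds))), 8L * 12L)
  tab <- table(conditionLabels(ds))
  expect_true(all(tab == nMaps(ds) / 4))

  # words are exactly noun/verb, pictures exactly object/implied_action
  expect_setequal(unique(conditionLabels(ds)[modalityLabels(ds) == "word"]),
                  c("noun", "verb"))
  expect_setequal(unique(conditionLabels(ds)[modalityLabels(ds) == "picture"]),
                  c("object", "implied_action"))
  expect_false(anyNA(featureMatrix(ds)))

  # maps of one trial share one condition and appear mapsPerTrial times
  expect_true(all(table(trialIds(ds)) == 4L))

  # determinism
  ds2 <- simulateDataset(cfg, makeGroundTruth(cfg))
  expect_identical(featureMatrix(ds), featureMatrix(ds2))
})

test_that("noiseless maps lie exactly in the component row span", {
  cfg <- smallConfig(seed = 5L, noiseSd = 0, subjectSd = 0,
                     nSubjects = 4L, trialsPerSubject = 8L)
  truth <- makeGroundTruth(cfg)
  ds <- simulateDataset(cfg, truth)
  X <- featureMatrix(ds)
  M <- componentMaps(truth)
  proj <- X %*% t(M) %*% solve(M %*% t(M)) %*% M
  expect_lt(max(abs(X - proj)), 1e-10)
})

test_that("per-condition mean maps track the generating signal as the noise model predicts", {
  # Monte-Carlo check against the generating equation: the observed
  # correlation between a condition's mean map and its loading x maps signal
  # must match sqrt(sv / (sv + noiseSd^2 / nMapsPerCondition)).
  cfg <- smallConfig(seed = 9L, nSubjects = 12L, noiseSd = 0.25)
  truth <- makeGroundTruth(cfg)
  ds <- simulateDataset(cfg, truth)
  X <- featureMatrix(ds)
  cond <- conditionLabels(ds)
  signal <- loadingMatrix(truth) %*% componentMaps(truth)
  nPerCond <- nMaps(ds) / 4
  for (c in rownames(signal)) {
    r <- cor(colMeans(X[cond == c, , drop = FALSE]), signal[c, ])
    sv <- stats::var(signal[c, ])
    pred <- sqrt(sv / (sv + cfg@noiseSd^2 / nPerCond))
    expect_gt(r, 0.9)
    expect_lt(abs(r - pred), 0.05)
  }
})

test_that("splitByModality partitions word-train and picture-test exactly", {
  ds <- smallDataset(seed = 2L)
  parts <- splitByModality(ds)
  expect_identical(nMaps(parts$train) + nMaps(parts$test), nMaps(ds))
  expect_true(all(modalityLabels(parts$train) == "word"))
  expect_true(all(modalityLabels(parts$test) == "picture"))
  expect_length(intersect(trialIds(parts$train), trialIds(parts$test)), 0L)
  expect_error(splitByModality(parts$train), "both modalities")
})

test_that("dataset serialization round-trips through NIfTI + TSV", {
  cfg <- smallConfig(seed = 4L, nSubjects = 2L, trialsPerSubject = 4L)
  ds <- simulateDataset(cfg, makeGroundTruth(cfg))
  prefix <- tempfile("ds")
  writeActivityDataset(ds, prefix)
  back <- readActivityDataset(paste0(prefix, ".nii.gz"),
                              paste0(prefix, "_labels.tsv"))
  expect_equal(featureMatrix(back), unname(featureMatrix(ds)),
               ignore_attr = TRUE, tolerance = 1e-12)
  expect_identical(conditionLabels(back), conditionLabels(ds))
  expect_identical(binaryLabels(back), binaryLabels(ds))
})
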