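# Factored model: initialization, loss contract, RMSProp recursion,
# training behavior, contributions, export.

conds4 <- c("noun", "verb", "object", "implied_action")

test_that("initialization follows the stated gain and zero biases", {
  cfg <- ssflrConfig(nComponents = 10L, gain = 0.004, seed = 3L)
  m <- initializeModel(cfg, 2000L)
  expect_lt(abs(sd(m@Wenc) - 0.004) / 0.004, 0.1)
  expect_identical(m@benc, numeric(10L))
  expect_identical(m@bdec, numeric(2000L))
  expect_identical(m@bcls, numeric(4L))
  m2 <- initializeModel(cfg, 2000L)
  expect_identical(m@Wenc, m2@Wenc)
  expect_error(initializeModel(cfg, 5L), "exceed")
})

test_that("the loss decomposes exactly as the weighted composite", {
  set.seed(4)
  cfg <- ssflrConfig(nComponents = 3L, lambda = 0.3, l1 = 0.2, l2 = 0.1,
                     ortho = 0.4, gain = 0.3, seed = 5L)
  m <- initializeModel(cfg, 25L)
  X <- matrix(rnorm(30 * 25), 30, 25)
  y <- sample(conds4, 30, replace = TRUE)
  ob <- ssflrObjective(CrossDecode:::modelParams(m), X, y, cfg)
  with(ob$loss, expect_equal(
    total,
    0.3 * classification + 0.7 * reconstruction + l1_term + l2_term +
      ortho_term,
    tolerance = 1e-10))

  # lambda = 1, penalties 0: classification only
  cfg1 <- ssflrConfig(nComponents = 3L, lambda = 1, l1 = 0, l2 = 0,
                      ortho = 0, gain = 0.3, seed = 5L)
  ob1 <- ssflrObjective(CrossDecode:::modelParams(m), X, y, cfg1)
  expect_equal(ob1$loss$total, ob1$loss$classification, tolerance = 1e-12)

  # zero weights: uniform softmax gives ln 4
  zero <- lapply(CrossDecode:::modelParams(m), function(p) p * 0)
  obz <- ssflrObjective(zero, X, y, cfg1)
  expect_equal(obz$loss$classification, log(4), tolerance = 1e-12)

  expect_error(ssflrObjective(zero, X * NA, y, cfg1), "non-finite")
  expect_error(ssflrObjective(zero, X, rep("cats", 30), cfg1), "labels")
})

test_that("analytic gradients match central finite differences", {
  set.seed(6)
  cfg <- ssflrConfig(nComponents = 3L, lambda = 0.5, l1 = 0.05, l2 = 0.05,
                     ortho = 0.1, gain = 0.5, seed = 6L)
  m <- initializeModel(cfg, 50L)
  params <- CrossDecode:::modelParams(m)
  X <- matrix(rnorm(40 * 50), 40, 50)
  y <- sample(conds4, 40, replace = TRUE)
  ob <- ssflrObjective(params, X, y, cfg)
  eps <- 1e-6
  for (nm in names(params)) {
    P <- params[[nm]]
    probe <- seq_len(min(length(P), 40L))   # spot-check coordinates
    for (i in probe) {
      pp <- params
      pp[[nm]][i] <- P[i] + eps
      f1 <- ssflrObjective(pp, X, y, cfg)$loss$total
      pp[[nm]][i] <- P[i] - eps
      f0 <- ssflrObjective(pp, X, y, cfg)$loss$total
      num <- (f1 - f0) / (2 * eps)
      expect_lt(abs(num - ob$grads[[nm]][i]) /
                  (abs(num) + abs(ob$grads[[nm]][i]) + 1e-8), 1e-5)
    }
  }
})

test_that("RMSProp follows its closed-form recursion and clips gradients", {
  cfg <- ssflrConfig(learningRate = 0.01, rho = 0.9, epsilon = 1e-6,
                     clipNorm = Inf)
  params <- list(w = c(1, 2))
  # zero gradient: no movement
  up0 <- rmspropStep(params, list(w = c(0, 0)), NULL, cfg)
  expect_identical(up0$params$w, c(1, 2))
  # first unit-gradient step: a = 0.1, step = lr / (sqrt(0.1) + eps)
  up1 <- rmspropStep(params, list(w = c(1, 1)), NULL, cfg)
  expect_equal(up1$state$w, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(up1$params$w,
               c(1, 2) - 0.01 / (sqrt(0.1) + 1e-6), tolerance = 1e-12)
  # constant gradient: accumulator -> g^2, step -> lr * sign(g)
  st <- NULL; p <- list(w = 0)
  steps <- numeric(400)
  for (i in 1:400) {
    old <- p$w
    up <- rmspropStep(p, list(w = 3), st, cfg)
    p <- up$params; st <- up$state
    steps[i] <- old - p$w
  }
  expect_equal(st$w, 9, tolerance = 1e-6)
  expect_equal(steps[400], 0.01, tolerance = 1e-6)
  # global norm clipping rescales the update
  cfgC <- ssflrConfig(learningRate = 0.01, clipNorm = 1)
  upC <- rmspropStep(list(w = c(0, 0)), list(w = c(30, 40)), NULL, cfgC)
  expect_equal(upC$state$w, 0.1 * c(0.6, 0.8)^2, tolerance = 1e-12)
})

test_that("full-batch training decreases the loss and fits the conditions", {
  ds <- smallDataset(seed = 20L, nSubjects = 4L, trialsPerSubject = 8L)
  cfg <- ssflrConfig(nComponents = 4L, learningRate = 5e-3,
                     maxEpochs = 200L, batchSize = 128L, l1 = 0, l2 = 0,
                     ortho = 0.1, seed = 21L)
  fit <- fitSSFLR(ds, config = cfg)
  h <- lossHistory(fit$model)
  expect_identical(nrow(h), 200L)
  expect_lt(tail(h$total, 1), h$total[1])
  # full-batch descent at a small step size is (near-)monotone
  cfgM <- ssflrConfig(nComponents = 4L, learningRate = 5e-4,
                      maxEpochs = 200L, batchSize = 128L, l1 = 0, l2 = 0,
                      ortho = 0.1, seed = 21L)
  hm <- lossHistory(fitSSFLR(ds, config = cfgM)$model)
  expect_gt(mean(diff(hm$total) <= 1e-8), 0.9)
  expect_lt(tail(hm$total, 1), hm$total[1])
  # condition prediction beats chance 0.25 on training data
  X <- standardizeTrainTest(featureMatrix(ds))$train
  expect_gt(mean(predict(fit$model, X) == conditionLabels(ds)), 0.25)
  # report shapes
  expect_identical(dim(componentMaps(fit$report)), c(4L, nVoxels(ds)))
  expect_identical(dim(contributions(fit$report)), c(4L, 4L))
})

test_that("training aborts with a diagnostic when it diverges", {
  set.seed(22)
  X <- matrix(rnorm(40 * 20, sd = 50), 40, 20)
  y <- rep(conds4, each = 10)
  # an absurd init scale overflows the reconstruction on the first batch
  cfg <- ssflrConfig(nComponents = 3L, learningRate = 1,
                     maxEpochs = 50L, clipNorm = Inf, gain = 1e160,
                     batchSize = 40L, seed = 23L)
  expect_error(fitSSFLR(X, y, cfg, standardize = FALSE), "diverged")
})

test_that("contributions scale classifier weights by latent spread and respect the sign gauge", {
  set.seed(24)
  cfg <- ssflrConfig(nComponents = 3L, seed = 25L)
  m <- initializeModel(cfg, 30L)
  m@history <- data.frame(epoch = 1L, total = 1, reconstruction = 1,
                          classification = 1, l1_term = 0, l2_term = 0,
                          ortho_term = 0)
  X <- matrix(rnorm(60 * 30), 60, 30)
  contrib <- componentContributions(m, X)
  h <- X %*% m@Wenc + matrix(m@benc, 60, 3, byrow = TRUE)
  expect_equal(contrib, t(m@Wcls * apply(h, 2, sd)), ignore_attr = TRUE,
               tolerance = 1e-12)

  # zero classifier column -> zero contributions for that condition
  m2 <- m; m2@Wcls[, 2] <- 0
  expect_true(all(componentContributions(m2, X)[2, ] == 0))

  # flipping (decoder row, classifier row, latent) jointly flips the
  # contribution sign and leaves predictions unchanged
  m3 <- m
  m3@Wenc[, 1] <- -m3@Wenc[, 1]; m3@benc[1] <- -m3@benc[1]
  m3@Wdec[1, ] <- -m3@Wdec[1, ]; m3@Wcls[1, ] <- -m3@Wcls[1, ]
  expect_identical(predict(m3, X), predict(m, X))
  c3 <- componentContributions(m3, X)
  expect_equal(c3[, 1], -contrib[, 1], tolerance = 1e-12)

  # untrained model warns
  m@history <- CrossDecode:::emptyHistory()
  expect_warning(componentContributions(m, X), "history")
})

test_that("component maps export to NIfTI volumes plus a TSV and re-load exactly", {
  mask <- randomMask(c(8L, 7L, 6L), p = 0.5, seed = 26L)
  V <- nVoxelsIn(mask)
  set.seed(27)
  maps <- matrix(rnorm(10 * V), 10, V)
  contrib <- matrix(rnorm(40), 4, 10,
                    dimnames = list(conds4, sprintf("component_%02d", 1:10)))
  report <- new("ComponentReport", componentMaps = maps,
                contributions = contrib, conditionOrder = conds4)
  outdir <- tempfile("comp")
  files <- exportComponentMaps(report, mask, outdir)
  niis <- files[grepl("nii", files)]
  expect_length(niis, 10L)
  expect_true(all(file.exists(files)))
  back <- readVolume(niis[3])
  expect_equal(extractFeatures(back$values, mask)[1, ], maps[3, ],
               tolerance = 1e-6, ignore_attr = TRUE)
  tsv <- read.delim(files[grepl("tsv", files)], check.names = FALSE)
  expect_identical(dim(tsv), c(4L, 11L))   # condition column + 10 components

  badMask <- randomMask(c(5L, 5L, 5L), p = 0.5, seed = 28L)
  expect_error(exportComponentMaps(report, badMask, outdir), "match")
})
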