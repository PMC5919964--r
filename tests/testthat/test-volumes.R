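# NIfTI I/O, resampling, mask construction, masked feature extraction and
# train-fitted standardization.

test_that("NIfTI volumes round-trip shape, affine and values", {
  set.seed(1)
  grid <- mniGrid(c(20L, 24L, 20L))
  vals <- array(rnorm(prod(gridShape(grid))), dim = gridShape(grid))
  path <- tempfile(fileext = ".nii.gz")
  writeVolume(grid, vals, path)
  back <- readVolume(path)
  expect_identical(gridShape(back$grid), gridShape(grid))
  expect_lt(max(abs(gridAffine(back$grid) - gridAffine(grid))), 1e-6)
  expect_lt(max(abs(back$values - vals)), 1e-6)

  # uncompressed too
  path2 <- tempfile(fileext = ".nii")
  writeVolume(grid, vals, path2)
  expect_lt(max(abs(readVolume(path2)$values - vals)), 1e-6)
})

test_that("4-D stacks yield one feature row per map after masking", {
  set.seed(2)
  grid <- randomGrid()
  stack <- array(rnorm(prod(gridShape(grid)) * 8), dim = c(gridShape(grid), 8L))
  path <- tempfile(fileext = ".nii.gz")
  writeVolume(grid, stack, path)
  back <- readVolume(path)
  expect_identical(dim(back$values), dim(stack))
  mask <- randomMask()
  feats <- extractFeatures(back$values, mask)
  expect_identical(dim(feats), c(8L, nVoxelsIn(mask)))
})

test_that("non-RAS volumes are reoriented to RAS+ with values at the same mm positions", {
  set.seed(3)
  sh <- c(6L, 5L, 4L)
  vals <- array(rnorm(prod(sh)), dim = sh)
  # LAS-style affine: x axis flipped
  aff <- rbind(cbind(diag(c(-2, 2, 2)), c(5, -4, -3)), c(0, 0, 0, 1))
  grid <- new("VolumeGrid", shape = sh, affine = aff)
  path <- tempfile(fileext = ".nii")
  writeVolume(grid, vals, path)
  back <- readVolume(path)
  expect_true(all(diag(gridAffine(back$grid))[1:3] > 0))
  expect_equal(back$values, vals[sh[1]:1, , ], tolerance = 1e-6)
  # mm position of a marked voxel is preserved
  vals2 <- array(0, dim = sh); vals2[2, 3, 4] <- 7
  writeVolume(grid, vals2, path)
  b2 <- readVolume(path)
  idx <- which(b2$values == 7, arr.ind = TRUE)[1, ] - 1
  mmNew <- gridAffine(b2$grid) %*% c(idx, 1)
  mmOld <- aff %*% c(1, 2, 3, 1)
  expect_equal(as.numeric(mmNew), as.numeric(mmOld), tolerance = 1e-5)
})

test_that("malformed volume files are rejected", {
  bad <- tempfile(fileext = ".nii")
  writeBin(as.raw(rep(1L, 400)), bad)
  expect_error(readVolume(bad), "NIfTI")
})

test_that("resampling keeps identity, binary value sets and constants", {
  set.seed(4)
  grid <- randomGrid(c(8L, 8L, 8L))
  vals <- array(rnorm(512), dim = c(8, 8, 8))
  expect_equal(resampleToGrid(grid, vals, grid, "nearest"), vals)
  expect_equal(resampleToGrid(grid, vals, grid, "linear"), vals,
               tolerance = 1e-12)

  # binary input, nearest mode -> binary output on a finer grid
  bin <- array(as.numeric(runif(512) > 0.5), dim = c(8, 8, 8))
  fine <- VolumeGrid(c(16L, 16L, 16L), affine = {
    a <- gridAffine(grid); a[1:3, 1:3] <- a[1:3, 1:3] / 2; a
  })
  out <- resampleToGrid(grid, bin, fine, "nearest")
  expect_true(all(out %in% c(0, 1)))

  # constant volume interpolates to the constant inside the overlap
  ones <- array(1, dim = c(8, 8, 8))
  mid <- resampleToGrid(grid, ones, fine, "linear")
  expect_true(all(abs(mid[4:12, 4:12, 4:12] - 1) < 1e-12))

  # disjoint fields of view warn and return zeros
  far <- VolumeGrid(c(4L, 4L, 4L), affine = {
    a <- diag(4); a[1:3, 4] <- 1000; a
  })
  expect_warning(z <- resampleToGrid(grid, ones, far), "overlap")
  expect_true(all(z == 0))
})

test_that("mask voxel counts scale with the voxel-volume ratio under resampling", {
  grid <- mniGrid(c(20L, 24L, 20L))     # 9 mm voxels
  peaks <- data.frame(cluster_id = 1, cluster_size = 10, x = 0, y = -40, z = 20)
  mask <- buildMaskFromPeaks(peaks, radiusMm = 30, grid)
  fine <- mniGrid(c(30L, 36L, 30L))     # 6 mm voxels
  res <- resampleToGrid(grid, array(as.numeric(maskData(mask)),
                                    dim = gridShape(grid)), fine, "nearest")
  ratio <- sum(res) / nVoxelsIn(mask)
  expect_lt(abs(ratio / (9 / 6)^3 - 1), 0.15)
})

test_that("gray-matter masking thresholds at 10% tissue probability", {
  grid <- randomGrid(c(6L, 6L, 6L))
  expect_identical(nVoxelsIn(grayMatterMask(grid, array(0.5, dim = c(6, 6, 6)))),
                   216L)
  expect_error(grayMatterMask(grid, array(0.05, dim = c(6, 6, 6))), "empty")
  expect_error(grayMatterMask(grid, array(1.5, dim = c(6, 6, 6))), "\\[0, 1\\]")

  # known fraction above threshold
  set.seed(5)
  probs <- array(0, dim = c(6, 6, 6))
  hot <- sample(216, 80)
  probs[hot] <- runif(80, 0.10, 1)
  m <- grayMatterMask(grid, probs, threshold = 0.10)
  expect_identical(nVoxelsIn(m), 80L)
})

test_that("peak-sphere masks are compact, tiny at tiny radius, and split when far apart", {
  grid <- mniGrid()                     # 60 x 72 x 60 at 3 mm
  m1 <- buildMaskFromPeaks(data.frame(cluster_id = 1, cluster_size = 141,
                                      x = -37, y = -40, z = 50),
                           radiusMm = 6, grid)
  expect_gt(nVoxelsIn(m1), 1L)
  expect_lt(nVoxelsIn(m1), 60L)
  # the voxel nearest the peak is inside
  inv <- solve(gridAffine(grid))
  idx <- round((inv %*% c(-37, -40, 50, 1))[1:3]) + 1
  expect_true(maskData(m1)[idx[1], idx[2], idx[3]])

  # tiny radius: zero voxels (off-centre peak -> empty-mask error) ...
  expect_error(
    buildMaskFromPeaks(data.frame(cluster_id = 1, cluster_size = 130,
                                  x = -50, y = -70, z = 4),
                       radiusMm = 0.1, grid),
    "no voxel")
  # ... or exactly one voxel when the peak sits on a voxel centre
  m2 <- buildMaskFromPeaks(data.frame(cluster_id = 1, cluster_size = 130,
                                      x = -51, y = -69, z = 3),
                           radiusMm = 0.1, grid)
  expect_identical(nVoxelsIn(m2), 1L)

  # two distant peaks: voxel count equals the sum of the single-peak counts
  pk <- data.frame(cluster_id = 1:2, cluster_size = c(5, 5),
                   x = c(-40, 40), y = c(0, 0), z = c(0, 0))
  both <- buildMaskFromPeaks(pk, radiusMm = 6, grid)
  one <- buildMaskFromPeaks(pk[1, ], radiusMm = 6, grid)
  two <- buildMaskFromPeaks(pk[2, ], radiusMm = 6, grid)
  expect_identical(nVoxelsIn(both), nVoxelsIn(one) + nVoxelsIn(two))

  expect_warning(
    buildMaskFromPeaks(data.frame(cluster_id = 1:2, cluster_size = c(5, 5),
                                  x = c(0, 500), y = c(0, 0), z = c(0, 0)),
                       radiusMm = 6, grid),
    "outside")
})

test_that("the packaged peak table builds the search-space mask", {
  peaks <- readPeakTable(system.file("extdata", "mirror_system_peaks.tsv",
                                     package = "CrossDecode"))
  expect_identical(nrow(peaks), 9L)
  expect_true(all(c("cluster_id", "cluster_size", "x", "y", "z") %in%
                    colnames(peaks)))
  mask <- buildMaskFromPeaks(peaks, radiusMm = 15,
                             mniGrid(c(20L, 24L, 20L)))
  expect_gt(nVoxelsIn(mask), 20L)
})

test_that("extract/insert round trip is the identity on masked voxels", {
  set.seed(6)
  mask <- randomMask(c(7L, 6L, 5L), p = 0.5)
  V <- nVoxelsIn(mask)
  mat <- matrix(rnorm(5 * V), 5, V)
  vol <- insertFeatures(mat, mask)
  expect_identical(dim(vol), c(7L, 6L, 5L, 5L))
  expect_identical(extractFeatures(vol, mask), mat)
  # out-of-mask voxels are zero
  outside <- array(rep(!maskData(mask), 5), dim = dim(vol))
  expect_true(all(vol[outside] == 0))
  # all-true mask keeps every voxel
  full <- new("MaskVolume", grid = mask@grid,
              data = array(TRUE, dim = gridShape(mask)))
  expect_identical(ncol(extractFeatures(vol, full)),
                   as.integer(prod(gridShape(mask))))
  expect_error(extractFeatures(vol[1:3, , , ], mask), "grid")
})

test_that("standardization uses training statistics only", {
  set.seed(7)
  train <- matrix(rnorm(50 * 6, mean = 2, sd = 3), 50, 6)
  test <- matrix(rnorm(20 * 6, mean = 2, sd = 3), 20, 6)
  std <- standardizeTrainTest(train, test)
  expect_lt(max(abs(colMeans(std$train))), 1e-8)
  expect_lt(max(abs(colMeans(std$train^2) - 1)), 1e-8)

  # a shifted test column lands at delta / sd_train
  delta <- 1.7
  std2 <- standardizeTrainTest(train, sweep(train, 2, -delta))
  expect_equal(colMeans(std2$test), delta / std$sds, tolerance = 1e-8)

  # train == test: test is standardized too
  std3 <- standardizeTrainTest(train, train)
  expect_lt(max(abs(colMeans(std3$test))), 1e-8)

  # constant training column zeroes both
  train[, 3] <- 5
  test[, 3] <- rnorm(20)
  std4 <- standardizeTrainTest(train, test)
  expect_true(all(std4$train[, 3] == 0))
  expect_true(all(std4$test[, 3] == 0))

  # permuting test rows never changes the transform
  std5 <- standardizeTrainTest(train, test[sample(20), ])
  expect_identical(std5$means, std4$means)
  expect_identical(std5$sds, std4$sds)
})
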