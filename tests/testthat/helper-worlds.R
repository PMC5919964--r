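# Shared small synthetic worlds for the test suite. Grids of 10 x 12 x 10
# voxels keep classifier fits fast while leaving room for six well-separated
# component blobs.

smallConfig <- function(seed = 1L, ...) {
  args <- list(nSubjects = 8L, trialsPerSubject = 12L,
               gridShape = c(10L, 12L, 10L), seed = as.integer(seed))
  override <- list(...)
  args[names(override)] <- override
  do.call(generatorConfig, args)
}

smallDataset <- function(seed = 1L, ...) {
  cfg <- smallConfig(seed, ...)
  simulateDataset(cfg, makeGroundTruth(cfg))
}

# Identifiable 3-component world for parameter recovery: mutually orthogonal
# condition contrasts (modality, object-vs-action signature, interaction)
# with distinct amplitudes, low map noise.
recoveryWorld <- function(seed) {
  cfg <- generatorConfig(nSubjects = 6L, trialsPerSubject = 16L,
                         gridShape = c(10L, 12L, 10L), nTrueComponents = 3L,
                         subjectSd = 0.3, noiseSd = 0.25,
                         seed = as.integer(seed))
  base <- makeGroundTruth(cfg)
  L <- cbind(2.0 * c(1, 1, -1, -1),   # word vs picture modality contrast
             1.4 * c(1, -1, 1, -1),   # object/noun up, action/verb down
             0.9 * c(1, -1, -1, 1))   # interaction contrast
  rownames(L) <- c("noun", "verb", "object", "implied_action")
  truth <- GroundTruth(componentMaps(base), L)
  list(config = cfg, truth = truth, dataset = simulateDataset(cfg, truth))
}

# Greedy best-match assignment of recovered to true maps by max |r|.
greedyMatchAbsCor <- function(trueMaps, recMaps) {
  cc <- abs(stats::cor(t(trueMaps), t(recMaps)))
  got <- numeric(nrow(trueMaps))
  for (i in seq_len(nrow(trueMaps))) {
    ix <- which(cc == max(cc), arr.ind = TRUE)[1, ]
    got[i] <- cc[ix[1], ix[2]]
    cc[ix[1], ] <- -1
    cc[, ix[2]] <- -1
  }
  got
}

randomGrid <- function(shape = c(6L, 5L, 4L), voxelSize = c(2, 2, 2)) {
  VolumeGrid(shape, voxelSize = voxelSize)
}

randomMask <- function(shape = c(6L, 5L, 4L), p = 0.4, seed = 1L) {
  set.seed(seed)
  d <- array(stats::runif(prod(shape)) < p, dim = shape)
  if (!any(d)) d[1] <- TRUE
  new("MaskVolume", grid = randomGrid(shape), data = d)
}
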