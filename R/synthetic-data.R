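# Seeded generator for trial-wise activity datasets with known latent
# structure: smooth spatial component maps, signed condition loadings, a
# multiplicative per-subject amplitude jitter and i.i.d. Gaussian map noise.
# Every downstream stage (masking, decoding, decomposition) is testable
# against this stated world without any scanner data.

#' Generator configuration
#'
#' Defaults are the emulated study design: 20 subjects x 60 modelled trials
#' (1200 trials), 4 activity maps per trial (4800 maps; the 2400 word-modality
#' maps train the cross-modal classifier, the 2400 picture-modality maps test
#' it), on a 20 x 24 x 20 grid standing in for the 60 x 72 x 60 3 mm space.
#' Signal amplitudes are in arbitrary beta units against unit map noise;
#' `subjectSd = 0.2` gives a realistic 20% between-subject amplitude spread.
#'
#' @param nSubjects,trialsPerSubject,mapsPerTrial design counts;
#'   `trialsPerSubject` must be divisible by 4 (balanced condition cells).
#' @param gridShape integer(3).
#' @param nTrueComponents latent component count (>= 3).
#' @param actionEffect amplitude of the action-signature component (shared by
#'   verbs and implied actions).
#' @param objectEffect amplitude of the object-signature component (common
#'   activation for objects and nouns, common decrease for actions and verbs).
#' @param modalityEffect amplitude of the modality-specific components.
#' @param subjectSd sd of the per-subject, per-component multiplicative
#'   amplitude jitter (mean 1).
#' @param noiseSd sd of the within-map Gaussian noise.
#' @param blobSigma Gaussian blob width in voxels.
#' @param seed integer; fully determines the generated world.
#' @return a [GeneratorConfig-class].
#' @export
generatorConfig <- function(nSubjects = 20L, trialsPerSubject = 60L,
                            mapsPerTrial = 4L, gridShape = c(20L, 24L, 20L),
                            nTrueComponents = 6L, actionEffect = 1.0,
                            objectEffect = 1.0, modalityEffect = 1.5,
                            subjectSd = 0.2, noiseSd = 1.0, blobSigma = 1.5,
                            seed = 1L) {
  new("GeneratorConfig", nSubjects = as.integer(nSubjects),
      trialsPerSubject = as.integer(trialsPerSubject),
      mapsPerTrial = as.integer(mapsPerTrial),
      gridShape = as.integer(gridShape),
      nTrueComponents = as.integer(nTrueComponents),
      actionEffect = actionEffect, objectEffect = objectEffect,
      modalityEffect = modalityEffect, subjectSd = subjectSd,
      noiseSd = noiseSd, blobSigma = blobSigma, seed = as.integer(seed))
}

#' Construct a GroundTruth directly
#'
#' @param componentMaps k x nVoxels matrix (rows are normalized to unit
#'   Euclidean norm).
#' @param loadingMatrix 4 x k signed amplitudes, rows in the order noun, verb,
#'   object, implied_action.
#' @return a [GroundTruth-class].
#' @export
GroundTruth <- function(componentMaps, loadingMatrix) {
  nrm <- sqrt(rowSums(componentMaps^2))
  componentMaps <- componentMaps / ifelse(nrm > 0, nrm, 1)
  rownames(loadingMatrix) <- CONDITIONS
  new("GroundTruth", componentMaps = componentMaps,
      loadingMatrix = loadingMatrix, conditionOrder = CONDITIONS)
}

# Canonical loading matrix for k components:
#   column 1  action signature: verbs and implied actions load +a, nouns and
#             plain objects 0.
#   column 2  object signature: common activation for objects and nouns (+o),
#             common decrease for actions and verbs (-o).
#   column 3+ modality components (word-specific, picture-specific; a single
#             word-vs-picture contrast when k == 3).
#   further columns: condition-independent background amplitude, varying only
#             through the subject jitter.
canonicalLoadings <- function(k, actionEffect, objectEffect, modalityEffect) {
  L <- matrix(0, nrow = 4L, ncol = k,
              dimnames = list(CONDITIONS, NULL))
  cn <- character(k)
  L[, 1] <- c(0, actionEffect, 0, actionEffect)
  cn[1] <- "action_signature"
  L[, 2] <- c(objectEffect, -objectEffect, objectEffect, -objectEffect)
  cn[2] <- "object_signature"
  if (k == 3L) {
    L[, 3] <- modalityEffect * c(1, 1, -1, -1)
    cn[3] <- "modality_contrast"
  } else {
    L[, 3] <- modalityEffect * c(1, 1, 0, 0)
    cn[3] <- "word_modality"
    L[, 4] <- modalityEffect * c(0, 0, 1, 1)
    cn[4] <- "picture_modality"
    if (k > 4L) {
      for (j in 5:k) {
        L[, j] <- 0.5
        cn[j] <- paste0("background_", j - 4L)
      }
    }
  }
  colnames(L) <- cn
  L
}

#' Generate the true component maps and condition loadings
#'
#' Draws `nTrueComponents` spatially smooth, unit-norm Gaussian blobs at
#' seeded random centres (kept mutually distant so pairwise map correlations
#' stay below 0.3) and assembles the canonical signed loading matrix: an
#' action signature shared by verbs and implied actions, an object signature
#' with common activation for objects and nouns and common decrease for
#' actions and verbs, modality-specific components, and background components.
#'
#' @param config a [GeneratorConfig-class].
#' @param mask optional [MaskVolume-class] on the same grid; blob centres are
#'   then drawn from in-mask voxels so the signal lies inside the search
#'   space.
#' @return a [GroundTruth-class]; deterministic given `config@seed`.
#' @export
makeGroundTruth <- function(config, mask = NULL) {
  sh <- config@gridShape
  V <- prod(sh)
  if (V < 200L)
    stop("grid too small to place distinct smooth blobs (need >= 200 voxels)")
  k <- config@nTrueComponents
  if (k < 3L) stop("nTrueComponents must be >= 3")
  if (!is.null(mask) && !identical(gridShape(mask), sh))
    stop("mask grid does not match config grid")

  set.seed(stageSeed(config@seed, "ground_truth"))
  coords <- cbind(
    rep.int(seq_len(sh[1]), sh[2] * sh[3]),
    rep.int(rep(seq_len(sh[2]), each = sh[1]), sh[3]),
    rep(seq_len(sh[3]), each = sh[1] * sh[2]))
  candidates <- if (is.null(mask)) {
    inner <- coords[, 1] > 1 & coords[, 1] < sh[1] &
             coords[, 2] > 1 & coords[, 2] < sh[2] &
             coords[, 3] > 1 & coords[, 3] < sh[3]
    which(if (any(inner)) inner else rep(TRUE, V))
  } else which(as.vector(mask@data))

  sigma <- config@blobSigma
  minSep <- 2.4 * sigma         # keeps blob overlap correlation ~ 0.24;
                                # the explicit |r| < 0.3 check below guards
  centers <- matrix(NA_real_, nrow = k, ncol = 3L)
  placed <- 0L
  for (restart in seq_len(25L)) {   # greedy placement can dead-end; restart
    placed <- 0L
    for (try in seq_len(400L)) {
      cand <- coords[candidates[sample.int(length(candidates), 1L)], ]
      if (placed == 0L ||
          all(sqrt(rowSums(sweep(centers[seq_len(placed), , drop = FALSE],
                                 2, cand)^2)) >= minSep)) {
        placed <- placed + 1L
        centers[placed, ] <- cand
        if (placed == k) break
      }
    }
    if (placed == k) break
  }
  if (placed < k)
    stop("grid too small to place ", k, " distinct smooth blobs")

  maps <- matrix(0, nrow = k, ncol = V)
  for (j in seq_len(k)) {
    d2 <- (coords[, 1] - centers[j, 1])^2 + (coords[, 2] - centers[j, 2])^2 +
          (coords[, 3] - centers[j, 3])^2
    m <- exp(-d2 / (2 * sigma^2))
    maps[j, ] <- m / sqrt(sum(m^2))
  }
  cc <- stats::cor(t(maps))
  if (any(abs(cc[upper.tri(cc)]) >= 0.3))
    stop("could not place spatially distinct components (|r| >= 0.3)")

  L <- canonicalLoadings(k, config@actionEffect, config@objectEffect,
                         config@modalityEffect)
  rownames(maps) <- colnames(L)
  GroundTruth(maps, L)
}

#' Construct an ActivityDataset from a feature matrix and labels
#'
#' @param features nMaps x nVoxels matrix of beta values.
#' @param condition per-map condition in noun/verb/object/implied_action;
#'   modality and the binary action label are derived from it.
#' @param subject,trial per-map identifiers; all maps of a trial must share
#'   one condition.
#' @param grid optional [VolumeGrid-class] stored in the metadata.
#' @return an [ActivityDataset-class].
#' @export
ActivityDataset <- function(features, condition, subject, trial, grid = NULL) {
  condition <- as.character(condition)
  cd <- S4Vectors::DataFrame(
    condition = condition,
    modality = conditionModality(condition),
    subject = as.character(subject),
    trial = as.character(trial),
    binary_label = conditionBinary(condition))
  rownames(cd) <- sprintf("map_%05d", seq_len(nrow(features)))
  betas <- t(features)
  colnames(betas) <- rownames(cd)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(betas = betas), colData = cd,
    metadata = if (is.null(grid)) list() else list(grid = grid))
  new("ActivityDataset", se)
}

#' Simulate a trial-wise activity dataset
#'
#' Each trial draws one condition; its signal is the condition's loading row
#' (jittered per subject) times the component maps, and each of the trial's
#' `mapsPerTrial` maps adds independent Gaussian noise to that shared signal.
#' Conditions are balanced within subject, and modality follows condition
#' (words are noun/verb trials, pictures object/implied-action trials).
#'
#' @param config a [GeneratorConfig-class].
#' @param truth a [GroundTruth-class] on the same grid (voxel counts must
#'   match), e.g. from [makeGroundTruth()].
#' @return an [ActivityDataset-class] with
#'   `nSubjects * trialsPerSubject * mapsPerTrial` maps.
#' @export
simulateDataset <- function(config, truth) {
  V <- prod(config@gridShape)
  if (ncol(truth@componentMaps) != V)
    stop("truth grid does not match config grid (voxel counts differ)")
  k <- nrow(truth@componentMaps)
  if (k != config@nTrueComponents)
    stop("truth component count does not match config")

  nS <- config@nSubjects; nT <- config@trialsPerSubject
  nM <- config@mapsPerTrial
  nTrials <- nS * nT
  nMapsTotal <- nTrials * nM

  set.seed(stageSeed(config@seed, "simulate"))
  subjects <- sprintf("s%02d", seq_len(nS))
  jitter <- matrix(stats::rnorm(nS * k, mean = 1, sd = config@subjectSd),
                   nrow = nS, ncol = k, dimnames = list(subjects, NULL))

  trialCondition <- character(nTrials)
  trialSubject <- character(nTrials)
  trialId <- character(nTrials)
  for (s in seq_len(nS)) {
    idx <- (s - 1L) * nT + seq_len(nT)
    trialCondition[idx] <- sample(rep(CONDITIONS, nT / 4L))
    trialSubject[idx] <- subjects[s]
    trialId[idx] <- sprintf("%s_t%03d", subjects[s], seq_len(nT))
  }

  condIdx <- match(trialCondition, CONDITIONS)
  scores <- truth@loadingMatrix[condIdx, , drop = FALSE] *
    jitter[match(trialSubject, subjects), , drop = FALSE]
  trialSignal <- scores %*% truth@componentMaps       # nTrials x V

  mapTrial <- rep(seq_len(nTrials), each = nM)
  X <- trialSignal[mapTrial, , drop = FALSE]
  if (config@noiseSd > 0)
    X <- X + stats::rnorm(length(X), sd = config@noiseSd)

  ActivityDataset(X,
    condition = trialCondition[mapTrial],
    subject = trialSubject[mapTrial],
    trial = trialId[mapTrial],
    grid = mniGrid(config@gridShape))
}

#' Write / read an ActivityDataset as NIfTI + TSV sidecar
#'
#' The feature matrix is stored as a 4-D NIfTI volume on the dataset's grid
#' (one 3-D map per trial map) and the labels as a tab-delimited sidecar with
#' header columns map_index, trial, subject, condition, modality,
#' binary_label.
#'
#' @param ds an [ActivityDataset-class] with a grid in its metadata.
#' @param prefix output path prefix; writes `<prefix>.nii.gz` and
#'   `<prefix>_labels.tsv`.
#' @param niiPath,tsvPath the two files written by [writeActivityDataset()].
#' @return `writeActivityDataset`: the two paths, invisibly;
#'   `readActivityDataset`: an [ActivityDataset-class].
#' @export
writeActivityDataset <- function(ds, prefix) {
  grid <- S4Vectors::metadata(ds)$grid
  if (is.null(grid)) stop("dataset has no grid; cannot write volumes")
  X <- featureMatrix(ds)
  if (ncol(X) != prod(grid@shape))
    stop("dataset voxel count does not match its grid (masked features?)")
  vol <- array(t(X), dim = c(grid@shape, nMaps(ds)))
  nii <- paste0(prefix, ".nii.gz")
  tsv <- paste0(prefix, "_labels.tsv")
  writeVolume(grid, vol, nii)
  utils::write.table(
    data.frame(map_index = seq_len(nMaps(ds)), trial = trialIds(ds),
               subject = subjectIds(ds), condition = conditionLabels(ds),
               modality = modalityLabels(ds), binary_label = binaryLabels(ds)),
    tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(nii, tsv))
}

#' @rdname writeActivityDataset
#' @export
readActivityDataset <- function(niiPath, tsvPath) {
  vol <- readVolume(niiPath)
  lab <- utils::read.delim(tsvPath, stringsAsFactors = FALSE)
  need <- c("trial", "subject", "condition")
  miss <- setdiff(need, colnames(lab))
  if (length(miss))
    stop("label TSV is missing columns: ", paste(miss, collapse = ", "))
  vals <- vol$values
  if (length(dim(vals)) == 3L) dim(vals) <- c(dim(vals), 1L)
  if (dim(vals)[4] != nrow(lab))
    stop("number of maps in volume and label rows differ")
  X <- t(matrix(vals, nrow = prod(vol$grid@shape)))
  ActivityDataset(X, condition = lab$condition, subject = lab$subject,
                  trial = lab$trial, grid = vol$grid)
}
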