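#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' VolumeGrid: a 3-D sampling grid with an affine into MNI millimetres
#'
#' Couples a voxel array shape with a 4x4 affine matrix that maps 0-based
#' voxel indices (i, j, k, 1) to MNI coordinates in millimetres. All mask and
#' resampling operations are expressed on such grids.
#'
#' @slot shape integer(3), number of voxels along x, y, z.
#' @slot affine 4x4 numeric matrix; invertible; last row (0, 0, 0, 1).
#' @export
setClass("VolumeGrid",
  representation(shape = "integer", affine = "matrix"),
  validity = function(object) {
    msg <- NULL
    if (length(object@shape) != 3L || any(object@shape < 1L))
      msg <- c(msg, "shape must be 3 positive integers")
    if (!all(dim(object@affine) == c(4L, 4L)))
      msg <- c(msg, "affine must be a 4x4 matrix")
    else {
      if (any(!is.finite(object@affine)))
        msg <- c(msg, "affine must be finite")
      else if (abs(det(object@affine[1:3, 1:3])) < 1e-12)
        msg <- c(msg, "affine must be invertible")
      if (any(voxelSize(object) <= 0))
        msg <- c(msg, "voxel size must be positive")
    }
    if (is.null(msg)) TRUE else msg
  })

#' MaskVolume: a boolean voxel selection on a VolumeGrid
#'
#' @slot grid a [VolumeGrid-class].
#' @slot data logical 3-D array, same shape as the grid.
#' @export
setClass("MaskVolume",
  representation(grid = "VolumeGrid", data = "array"),
  validity = function(object) {
    msg <- NULL
    if (!is.logical(object@data))
      msg <- c(msg, "mask data must be logical")
    if (!identical(dim(object@data), as.integer(object@grid@shape)))
      msg <- c(msg, "mask data shape must equal grid shape")
    if (sum(object@data) < 1L)
      msg <- c(msg, "mask must select at least one voxel")
    if (is.null(msg)) TRUE else msg
  })

#' GeneratorConfig: stated world of the synthetic activity-map generator
#'
#' Defaults mirror the study design the generator emulates: 20 subjects, 60
#' modelled trials each, 4 activity maps per trial (1200 trials, 4800 maps),
#' on a 20x24x20 grid standing in for the 60x72x60 3 mm MNI space.
#'
#' @slot nSubjects,trialsPerSubject,mapsPerTrial design counts.
#' @slot gridShape integer(3) voxel grid.
#' @slot nTrueComponents number of latent spatial components (>= 3).
#' @slot actionEffect,objectEffect,modalityEffect signal amplitudes (beta units).
#' @slot subjectSd sd of the multiplicative per-subject amplitude jitter.
#' @slot noiseSd sd of i.i.d. Gaussian map noise.
#' @slot blobSigma spatial Gaussian width of component blobs, in voxels.
#' @slot seed integer; fully determines the generated world.
#' @export
setClass("GeneratorConfig",
  representation(nSubjects = "integer", trialsPerSubject = "integer",
    mapsPerTrial = "integer", gridShape = "integer",
    nTrueComponents = "integer", actionEffect = "numeric",
    objectEffect = "numeric", modalityEffect = "numeric",
    subjectSd = "numeric", noiseSd = "numeric", blobSigma = "numeric",
    seed = "integer"),
  validity = function(object) {
    msg <- NULL
    counts <- c(object@nSubjects, object@trialsPerSubject, object@mapsPerTrial,
                object@nTrueComponents)
    if (any(counts < 1L)) msg <- c(msg, "all counts must be >= 1")
    if (object@trialsPerSubject %% 4L != 0L)
      msg <- c(msg, "trialsPerSubject must be divisible by 4 (balanced conditions)")
    if (length(object@gridShape) != 3L || any(object@gridShape < 1L))
      msg <- c(msg, "gridShape must be 3 positive integers")
    if (object@noiseSd < 0 || object@subjectSd < 0 || object@blobSigma <= 0)
      msg <- c(msg, "noiseSd/subjectSd must be >= 0 and blobSigma > 0")
    if (is.null(msg)) TRUE else msg
  })

#' GroundTruth: generating components and condition loadings
#'
#' @slot componentMaps k x nVoxels matrix; unit-norm, spatially smooth rows.
#' @slot loadingMatrix 4 x k signed amplitudes; rows in the fixed condition
#'   order noun, verb, object, implied_action.
#' @slot conditionOrder character(4).
#' @export
setClass("GroundTruth",
  representation(componentMaps = "matrix", loadingMatrix = "matrix",
    conditionOrder = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@loadingMatrix) != 4L)
      msg <- c(msg, "loadingMatrix must have 4 condition rows")
    if (ncol(object@loadingMatrix) != nrow(object@componentMaps))
      msg <- c(msg, "loadingMatrix columns must match component count")
    if (!identical(object@conditionOrder, CONDITIONS))
      msg <- c(msg, "conditionOrder must be noun, verb, object, implied_action")
    if (any(!is.finite(object@componentMaps)) ||
        any(!is.finite(object@loadingMatrix)))
      msg <- c(msg, "maps and loadings must be finite")
    if (is.null(msg)) TRUE else msg
  })

#' ActivityDataset: trial-wise activity maps with labels
#'
#' A [SummarizedExperiment-class] whose assay `"betas"` holds voxels (rows) by
#' maps (columns), and whose `colData` carries per-map `condition`,
#' `modality`, `subject`, `trial` and the derived `binary_label`. The source
#' [VolumeGrid-class] lives in `metadata(ds)$grid` when known.
#'
#' @export
setClass("ActivityDataset", contains = "SummarizedExperiment",
  validity = function(object) {
    msg <- NULL
    cd <- SummarizedExperiment::colData(object)
    need <- c("condition", "modality", "subject", "trial", "binary_label")
    miss <- setdiff(need, colnames(cd))
    if (length(miss))
      return(paste("missing colData columns:", paste(miss, collapse = ", ")))
    if (!all(cd$condition %in% CONDITIONS))
      msg <- c(msg, "unknown condition labels")
    if (!identical(as.character(cd$modality),
                   conditionModality(as.character(cd$condition))))
      msg <- c(msg, "modality inconsistent with condition (words are noun/verb, pictures object/implied_action)")
    if (!identical(as.character(cd$binary_label),
                   conditionBinary(as.character(cd$condition))))
      msg <- c(msg, "binary_label inconsistent with condition")
    if (anyNA(SummarizedExperiment::assay(object, "betas")))
      msg <- c(msg, "feature matrix contains missing values")
    percond <- tapply(as.character(cd$condition), as.character(cd$trial),
                      function(z) length(unique(z)))
    if (length(percond) && any(percond != 1L))
      msg <- c(msg, "all maps of a trial must share one condition")
    if (is.null(msg)) TRUE else msg
  })

#' LinearClassifier: a fitted linear decision rule
#'
#' @slot weights numeric feature weights.
#' @slot bias numeric(1) intercept.
#' @slot levels character(2); the decision is `levels[2]` when
#'   `x %*% weights + bias > 0`.
#' @slot loss,cost training loss ("squared_hinge" or "hinge") and C.
#' @export
setClass("LinearClassifier",
  representation(weights = "numeric", bias = "numeric", levels = "character",
    loss = "character", cost = "numeric"))

#' RFETrace: the nested elimination path of recursive feature elimination
#'
#' @slot sizes integer vector of retained-feature counts, strictly decreasing,
#'   starting at the initial feature count.
#' @slot retained list of logical retain-masks, one per size, each nested in
#'   the previous.
#' @slot scores per-step training criterion (grouped cross-validated accuracy).
#' @slot bestStep index of the step with the best score.
#' @export
setClass("RFETrace",
  representation(sizes = "integer", retained = "list", scores = "numeric",
    bestStep = "integer"),
  validity = function(object) {
    msg <- NULL
    if (length(object@sizes) != length(object@retained))
      msg <- c(msg, "one retain-mask per step required")
    if (any(diff(object@sizes) >= 0))
      msg <- c(msg, "sizes must be strictly decreasing")
    for (i in seq_along(object@retained)[-1]) {
      if (any(object@retained[[i]] & !object@retained[[i - 1L]]))
        msg <- c(msg, "retain-sets must be nested"); break
    }
    if (is.null(msg)) TRUE else msg
  })

#' DecodingResult: out-of-sample decoding performance
#'
#' @slot nCorrect,nTotal counts of correct predictions and scored test items.
#' @slot accuracy nCorrect/nTotal.
#' @slot pValue exact binomial tail probability against chance.
#' @slot chance chance level (0.5 for the binary action contrast).
#' @slot selectedFeatures logical retain-mask actually used by the classifier.
#' @slot rfe the [RFETrace-class], or NULL when RFE was disabled.
#' @export
setClass("DecodingResult",
  representation(nCorrect = "integer", nTotal = "integer",
    accuracy = "numeric", pValue = "numeric", chance = "numeric",
    selectedFeatures = "logical", rfe = "ANY"),
  validity = function(object) {
    msg <- NULL
    if (abs(object@accuracy - object@nCorrect / object@nTotal) > 1e-12)
      msg <- c(msg, "accuracy must equal nCorrect/nTotal")
    if (object@pValue < 0 || object@pValue > 1)
      msg <- c(msg, "pValue must be in [0, 1]")
    if (is.null(msg)) TRUE else msg
  })

#' PerturbationSummary: stability of decoding under resampling
#'
#' @slot scheme "jackknife", "bootstrap" or "split_half".
#' @slot nIterations number of refits.
#' @slot accuracies,pValues per-iteration out-of-sample results.
#' @slot meanAccuracy,sdAccuracy,meanP,sdP summary statistics.
#' @export
setClass("PerturbationSummary",
  representation(scheme = "character", nIterations = "integer",
    accuracies = "numeric", pValues = "numeric", meanAccuracy = "numeric",
    sdAccuracy = "numeric", meanP = "numeric", sdP = "numeric"),
  validity = function(object) {
    if (any(object@accuracies < 0 | object@accuracies > 1))
      "accuracies must be in [0, 1]" else TRUE
  })

#' SSFLRConfig: hyperparameters of semi-supervised factored logistic regression
#'
#' Stated values: equally weighted composite (lambda = 0.5), RMSProp with
#' learning rate 1e-4, decay rho 0.9, damping epsilon 1e-6, at most 500
#' epochs, gradient clipping, Gaussian init scaled by gain 0.004, zero biases.
#' Penalty coefficients, clip threshold and batch size are free parameters.
#'
#' @slot nComponents latent dimensionality k (default 10).
#' @slot lambda weight of the classification loss; 1-lambda weighs
#'   reconstruction.
#' @slot l1,l2,ortho penalty coefficients (Elastic Net + latent orthogonality).
#' @slot learningRate,rho,epsilon,maxEpochs,clipNorm,batchSize RMSProp control.
#' @slot gain init scale for Gaussian weights.
#' @slot orthoTarget "latent" penalizes the off-diagonal latent covariance;
#'   "spatial" the off-diagonal Gram matrix of decoder rows.
#' @slot seed integer RNG seed for init and batch order.
#' @export
setClass("SSFLRConfig",
  representation(nComponents = "integer", lambda = "numeric", l1 = "numeric",
    l2 = "numeric", ortho = "numeric", learningRate = "numeric",
    rho = "numeric", epsilon = "numeric", maxEpochs = "integer",
    clipNorm = "numeric", gain = "numeric", batchSize = "integer",
    orthoTarget = "character", seed = "integer"),
  validity = function(object) {
    msg <- NULL
    if (object@nComponents < 1L) msg <- c(msg, "k must be >= 1")
    if (object@lambda < 0 || object@lambda > 1)
      msg <- c(msg, "lambda must be in [0, 1]")
    if (object@l1 < 0 || object@l2 < 0 || object@ortho < 0)
      msg <- c(msg, "penalty coefficients must be >= 0")
    if (object@rho <= 0 || object@rho >= 1) msg <- c(msg, "rho must be in (0, 1)")
    if (!object@orthoTarget %in% c("latent", "spatial"))
      msg <- c(msg, "orthoTarget must be 'latent' or 'spatial'")
    if (is.null(msg)) TRUE else msg
  })

#' SSFLRModel: fitted factored model
#'
#' Linear encoder/decoder (untied) plus a 4-class softmax read-out sharing the
#' latent components.
#'
#' @slot Wenc nVoxels x k encoder weights; @slot benc k encoder biases.
#' @slot Wdec k x nVoxels decoder weights; @slot bdec nVoxels decoder biases.
#' @slot Wcls k x 4 classifier weights; @slot bcls 4 classifier biases.
#' @slot history data.frame, one row per epoch with the loss breakdown.
#' @slot config the [SSFLRConfig-class] used.
#' @export
setClass("SSFLRModel",
  representation(Wenc = "matrix", benc = "numeric", Wdec = "matrix",
    bdec = "numeric", Wcls = "matrix", bcls = "numeric",
    history = "data.frame", config = "SSFLRConfig"),
  validity = function(object) {
    msg <- NULL
    if (ncol(object@Wenc) != nrow(object@Wdec) ||
        nrow(object@Wdec) != nrow(object@Wcls))
      msg <- c(msg, "latent dimensions of encoder/decoder/classifier must agree")
    if (ncol(object@Wcls) != 4L) msg <- c(msg, "classifier must have 4 classes")
    if (nrow(object@history) > object@config@maxEpochs)
      msg <- c(msg, "history cannot exceed maxEpochs")
    if (is.null(msg)) TRUE else msg
  })

#' ComponentReport: spatial components and their condition contributions
#'
#' @slot componentMaps k x nVoxels matrix, z-scored over voxels per component.
#' @slot contributions 4 x k matrix; entry (c, j) is the classifier weight of
#'   component j for condition c scaled by the latent standard deviation of j.
#' @slot conditionOrder character(4).
#' @export
setClass("ComponentReport",
  representation(componentMaps = "matrix", contributions = "matrix",
    conditionOrder = "character"),
  validity = function(object) {
    msg <- NULL
    if (nrow(object@contributions) != 4L)
      msg <- c(msg, "contributions must have 4 condition rows")
    if (ncol(object@contributions) != nrow(object@componentMaps))
      msg <- c(msg, "contribution columns must match component count")
    if (any(!is.finite(object@contributions)))
      msg <- c(msg, "contributions must be finite")
    if (is.null(msg)) TRUE else msg
  })
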