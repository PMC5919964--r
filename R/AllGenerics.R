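#' @include AllClasses.R
NULL

#' Accessors for CrossDecode classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' map/voxel counts and label columns of an [ActivityDataset-class], geometry
#' of a [VolumeGrid-class]/[MaskVolume-class], and result fields of a
#' [DecodingResult-class].
#'
#' @param x,object an object of the documented class.
#' @name accessors
#' @aliases nMaps nVoxels featureMatrix conditionLabels modalityLabels
#'   subjectIds trialIds binaryLabels voxelSize gridShape gridAffine
#'   maskData nVoxelsIn accuracy pValue componentMaps contributions
#'   loadingMatrix lossHistory
NULL

#' @rdname accessors
#' @export
setGeneric("nMaps", function(x) standardGeneric("nMaps"))
#' @rdname accessors
#' @export
setGeneric("nVoxels", function(x) standardGeneric("nVoxels"))
#' @rdname accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname accessors
#' @export
setGeneric("conditionLabels", function(x) standardGeneric("conditionLabels"))
#' @rdname accessors
#' @export
setGeneric("modalityLabels", function(x) standardGeneric("modalityLabels"))
#' @rdname accessors
#' @export
setGeneric("subjectIds", function(x) standardGeneric("subjectIds"))
#' @rdname accessors
#' @export
setGeneric("trialIds", function(x) standardGeneric("trialIds"))
#' @rdname accessors
#' @export
setGeneric("binaryLabels", function(x) standardGeneric("binaryLabels"))
#' @rdname accessors
#' @export
setGeneric("voxelSize", function(x) standardGeneric("voxelSize"))
#' @rdname accessors
#' @export
setGeneric("gridShape", function(x) standardGeneric("gridShape"))
#' @rdname accessors
#' @export
setGeneric("gridAffine", function(x) standardGeneric("gridAffine"))
#' @rdname accessors
#' @export
setGeneric("maskData", function(x) standardGeneric("maskData"))
#' @rdname accessors
#' @export
setGeneric("nVoxelsIn", function(x) standardGeneric("nVoxelsIn"))
#' @rdname accessors
#' @export
setGeneric("accuracy", function(x) standardGeneric("accuracy"))
#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setGeneric("componentMaps", function(x) standardGeneric("componentMaps"))
#' @rdname accessors
#' @export
setGeneric("contributions", function(x) standardGeneric("contributions"))
#' @rdname accessors
#' @export
setGeneric("loadingMatrix", function(x) standardGeneric("loadingMatrix"))
#' @rdname accessors
#' @export
setGeneric("lossHistory", function(x) standardGeneric("lossHistory"))

#' Split a dataset into word-modality training and picture-modality test parts
#'
#' @param ds an [ActivityDataset-class] containing both modalities.
#' @return a list with elements `train` (word maps) and `test` (picture maps);
#'   their union is the input and their intersection empty.
#' @export
setGeneric("splitByModality", function(ds) standardGeneric("splitByModality"))

# ---- methods ---------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("voxelSize", "VolumeGrid", function(x)
  sqrt(colSums(x@affine[1:3, 1:3]^2)))
#' @rdname accessors
#' @export
setMethod("gridShape", "VolumeGrid", function(x) x@shape)
#' @rdname accessors
#' @export
setMethod("gridAffine", "VolumeGrid", function(x) x@affine)
#' @rdname accessors
#' @export
setMethod("gridShape", "MaskVolume", function(x) x@grid@shape)
#' @rdname accessors
#' @export
setMethod("gridAffine", "MaskVolume", function(x) x@grid@affine)
#' @rdname accessors
#' @export
setMethod("maskData", "MaskVolume", function(x) x@data)
#' @rdname accessors
#' @export
setMethod("nVoxelsIn", "MaskVolume", function(x) sum(x@data))

#' @rdname accessors
#' @export
setMethod("nMaps", "ActivityDataset", function(x) ncol(x))
#' @rdname accessors
#' @export
setMethod("nVoxels", "ActivityDataset", function(x) nrow(x))
#' @rdname accessors
#' @export
setMethod("featureMatrix", "ActivityDataset", function(x)
  t(SummarizedExperiment::assay(x, "betas")))
#' @rdname accessors
#' @export
setMethod("conditionLabels", "ActivityDataset", function(x)
  as.character(SummarizedExperiment::colData(x)$condition))
#' @rdname accessors
#' @export
setMethod("modalityLabels", "ActivityDataset", function(x)
  as.character(SummarizedExperiment::colData(x)$modality))
#' @rdname accessors
#' @export
setMethod("subjectIds", "ActivityDataset", function(x)
  as.character(SummarizedExperiment::colData(x)$subject))
#' @rdname accessors
#' @export
setMethod("trialIds", "ActivityDataset", function(x)
  as.character(SummarizedExperiment::colData(x)$trial))
#' @rdname accessors
#' @export
setMethod("binaryLabels", "ActivityDataset", function(x)
  as.character(SummarizedExperiment::colData(x)$binary_label))

#' @rdname accessors
#' @export
setMethod("accuracy", "DecodingResult", function(x) x@accuracy)
#' @rdname accessors
#' @export
setMethod("pValue", "DecodingResult", function(x) x@pValue)
#' @rdname accessors
#' @export
setMethod("accuracy", "PerturbationSummary", function(x) x@accuracies)

#' @rdname accessors
#' @export
setMethod("componentMaps", "GroundTruth", function(x) x@componentMaps)
#' @rdname accessors
#' @export
setMethod("loadingMatrix", "GroundTruth", function(x) x@loadingMatrix)
#' @rdname accessors
#' @export
setMethod("componentMaps", "ComponentReport", function(x) x@componentMaps)
#' @rdname accessors
#' @export
setMethod("contributions", "ComponentReport", function(x) x@contributions)
#' @rdname accessors
#' @export
setMethod("lossHistory", "SSFLRModel", function(x) x@history)

# ---- show ------------------------------------------------------------------

setMethod("show", "VolumeGrid", function(object) {
  cat("VolumeGrid:", paste(object@shape, collapse = " x "), "voxels,",
      paste(sprintf("%.3g", voxelSize(object)), collapse = " x "), "mm\n")
})

setMethod("show", "MaskVolume", function(object) {
  cat("MaskVolume:", nVoxelsIn(object), "of", prod(gridShape(object)),
      "voxels selected on a", paste(gridShape(object), collapse = " x "),
      "grid\n")
})

setMethod("show", "ActivityDataset", function(object) {
  cat("ActivityDataset:", nMaps(object), "maps x", nVoxels(object),
      "voxels\n")
  cat("  subjects:", length(unique(subjectIds(object))),
      " trials:", length(unique(trialIds(object))), "\n")
  tab <- table(conditionLabels(object))
  cat("  conditions:", paste(names(tab), tab, sep = "=", collapse = ", "),
      "\n")
})

setMethod("show", "GroundTruth", function(object) {
  cat("GroundTruth:", nrow(object@componentMaps), "components x",
      ncol(object@componentMaps), "voxels\n")
  print(round(object@loadingMatrix, 3))
})

setMethod("show", "DecodingResult", function(object) {
  cat(sprintf("DecodingResult: %d/%d correct (%.2f%%), chance %.0f%%, p = %.3g\n",
              object@nCorrect, object@nTotal, 100 * object@accuracy,
              100 * object@chance, object@pValue))
  if (!is.null(object@rfe))
    cat("  RFE sizes:", paste(object@rfe@sizes, collapse = " -> "),
        sprintf("(best step %d: %d features)\n", object@rfe@bestStep,
                object@rfe@sizes[object@rfe@bestStep]))
})

setMethod("show", "PerturbationSummary", function(object) {
  cat(sprintf("PerturbationSummary [%s]: %d iterations, accuracy %.2f +/- %.2f%%, p %.3g +/- %.3g\n",
              object@scheme, object@nIterations, 100 * object@meanAccuracy,
              100 * object@sdAccuracy, object@meanP, object@sdP))
})

setMethod("show", "SSFLRModel", function(object) {
  cat("SSFLRModel:", nrow(object@Wenc), "voxels ->", ncol(object@Wenc),
      "components -> 4 classes;", nrow(object@history), "epochs trained\n")
  if (nrow(object@history))
    cat(sprintf("  final loss %.5g (recon %.5g, class %.5g)\n",
                utils::tail(object@history$total, 1),
                utils::tail(object@history$reconstruction, 1),
                utils::tail(object@history$classification, 1)))
})

setMethod("show", "ComponentReport", function(object) {
  cat("ComponentReport:", nrow(object@componentMaps), "component maps x",
      ncol(object@componentMaps), "voxels\n")
  print(round(object@contributions, 3))
})
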