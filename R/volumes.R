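# Mask construction, grid resampling, masked feature extraction and
# train-fitted standardization.

# mm coordinates of every voxel centre of a grid, as an nVoxels x 3 matrix in
# array (column-major) order.
gridCoordinates <- function(grid) {
  sh <- grid@shape
  idx <- cbind(
    rep.int(seq_len(sh[1]) - 1L, sh[2] * sh[3]),
    rep.int(rep(seq_len(sh[2]) - 1L, each = sh[1]), sh[3]),
    rep(seq_len(sh[3]) - 1L, each = sh[1] * sh[2]))
  sweep(idx %*% t(grid@affine[1:3, 1:3]), 2, grid@affine[1:3, 4], `+`)
}

#' Resample a volume onto a target grid
#'
#' Pulls values from the source grid at each target voxel centre via the two
#' affines. `"nearest"` keeps the source value set (so binary masks stay
#' binary); `"linear"` is trilinear interpolation. Target voxels outside the
#' source field of view become zero; if the fields of view do not overlap at
#' all, a warning is raised and an all-zero volume returned.
#'
#' @param srcGrid,srcValues source [VolumeGrid-class] and 3-D array.
#' @param target target [VolumeGrid-class].
#' @param mode `"linear"` or `"nearest"`.
#' @return 3-D array with the target shape.
#' @export
resampleToGrid <- function(srcGrid, srcValues, target,
                           mode = c("linear", "nearest")) {
  mode <- match.arg(mode)
  if (!identical(as.integer(dim(srcValues)), srcGrid@shape))
    stop("srcValues shape does not match srcGrid")
  mm <- gridCoordinates(target)
  inv <- solve(srcGrid@affine)
  sidx <- sweep(mm %*% t(inv[1:3, 1:3]), 2, inv[1:3, 4], `+`)  # 0-based
  sh <- srcGrid@shape
  out <- numeric(nrow(sidx))
  if (mode == "nearest") {
    r <- round(sidx)
    ok <- r[, 1] >= 0 & r[, 1] <= sh[1] - 1 &
          r[, 2] >= 0 & r[, 2] <= sh[2] - 1 &
          r[, 3] >= 0 & r[, 3] <= sh[3] - 1
    lin <- 1 + r[ok, 1] + sh[1] * (r[ok, 2] + sh[2] * r[ok, 3])
    out[ok] <- srcValues[lin]
  } else {
    f <- floor(sidx)
    w <- sidx - f
    ok <- f[, 1] >= -1 & f[, 1] <= sh[1] - 1 &
          f[, 2] >= -1 & f[, 2] <= sh[2] - 1 &
          f[, 3] >= -1 & f[, 3] <= sh[3] - 1
    acc <- numeric(sum(ok))
    fo <- f[ok, , drop = FALSE]; wo <- w[ok, , drop = FALSE]
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      cx <- fo[, 1] + dx; cy <- fo[, 2] + dy; cz <- fo[, 3] + dz
      wt <- (if (dx) wo[, 1] else 1 - wo[, 1]) *
            (if (dy) wo[, 2] else 1 - wo[, 2]) *
            (if (dz) wo[, 3] else 1 - wo[, 3])
      inb <- cx >= 0 & cx <= sh[1] - 1 & cy >= 0 & cy <= sh[2] - 1 &
             cz >= 0 & cz <= sh[3] - 1
      lin <- 1 + cx[inb] + sh[1] * (cy[inb] + sh[2] * cz[inb])
      acc[inb] <- acc[inb] + wt[inb] * srcValues[lin]
    }
    out[ok] <- acc
  }
  if (all(out == 0) && any(srcValues != 0))
    warning("source and target fields of view do not overlap; returning zeros")
  array(out, dim = target@shape)
}

#' Gray-matter mask from a tissue-probability volume
#'
#' A voxel enters the analysis when its gray-matter tissue probability is at
#' least `threshold` (default 10%).
#'
#' @param grid a [VolumeGrid-class].
#' @param probValues 3-D array of tissue probabilities in `[0, 1]`.
#' @param threshold inclusion threshold.
#' @return a [MaskVolume-class].
#' @export
grayMatterMask <- function(grid, probValues, threshold = 0.10) {
  if (any(probValues < 0 | probValues > 1, na.rm = TRUE))
    stop("tissue probabilities must lie in [0, 1]")
  sel <- !is.na(probValues) & probValues >= threshold
  if (!any(sel))
    stop("gray-matter mask is empty at threshold ", threshold)
  new("MaskVolume", grid = grid, data = array(sel, dim = grid@shape))
}

#' Build a search-space mask from a peak coordinate table
#'
#' Stands in for unpublished meta-analytic cluster extents: the mask is the
#' union of spheres of `radiusMm` around each peak MNI coordinate,
#' intersected with the target grid. Peaks outside the grid's field of view
#' contribute nothing (with a warning).
#'
#' @param peaks data.frame with columns `x`, `y`, `z` (MNI mm); typically a
#'   [readPeakTable()] result.
#' @param radiusMm sphere radius in millimetres (> 0).
#' @param target a [VolumeGrid-class].
#' @return a [MaskVolume-class].
#' @export
buildMaskFromPeaks <- function(peaks, radiusMm = 6, target) {
  stopifnot(radiusMm > 0)
  if (!all(c("x", "y", "z") %in% colnames(peaks)))
    stop("peaks must have columns x, y, z")
  mm <- gridCoordinates(target)
  lo <- apply(mm, 2, min); hi <- apply(mm, 2, max)
  sel <- rep(FALSE, nrow(mm))
  for (i in seq_len(nrow(peaks))) {
    p <- as.numeric(peaks[i, c("x", "y", "z")])
    if (any(p < lo - radiusMm) || any(p > hi + radiusMm)) {
      warning("peak (", paste(p, collapse = ", "),
              ") lies outside the grid field of view; skipped")
      next
    }
    d2 <- (mm[, 1] - p[1])^2 + (mm[, 2] - p[2])^2 + (mm[, 3] - p[3])^2
    sel <- sel | d2 <= radiusMm^2
  }
  if (!any(sel)) stop("no voxel falls inside any peak sphere")
  new("MaskVolume", grid = target, data = array(sel, dim = target@shape))
}

#' Read a tab-separated peak table
#'
#' Expected columns: `cluster_id`, `cluster_size` (voxels), `x`, `y`, `z`
#' (peak MNI mm). Extra columns are kept.
#'
#' @param path TSV file with a header row.
#' @return a data.frame.
#' @export
readPeakTable <- function(path) {
  tab <- utils::read.delim(path, comment.char = "#",
                           stringsAsFactors = FALSE)
  need <- c("cluster_id", "cluster_size", "x", "y", "z")
  miss <- setdiff(need, colnames(tab))
  if (length(miss))
    stop("peak table is missing columns: ", paste(miss, collapse = ", "))
  if (any(!is.finite(as.matrix(tab[, c("x", "y", "z")]))))
    stop("peak coordinates must be finite")
  if (any(tab$cluster_size < 1)) stop("cluster sizes must be >= 1")
  tab
}

#' Extract masked features from a stack of maps / re-insert them
#'
#' `extractFeatures` turns a 3-D volume or 4-D stack into an nMaps x nVoxelsIn
#' feature matrix (masked voxels in array order); `insertFeatures` embeds such
#' a matrix back into full volumes, zero outside the mask. The two are exact
#' inverses on the masked voxels.
#'
#' @param values 3-D array or 4-D stack with the mask's grid shape.
#' @param mat nMaps x nVoxelsIn matrix (or a vector for one map).
#' @param mask a [MaskVolume-class].
#' @return a matrix for `extractFeatures`; a 4-D array (x, y, z, nMaps) for
#'   `insertFeatures` (3-D if a single vector was given).
#' @export
extractFeatures <- function(values, mask) {
  sh <- gridShape(mask)
  dv <- dim(values)
  if (length(dv) == 3L) dv <- c(dv, 1L)
  if (length(dv) != 4L || !identical(as.integer(dv[1:3]), sh))
    stop("map grid does not equal mask grid")
  m <- matrix(values, nrow = prod(sh))
  t(m[as.vector(mask@data), , drop = FALSE])
}

#' @rdname extractFeatures
#' @export
insertFeatures <- function(mat, mask) {
  single <- is.null(dim(mat))
  if (single) mat <- matrix(mat, nrow = 1L)
  sh <- gridShape(mask)
  if (ncol(mat) != nVoxelsIn(mask))
    stop("feature count does not match mask voxel count")
  out <- matrix(0, nrow = prod(sh), ncol = nrow(mat))
  out[as.vector(mask@data), ] <- t(mat)
  if (single) array(out, dim = sh) else array(out, dim = c(sh, nrow(mat)))
}

#' Standardize features with training-set statistics
#'
#' Mean-centres and unit-variance scales every voxel column using statistics
#' estimated on the training matrix only; the test matrix is transformed with
#' those same training means and standard deviations, never its own. The
#' population (divide-by-n) variance estimator is used. Columns constant in
#' training carry no information and are set to all-zeros in both outputs.
#'
#' @param train,test numeric matrices with matching columns (`test` may be
#'   NULL).
#' @return list with `train`, `test`, `means`, `sds`.
#' @export
standardizeTrainTest <- function(train, test = NULL) {
  if (nrow(train) < 2L) stop("training matrix needs at least 2 rows")
  if (!is.null(test) && ncol(test) != ncol(train))
    stop("train and test must have the same columns")
  mu <- colMeans(train)
  sds <- colSdPop(train)
  zero <- sds <= 0
  sdsAdj <- ifelse(zero, 1, sds)
  scaleMat <- function(x) {
    x <- sweep(x, 2, mu, `-`)
    x <- sweep(x, 2, sdsAdj, `/`)
    if (any(zero)) x[, zero] <- 0
    x
  }
  list(train = scaleMat(train),
       test = if (is.null(test)) NULL else scaleMat(test),
       means = mu, sds = sds)
}

#' @rdname splitByModality
#' @export
setMethod("splitByModality", "ActivityDataset", function(ds) {
  mod <- modalityLabels(ds)
  if (length(unique(mod)) < 2L)
    stop("both modalities must be present to split")
  list(train = ds[, mod == "word"], test = ds[, mod == "picture"])
})
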