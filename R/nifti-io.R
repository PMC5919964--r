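# Minimal NIfTI-1 single-file (.nii / .nii.gz) reader and writer.
#
# No NIfTI package ships with this R stack, so the format is handled directly:
# the 348-byte header, little- or big-endian, the common scalar datatypes,
# sform/qform affines and 3-D or 4-D data. Volumes are reoriented to canonical
# RAS+ axes on load whenever the affine is axis-aligned up to permutation and
# flips (oblique affines are kept as stored, with a warning).

NIFTI_DTYPES <- list(
  `2`   = list(what = "integer", size = 1L, signed = FALSE),  # uint8
  `4`   = list(what = "integer", size = 2L, signed = TRUE),   # int16
  `8`   = list(what = "integer", size = 4L, signed = TRUE),   # int32
  `16`  = list(what = "numeric", size = 4L, signed = TRUE),   # float32
  `64`  = list(what = "numeric", size = 8L, signed = TRUE),   # float64
  `256` = list(what = "integer", size = 1L, signed = TRUE),   # int8
  `512` = list(what = "integer", size = 2L, signed = FALSE))  # uint16

#' Construct a VolumeGrid
#'
#' @param shape integer(3) voxel counts per axis.
#' @param affine 4x4 voxel-index (0-based) to MNI mm affine. If omitted, an
#'   RAS+ diagonal affine with the given voxel size centred like the MNI
#'   bounding box is used.
#' @param voxelSize mm per axis, used only when `affine` is missing.
#' @return a [VolumeGrid-class].
#' @export
VolumeGrid <- function(shape, affine = NULL, voxelSize = c(3, 3, 3)) {
  shape <- as.integer(shape)
  if (is.null(affine)) {
    affine <- diag(4)
    affine[cbind(1:3, 1:3)] <- voxelSize
    affine[1:3, 4] <- -voxelSize * (shape - 1) / 2
  }
  new("VolumeGrid", shape = shape, affine = unname(affine))
}

#' MNI-like grid covering the standard bounding box
#'
#' The full 60 x 72 x 60 grid of 3 mm isotropic voxels spans the 180 x 216 x
#' 180 mm MNI field of view starting at (-90, -126, -72). Any other shape
#' yields the proportionally scaled stand-in grid over the same field of view
#' (e.g. the default synthetic 20 x 24 x 20 grid has 9 mm voxels).
#'
#' @param shape integer(3); default the full-resolution grid.
#' @return a [VolumeGrid-class] with a diagonal RAS+ affine.
#' @export
mniGrid <- function(shape = c(60L, 72L, 60L)) {
  shape <- as.integer(shape)
  vs <- c(180, 216, 180) / shape
  affine <- diag(4)
  affine[cbind(1:3, 1:3)] <- vs
  affine[1:3, 4] <- c(-90, -126, -72)
  new("VolumeGrid", shape = shape, affine = affine)
}

#' Read a NIfTI-1 volume
#'
#' Reads a single-file NIfTI-1 image (optionally gzip-compressed), applies any
#' stored value scaling, and reorients the data to canonical RAS+ axes when
#' the affine permits.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @param reorient reorder axes to RAS+ when the affine is axis-aligned.
#' @return a list with `grid` (a [VolumeGrid-class]) and `values` (3-D array,
#'   or 4-D for multi-map files).
#' @export
readVolume <- function(path, reorient = TRUE) {
  con <- gzfile(path, "rb")
  on.exit(close(con))
  sz <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  endian <- "little"
  if (!identical(sz, 348L)) {
    swapped <- readBin(writeBin(sz, raw(), size = 4L, endian = "big"),
                       "integer", 1L, size = 4L, endian = "little")
    if (identical(swapped, 348L)) endian <- "big"
    else stop("not a NIfTI-1 file (bad header size): ", path)
  }
  readBin(con, "raw", 36L)                                   # unused fields
  hdim <- readBin(con, "integer", 8L, size = 2L, endian = endian)
  readBin(con, "numeric", 3L, size = 4L, endian = endian)    # intent params
  readBin(con, "integer", 1L, size = 2L, endian = endian)    # intent code
  datatype <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  readBin(con, "integer", 2L, size = 2L, endian = endian)    # bitpix, slice
  pixdim <- readBin(con, "numeric", 8L, size = 4L, endian = endian)
  voxOffset <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  sclSlope <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  sclInter <- readBin(con, "numeric", 1L, size = 4L, endian = endian)
  readBin(con, "raw", 132L)                                  # to qform_code
  qformCode <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  sformCode <- readBin(con, "integer", 1L, size = 2L, endian = endian)
  quat <- readBin(con, "numeric", 6L, size = 4L, endian = endian)
  srow <- matrix(readBin(con, "numeric", 12L, size = 4L, endian = endian),
                 nrow = 3L, byrow = TRUE)
  readBin(con, "raw", 16L)                                   # intent_name
  magic <- rawToChar(readBin(con, "raw", 4L)[1:3])
  if (!magic %in% c("n+1", "ni1"))
    stop("not a NIfTI-1 file (bad magic): ", path)
  if (identical(magic, "ni1"))
    stop("two-file NIfTI-1 (.hdr/.img) is not supported: ", path)

  ndim <- hdim[1]
  if (ndim < 3L || ndim > 4L)
    stop("only 3-D and 4-D NIfTI volumes are supported (got ", ndim, "-D)")
  shape <- pmax(hdim[2:(ndim + 1L)], 1L)
  dt <- NIFTI_DTYPES[[as.character(datatype)]]
  if (is.null(dt)) stop("unsupported NIfTI datatype code: ", datatype)

  skip <- voxOffset - 348
  if (skip > 0) readBin(con, "raw", as.integer(skip))
  n <- prod(shape)
  vals <- readBin(con, dt$what, n, size = dt$size, signed = dt$signed,
                  endian = endian)
  vals <- as.double(vals)
  if (length(vals) < n) stop("truncated NIfTI data in ", path)
  if (is.finite(sclSlope) && sclSlope != 0 &&
      !(sclSlope == 1 && sclInter == 0))
    vals <- vals * sclSlope + sclInter

  affine <- if (sformCode > 0L) {
    rbind(srow, c(0, 0, 0, 1))
  } else if (qformCode > 0L) {
    qformAffine(quat, pixdim)
  } else {
    a <- diag(4); a[cbind(1:3, 1:3)] <- abs(pixdim[2:4]); a
  }
  if (any(!is.finite(affine)))
    stop("NIfTI affine contains non-finite entries: ", path)

  values <- array(vals, dim = shape)
  grid <- new("VolumeGrid", shape = as.integer(shape[1:3]), affine = affine)
  if (reorient) {
    ras <- reorientRAS(grid, values)
    grid <- ras$grid; values <- ras$values
  }
  list(grid = grid, values = values)
}

# qform quaternion (b, c, d, qoffset xyz) + pixdim -> affine; qfac in pixdim[1].
qformAffine <- function(quat, pixdim) {
  b <- quat[1]; c <- quat[2]; d <- quat[3]
  a <- sqrt(max(0, 1 - b^2 - c^2 - d^2))
  R <- matrix(c(
    a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d),   2 * (b * d + a * c),
    2 * (b * c + a * d),   a^2 + c^2 - b^2 - d^2, 2 * (c * d - a * b),
    2 * (b * d - a * c),   2 * (c * d + a * b),   a^2 + d^2 - b^2 - c^2),
    nrow = 3L, byrow = TRUE)
  qfac <- if (pixdim[1] < 0) -1 else 1
  R <- R %*% diag(c(pixdim[2], pixdim[3], qfac * pixdim[4]))
  rbind(cbind(R, quat[4:6]), c(0, 0, 0, 1))
}

# Reorder/flip voxel axes so the affine becomes RAS+ (positive, axis-aligned
# dominant directions). Works on 3-D or 4-D arrays (4th axis untouched).
reorientRAS <- function(grid, values) {
  A <- grid@affine
  R <- A[1:3, 1:3]
  worldAxis <- apply(abs(R), 2, which.max)
  if (anyDuplicated(worldAxis)) {
    warning("oblique affine; volume orientation left as stored")
    return(list(grid = grid, values = values))
  }
  shape <- grid@shape
  # flip axes with negative dominant direction
  for (j in 1:3) {
    if (R[worldAxis[j], j] < 0) {
      idx <- rep(list(quote(expr = )), length(dim(values)))
      idx[[j]] <- shape[j]:1
      values <- do.call(`[`, c(list(values), idx, list(drop = FALSE)))
      A[, 4] <- A[, 4] + A[, j] * (shape[j] - 1)
      A[, j] <- -A[, j]
    }
  }
  # permute so voxel axis i follows world axis i
  perm <- order(worldAxis)
  if (!identical(perm, 1:3)) {
    fullPerm <- c(perm, seq_along(dim(values))[-(1:3)])
    values <- aperm(values, fullPerm)
    A[, 1:3] <- A[, perm]
    shape <- shape[perm]
  } else shape <- grid@shape
  list(grid = new("VolumeGrid", shape = as.integer(dim(values)[1:3]),
                  affine = A),
       values = values)
}

#' Write a NIfTI-1 volume
#'
#' Writes a 3-D array (or a 4-D stack of maps) as a single-file NIfTI-1 image,
#' float64 data, little-endian, with the grid affine stored as sform (code 2)
#' and qform left unset.
#'
#' @param grid a [VolumeGrid-class].
#' @param values numeric array whose first three dimensions equal the grid
#'   shape; a 4th dimension holds multiple maps.
#' @param path output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
writeVolume <- function(grid, values, path) {
  values <- as.array(values)
  nd <- length(dim(values))
  if (nd == 2L || nd > 4L) stop("values must be a 3-D or 4-D array")
  if (!identical(as.integer(dim(values)[1:3]), grid@shape))
    stop("values shape does not match grid shape")
  vs <- voxelSize(grid)
  dims <- c(nd, dim(values), rep(1L, 7L - nd))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  w <- function(x, size, what = "integer")
    writeBin(if (what == "integer") as.integer(x) else as.numeric(x),
             con, size = size, endian = "little")
  w(348L, 4L)                                    # sizeof_hdr
  writeBin(raw(36L), con)                        # data_type..dim_info
  w(dims, 2L)                                    # dim[8]
  w(c(0, 0, 0), 4L, "numeric")                   # intent params
  w(0L, 2L)                                      # intent_code
  w(64L, 2L); w(64L, 2L)                         # datatype float64, bitpix
  w(0L, 2L)                                      # slice_start
  w(c(1, vs, rep(1, 4)), 4L, "numeric")          # pixdim (qfac 1)
  w(352, 4L, "numeric")                          # vox_offset
  w(c(1, 0), 4L, "numeric")                      # scl_slope, scl_inter
  w(0L, 2L); writeBin(raw(1L), con)              # slice_end, slice_code
  writeBin(as.raw(10L), con)                     # xyzt_units: mm + s
  w(c(0, 0, 0, 0), 4L, "numeric")                # cal/slice_duration/toffset
  w(c(0L, 0L), 4L)                               # glmax, glmin
  writeBin(raw(104L), con)                       # descrip + aux_file
  w(c(0L, 2L), 2L)                               # qform_code 0, sform_code 2
  w(rep(0, 6), 4L, "numeric")                    # quaternion + qoffset
  w(t(grid@affine[1:3, ]), 4L, "numeric")        # srow_x, srow_y, srow_z
  writeBin(raw(16L), con)                        # intent_name
  writeBin(c(charToRaw("n+1"), raw(1L)), con)    # magic
  writeBin(raw(4L), con)                         # extension flag
  writeBin(as.numeric(values), con, size = 8L, endian = "little")
  invisible(path)
}
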