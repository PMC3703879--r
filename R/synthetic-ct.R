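#' @include bone-geometry.R
NULL

## Synthetic Hounsfield-unit volumes and threshold segmentation, standing in
## for a multislice-CT acquisition of the bone segment.

#' Hounsfield-unit voxel volume
#'
#' @slot voxels 3D numeric array of HU values
#' @slot spacing_mm per-axis voxel size
#' @slot origin_mm position of the centre of voxel (1,1,1)
#' @export
setClass("HUVolume", representation(
  voxels = "array", spacing_mm = "numeric", origin_mm = "numeric"
), validity = function(object) {
  if (any(object@spacing_mm <= 0)) return("spacing must be positive")
  if (any(!is.finite(object@voxels))) return("HU values must be finite")
  TRUE
})

#' Tissue label volume
#'
#' @slot labels 3D character array over soft / trabecular / cortical
#' @slot thresholds the HU thresholds used (provenance)
#' @export
setClass("TissueLabelVolume", representation(
  labels = "array", thresholds = "numeric"))

## cell-centred voxel coordinate grids for a bone segment (centres offset by
## half a voxel so that flat model surfaces never coincide with a centre
## plane, which would bias volume fractions)
.voxelGrid <- function(bone, spacing) {
  W <- bone@crest_width_mm / 2 + 1.5 + spacing
  L <- bone@mesiodistal_length_mm / 2 + spacing
  H <- bone@crest_height_mm
  half <- seq(spacing / 2, W, by = spacing)
  xs <- c(-rev(half), half)
  halfy <- seq(spacing / 2, L, by = spacing)
  ys <- c(-rev(halfy), halfy)
  zs <- seq(-H - spacing / 2, spacing, by = spacing)
  list(x = xs, y = ys, z = zs)
}

#' Generate a synthetic HU volume of the bone segment
#'
#' Voxels take class means of 1200 HU (cortical shell), 400 HU (trabecular
#' core) and 0 HU (exterior / soft tissue), evaluated at voxel centres from
#' the analytic bone model, plus optional Gaussian noise.  Deterministic for
#' a fixed seed.
#'
#' @param bone a \code{\link{boneSegmentSpec}}
#' @param noise_sd HU noise standard deviation (>= 0)
#' @param seed RNG seed
#' @param spacing_mm isotropic voxel size
#' @param means named HU class means (soft, trabecular, cortical)
#' @return an \code{\link{HUVolume}}
#' @examples
#' vol <- generateHUVolume(boneSegmentSpec(), noise_sd = 0, spacing_mm = 1)
#' range(vol@voxels)
#' @export
generateHUVolume <- function(bone, noise_sd = 30, seed = 1L, spacing_mm = 0.5,
                             means = c(soft = 0, trabecular = 400,
                                       cortical = 1200)) {
  stopifnot(noise_sd >= 0)
  if (spacing_mm > bone@cortical_thickness_mm)
    warning("voxel spacing exceeds the cortical thickness; the shell may alias")
  solid <- buildBoneSegment(bone)
  g <- .voxelGrid(bone, spacing_mm)
  dims <- c(length(g$x), length(g$y), length(g$z))
  xx <- rep(g$x, times = dims[2] * dims[3])
  yy <- rep(rep(g$y, each = dims[1]), times = dims[3])
  zz <- rep(g$z, each = dims[1] * dims[2])
  tis <- solid@tissueFun(xx, yy, zz)
  hu <- means[ifelse(tis == "outside", "soft", tis)]
  if (noise_sd > 0) {
    set.seed(as.integer(seed))
    hu <- hu + rnorm(length(hu), 0, noise_sd)
  }
  new("HUVolume", voxels = array(unname(hu), dims), spacing_mm = rep(spacing_mm, 3),
      origin_mm = c(g$x[1], g$y[1], g$z[1]))
}

#' Threshold segmentation of an HU volume
#'
#' Labels follow the standard bone windows: soft tissue for HU <= soft_max,
#' cancellous (trabecular) bone for soft_max < HU <= trabecular_max, cortical
#' bone for HU > trabecular_max.  Defaults 150 and 750 HU.  Upper bounds are
#' inclusive for the trabecular class.
#'
#' @param vol an \code{\link{HUVolume}}
#' @param soft_max soft-tissue upper bound (inclusive)
#' @param trabecular_max trabecular upper bound (inclusive)
#' @return a \code{\link{TissueLabelVolume}}
#' @examples
#' v <- new("HUVolume", voxels = array(c(150, 150.5, 750, 751), c(4, 1, 1)),
#'          spacing_mm = c(1, 1, 1), origin_mm = c(0, 0, 0))
#' segmentHU(v)@labels[, 1, 1]
#' @export
segmentHU <- function(vol, soft_max = 150, trabecular_max = 750) {
  stopifnot(soft_max < trabecular_max)
  hu <- vol@voxels
  lab <- array("soft", dim(hu))
  lab[hu > soft_max & hu <= trabecular_max] <- "trabecular"
  lab[hu > trabecular_max] <- "cortical"
  new("TissueLabelVolume", labels = lab,
      thresholds = c(soft_max = soft_max, trabecular_max = trabecular_max))
}

#' Volume fraction of a label
#' @param seg a \code{\link{TissueLabelVolume}}
#' @param label label name
#' @return fraction of voxels carrying the label
#' @export
labelFraction <- function(seg, label) mean(seg@labels == label)

#' Export an HU volume to NIfTI
#'
#' Requires the RNifti package.
#'
#' @param vol an \code{\link{HUVolume}}
#' @param path output file (.nii or .nii.gz)
#' @return the path, invisibly
#' @export
writeHUVolume <- function(vol, path) {
  if (!requireNamespace("RNifti", quietly = TRUE))
    stop("RNifti is required for NIfTI export")
  img <- RNifti::asNifti(vol@voxels, pixdim = vol@spacing_mm)
  RNifti::writeNifti(img, path)
  invisible(path)
}
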