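#' @import methods
NULL

#' Access the voxel array of an image stack
#'
#' @param x An [ImageStack-class] object.
#' @return A numeric array with dimensions rows x cols x slices.
#' @export
setGeneric("voxels", function(x) standardGeneric("voxels"))

#' Physical pixel size in micrometers
#'
#' @param x An [ImageStack-class] object.
#' @return Scalar pixel edge length in micrometers.
#' @export
setGeneric("pixelSizeUm", function(x) standardGeneric("pixelSizeUm"))

#' Axial step between slices in micrometers
#'
#' @param x An [ImageStack-class] object.
#' @return Scalar z step in micrometers.
#' @export
setGeneric("zStepUm", function(x) standardGeneric("zStepUm"))

#' Number of slices in a stack
#'
#' @param x An [ImageStack-class] object.
#' @return Integer slice count.
#' @export
setGeneric("nSlices", function(x) standardGeneric("nSlices"))

#' Extract one slice of a stack as a matrix
#'
#' @param x An [ImageStack-class] object.
#' @param i Slice index (1-based).
#' @return A rows x cols numeric matrix.
#' @export
setGeneric("getSlice", function(x, i) standardGeneric("getSlice"))

#' Crop a stack to a rectangular region of interest
#'
#' @param x An [ImageStack-class] object.
#' @param roi An [RoiRect-class] region.
#' @return An [ImageStack-class] with extent equal to the ROI; intensities
#'   are carried over unchanged.
#' @export
setGeneric("cropStack", function(x, roi) standardGeneric("cropStack"))

#' Mean area fraction (density) of a gridded image
#'
#' The density parameter is the arithmetic mean of the per-cell SHG area
#' fractions over the whole grid; it lies in \[0, 1\].
#'
#' @param x An [AreaFractionMap-class] object.
#' @return Scalar density in \[0, 1\].
#' @export
setGeneric("densityIndex", function(x) standardGeneric("densityIndex"))

#' Per-label counts of a cell classification grid
#'
#' @param x An [OrientationMap-class] object.
#' @return Named integer vector with elements `anisotropic`, `isotropic`
#'   and `dark`, summing to the number of grid cells.
#' @export
setGeneric("countClasses", function(x) standardGeneric("countClasses"))

#' Coherence-weighted preferred orientation of a classified grid
#'
#' Axial (mod-180) circular mean of the per-cell fiber orientations of the
#' anisotropic cells, weighted by structure-tensor coherence.
#'
#' @param x An [OrientationMap-class] object.
#' @return Angle in degrees in \[0, 180), or `NA` if no cell is anisotropic.
#' @export
setGeneric("preferredOrientation", function(x) standardGeneric("preferredOrientation"))
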