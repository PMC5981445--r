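#' ImageStack: a 3-D grayscale raster with physical metadata
#'
#' Container for a z-stack of grayscale images. Voxels are stored as a
#' numeric array with dimensions rows x cols x slices; intensities are
#' nonnegative and in arbitrary units. Physical metadata record the lateral
#' pixel size and the axial step, both in micrometers (a typical SHG
#' acquisition covers a 100 x 100 um field with a 0.5 um z step).
#'
#' @slot voxels Numeric array, rows x cols x slices, all values >= 0.
#' @slot pixelSizeUm Lateral pixel edge length in micrometers (> 0).
#' @slot zStepUm Axial slice spacing in micrometers (> 0).
#'
#' @seealso [imageStack()], [readStack()], [writeStack()], [cropStack()]
#' @export
setClass("ImageStack",
  representation(voxels = "array", pixelSizeUm = "numeric", zStepUm = "numeric"),
  validity = function(object) {
    v <- object@voxels
    if (length(dim(v)) != 3L)
      return("voxels must be a 3-D array (rows x cols x slices)")
    if (dim(v)[3L] < 1L) return("at least one slice is required")
    if (dim(v)[1L] < 16L || dim(v)[2L] < 16L)
      return("image extent must be at least 16 x 16 pixels")
    if (anyNA(v) || any(v < 0)) return("intensities must be nonnegative and finite")
    if (length(object@pixelSizeUm) != 1L || object@pixelSizeUm <= 0)
      return("pixelSizeUm must be a positive scalar")
    if (length(object@zStepUm) != 1L || object@zStepUm <= 0)
      return("zStepUm must be a positive scalar")
    TRUE
  }
)

#' Construct an ImageStack
#'
#' @param voxels A rows x cols x slices numeric array, or a single matrix
#'   (promoted to a one-slice stack). All values must be nonnegative.
#' @param pixelSizeUm Lateral pixel size in micrometers.
#' @param zStepUm Axial step in micrometers.
#' @return An [ImageStack-class] object.
#' @examples
#' s <- imageStack(matrix(0, 32, 32), pixelSizeUm = 0.2)
#' nSlices(s)
#' @export
imageStack <- function(voxels, pixelSizeUm = 1, zStepUm = 0.5) {
  if (is.matrix(voxels)) voxels <- array(voxels, dim = c(dim(voxels), 1L))
  new("ImageStack", voxels = voxels, pixelSizeUm = as.numeric(pixelSizeUm),
      zStepUm = as.numeric(zStepUm))
}

#' GridSpec: square analysis grid over an image
#'
#' The grid partitions an image into square cells of `cellPx` pixels
#' (16 by default, the scale at which the SHG area fraction is computed).
#' Partial cells at the right/bottom edge are dropped, never padded.
#'
#' @slot cellPx Cell edge length in pixels (>= 2).
#' @slot handling Edge rule; only `"drop"` is implemented.
#' @export
setClass("GridSpec",
  representation(cellPx = "integer", handling = "character"),
  validity = function(object) {
    if (object@cellPx < 2L) return("cellPx must be >= 2")
    if (!identical(object@handling, "drop"))
      return("only handling = 'drop' is supported")
    TRUE
  }
)

#' Construct a GridSpec
#'
#' @param cellPx Cell edge length in pixels; default 16.
#' @param handling Partial-edge-cell rule; `"drop"`.
#' @return A [GridSpec-class] object.
#' @export
gridSpec <- function(cellPx = 16L, handling = "drop")
  new("GridSpec", cellPx = as.integer(cellPx), handling = handling)

#' RoiRect: rectangular region of interest
#'
#' Pixel offsets are 0-based and the extent is half-open on both axes,
#' so the ROI covers rows `row0 .. row0 + height - 1` (1-based rows
#' `row0 + 1 .. row0 + height`). The spectral parameters are computed on
#' such a selected region.
#'
#' @slot row0,col0 0-based offsets of the top-left corner.
#' @slot height,width Extent in pixels (each >= 16).
#' @export
setClass("RoiRect",
  representation(row0 = "integer", col0 = "integer",
                 height = "integer", width = "integer"),
  validity = function(object) {
    if (object@row0 < 0L || object@col0 < 0L) return("offsets must be >= 0")
    if (object@height < 16L || object@width < 16L)
      return("ROI extent must be at least 16 x 16")
    TRUE
  }
)

#' Construct an RoiRect
#'
#' @param row0,col0 0-based pixel offsets of the top-left corner.
#' @param height,width Extent in pixels, each at least 16.
#' @return An [RoiRect-class] object.
#' @export
roiRect <- function(row0, col0, height, width)
  new("RoiRect", row0 = as.integer(row0), col0 = as.integer(col0),
      height = as.integer(height), width = as.integer(width))

#' AreaFractionMap: per-cell SHG area fractions
#'
#' For each grid cell, the fraction of pixels strictly above the noise
#' threshold, in \[0, 1\]; 0 means no SHG signal in the cell, 1 means every
#' pixel carries signal. The grid mean is the density parameter, see
#' [densityIndex()].
#'
#' @slot values Numeric matrix of cell fractions in \[0, 1\].
#' @slot cellPx Cell size used (pixels).
#' @slot noiseThreshold Intensity cutoff used.
#' @export
setClass("AreaFractionMap",
  representation(values = "matrix", cellPx = "integer", noiseThreshold = "numeric"),
  validity = function(object) {
    v <- object@values
    if (length(v) < 1L) return("empty map")
    if (anyNA(v) || any(v < 0) || any(v > 1)) return("fractions must lie in [0, 1]")
    TRUE
  }
)

#' MagnitudeSpectrum: centered 2-D Fourier magnitude
#'
#' Magnitude of the 2-D discrete Fourier transform of a real image, shifted
#' so the zero-frequency (DC) term sits at the geometric center
#' `(floor(nrow/2) + 1, floor(ncol/2) + 1)`. When `dcExcluded` the center
#' value has been set to 0 before any downstream use; a constant input then
#' yields an identically zero spectrum, flagged via `degenerate`.
#'
#' @slot amplitude Nonnegative numeric matrix.
#' @slot dcExcluded Logical; was the DC term zeroed.
#' @slot center Integer (row, col) of the DC bin.
#' @slot degenerate Logical; TRUE when the spectrum is identically zero.
#' @export
setClass("MagnitudeSpectrum",
  representation(amplitude = "matrix", dcExcluded = "logical",
                 center = "integer", degenerate = "logical"),
  validity = function(object) {
    if (anyNA(object@amplitude) || any(object@amplitude < 0))
      return("amplitudes must be nonnegative")
    if (length(object@center) != 2L) return("center must be (row, col)")
    TRUE
  }
)

#' AngularProfile: radially integrated spectrum strength versus angle
#'
#' For each angular bin in \[0, 180) degrees, the sum of spectral amplitudes
#' sampled along the ray at that angle. The profile maximum is the peak
#' spectral intensity, see [peakSpectralIntensity()].
#'
#' @slot angles Bin centers in degrees, in \[0, 180).
#' @slot strength Nonnegative integrated amplitude per bin.
#' @slot rRange Radial range (pixels) integrated over.
#' @export
setClass("AngularProfile",
  representation(angles = "numeric", strength = "numeric", rRange = "integer"),
  validity = function(object) {
    if (length(object@angles) < 36L) return("at least 36 angular bins are required")
    if (length(object@angles) != length(object@strength))
      return("angles and strength lengths differ")
    if (anyNA(object@strength) || any(object@strength < 0))
      return("strengths must be nonnegative")
    if (any(object@angles < 0 | object@angles >= 180))
      return("angles must lie in [0, 180)")
    TRUE
  }
)

#' EllipseFit: equivalent ellipse of a binarized spectrum
#'
#' Full major/minor axis lengths (alpha, beta) of the ellipse with the same
#' second central moments as the set of true pixels of a binary mask; the
#' anisotropy ratio is r = alpha / beta >= 1.
#'
#' @slot alpha Full major-axis length (spectrum pixels).
#' @slot beta Full minor-axis length.
#' @slot orientationDeg Major-axis angle, degrees in \[0, 180).
#' @slot ratio alpha / beta.
#' @export
setClass("EllipseFit",
  representation(alpha = "numeric", beta = "numeric",
                 orientationDeg = "numeric", ratio = "numeric"),
  validity = function(object) {
    if (object@beta <= 0) return("beta must be positive")
    if (object@alpha < object@beta) return("alpha must be >= beta")
    if (object@ratio < 1) return("ratio must be >= 1")
    TRUE
  }
)

#' OrientationMap: three-way cell classification with fiber orientation
#'
#' Per grid cell: a label (`anisotropic`, `isotropic` or `dark`), the
#' structure-tensor coherence in \[0, 1\], the mean intensity, and — for
#' anisotropic cells only — the preferred fiber orientation in degrees
#' (counterclockwise from the +x/column axis, mod 180).
#'
#' @slot labels Character matrix of cell labels.
#' @slot orientationDeg Numeric matrix; NA except for anisotropic cells.
#' @slot coherence Numeric matrix in \[0, 1\].
#' @slot meanIntensity Numeric matrix.
#' @slot cellPx Cell size used (pixels).
#' @export
setClass("OrientationMap",
  representation(labels = "matrix", orientationDeg = "matrix",
                 coherence = "matrix", meanIntensity = "matrix", cellPx = "integer"),
  validity = function(object) {
    ok <- c("anisotropic", "isotropic", "dark")
    if (!all(object@labels %in% ok))
      return("labels must be anisotropic/isotropic/dark")
    if (!identical(dim(object@labels), dim(object@orientationDeg)) ||
        !identical(dim(object@labels), dim(object@coherence)))
      return("component matrices must share one shape")
    hasOri <- !is.na(object@orientationDeg)
    if (any(hasOri != (object@labels == "anisotropic")))
      return("orientation must be present iff the cell is anisotropic")
    coh <- object@coherence[object@labels != "dark"]
    if (any(coh < -1e-9 | coh > 1 + 1e-9, na.rm = TRUE))
      return("coherence must lie in [0, 1]")
    TRUE
  }
)

#' StackSummary: stack-averaged quantitative parameters
#'
#' The three image parameters — density `Id`, peak spectral intensity `Is`
#' and spectral anisotropy ratio `r` — measured on every slice of a z-stack
#' and averaged across slices. Per-slice values are retained.
#'
#' @slot Id Mean density over slices, in \[0, 1\].
#' @slot Is Mean peak spectral intensity.
#' @slot r Mean ellipse axis ratio (>= 1).
#' @slot nSlices Number of slices averaged.
#' @slot perSlice data.frame with columns slice, Id, Is, r.
#' @export
setClass("StackSummary",
  representation(Id = "numeric", Is = "numeric", r = "numeric",
                 nSlices = "integer", perSlice = "data.frame"),
  validity = function(object) {
    if (object@Id < 0 || object@Id > 1) return("Id must lie in [0, 1]")
    if (object@r < 1) return("r must be >= 1")
    if (object@nSlices < 1L) return("nSlices must be >= 1")
    TRUE
  }
)

#' GroupComparison: two-group summary with Student's t test
#'
#' Group summaries (mean, sample SD, n of percent changes) together with the
#' pooled-variance two-tailed Student t statistic, its degrees of freedom
#' `n_a + n_b - 2`, and the two-tailed p value.
#'
#' @slot meanA,sdA,nA Summary of group A.
#' @slot meanB,sdB,nB Summary of group B.
#' @slot t Test statistic.
#' @slot df Degrees of freedom.
#' @slot p Two-tailed p value in \[0, 1\].
#' @slot method `"pooled"` or `"welch"`.
#' @slot degenerate TRUE when both SDs are zero with unequal means.
#' @export
setClass("GroupComparison",
  representation(meanA = "numeric", sdA = "numeric", nA = "integer",
                 meanB = "numeric", sdB = "numeric", nB = "integer",
                 t = "numeric", df = "numeric", p = "numeric",
                 method = "character", degenerate = "logical"),
  validity = function(object) {
    if (object@sdA < 0 || object@sdB < 0) return("SDs must be >= 0")
    if (object@nA < 2L || object@nB < 2L) return("each group needs n >= 2")
    if (object@p < 0 || object@p > 1) return("p must lie in [0, 1]")
    TRUE
  }
)

## ---- show methods ----

setMethod("show", "ImageStack", function(object) {
  d <- dim(object@voxels)
  cat(sprintf("ImageStack: %d x %d px, %d slice(s)\n", d[1], d[2], d[3]))
  cat(sprintf("  pixel size %.4g um, z step %.4g um (field %.3g x %.3g x %.3g um)\n",
              object@pixelSizeUm, object@zStepUm,
              d[1] * object@pixelSizeUm, d[2] * object@pixelSizeUm,
              (d[3] - 1) * object@zStepUm))
  cat(sprintf("  intensity range [%.4g, %.4g]\n",
              min(object@voxels), max(object@voxels)))
})

setMethod("show", "AreaFractionMap", function(object) {
  d <- dim(object@values)
  cat(sprintf("AreaFractionMap: %d x %d cells of %d px, threshold %.4g\n",
              d[1], d[2], object@cellPx, object@noiseThreshold))
  cat(sprintf("  density Id = %.4f\n", mean(object@values)))
})

setMethod("show", "MagnitudeSpectrum", function(object) {
  cat(sprintf("MagnitudeSpectrum: %d x %d, DC %s%s\n",
              nrow(object@amplitude), ncol(object@amplitude),
              if (object@dcExcluded) "excluded" else "included",
              if (object@degenerate) " [degenerate: all-zero]" else ""))
})

setMethod("show", "AngularProfile", function(object) {
  pk <- peakSpectralIntensity(object)
  cat(sprintf("AngularProfile: %d bins over [0, 180), radii %d..%d\n",
              length(object@angles), object@rRange[1], object@rRange[2]))
  cat(sprintf("  peak spectral intensity Is = %.6g at %.1f deg\n",
              pk$Is, pk$angleDeg))
})

setMethod("show", "EllipseFit", function(object) {
  cat(sprintf("EllipseFit: alpha %.3f, beta %.3f, ratio r = %.4f at %.1f deg\n",
              object@alpha, object@beta, object@ratio, object@orientationDeg))
})

setMethod("show", "OrientationMap", function(object) {
  n <- countClasses(object)
  cat(sprintf("OrientationMap: %d x %d cells of %d px\n",
              nrow(object@labels), ncol(object@labels), object@cellPx))
  cat(sprintf("  anisotropic %d, isotropic %d, dark %d\n",
              n["anisotropic"], n["isotropic"], n["dark"]))
})

setMethod("show", "StackSummary", function(object) {
  cat(sprintf("StackSummary over %d slice(s): Id = %.4f, Is = %.6g, r = %.4f\n",
              object@nSlices, object@Id, object@Is, object@r))
})

setMethod("show", "GroupComparison", function(object) {
  cat(sprintf("GroupComparison (%s t test)\n", object@method))
  cat(sprintf("  A: %.4g +/- %.4g (n = %d)   B: %.4g +/- %.4g (n = %d)\n",
              object@meanA, object@sdA, object@nA,
              object@meanB, object@sdB, object@nB))
  cat(sprintf("  t = %.4g, df = %.4g, p = %s%s\n",
              object@t, object@df, formatPValue(object@p),
              if (object@degenerate) " [degenerate]" else ""))
})

## ---- basic accessors ----

#' @rdname voxels
#' @export
setMethod("voxels", "ImageStack", function(x) x@voxels)

#' @rdname pixelSizeUm
#' @export
setMethod("pixelSizeUm", "ImageStack", function(x) x@pixelSizeUm)

#' @rdname zStepUm
#' @export
setMethod("zStepUm", "ImageStack", function(x) x@zStepUm)

#' @rdname nSlices
#' @export
setMethod("nSlices", "ImageStack", function(x) dim(x@voxels)[3L])

#' @rdname getSlice
#' @export
setMethod("getSlice", "ImageStack", function(x, i) {
  stopifnot(i >= 1L, i <= dim(x@voxels)[3L])
  x@voxels[, , i]
})

#' Dimensions of an ImageStack
#'
#' @param x An [ImageStack-class].
#' @return Integer vector (rows, cols, slices).
#' @export
setMethod("dim", "ImageStack", function(x) dim(x@voxels))

#' Cell values of an AreaFractionMap
#'
#' @param x An [AreaFractionMap-class].
#' @return Numeric matrix of per-cell fractions.
#' @export
afValues <- function(x) {
  stopifnot(is(x, "AreaFractionMap"))
  x@values
}

#' @rdname densityIndex
#' @export
setMethod("densityIndex", "AreaFractionMap", function(x) mean(x@values))

#' @describeIn AngularProfile-class Coerce an angular profile to a
#'   data.frame with columns `angleDeg` and `strength`.
#' @param x An [AngularProfile-class] object.
#' @param ... Ignored.
#' @export
as.data.frame.AngularProfile <- function(x, ...)
  data.frame(angleDeg = x@angles, strength = x@strength)

#' @describeIn OrientationMap-class Coerce a classification grid to a long
#'   data.frame with one row per cell.
#' @param x An [OrientationMap-class] object.
#' @param ... Ignored.
#' @export
as.data.frame.OrientationMap <- function(x, ...) {
  d <- dim(x@labels)
  data.frame(cellRow = rep(seq_len(d[1]), d[2]),
             cellCol = rep(seq_len(d[2]), each = d[1]),
             label = as.vector(x@labels),
             orientationDeg = as.vector(x@orientationDeg),
             coherence = as.vector(x@coherence),
             meanIntensity = as.vector(x@meanIntensity))
}
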