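#' Estimate the noise-level intensity threshold of an image
#'
#' The area fraction counts pixels above the noise level; this chooses that
#' level. Two methods are available:
#' \describe{
#'   \item{`"fixed"`}{returns `value` unchanged;}
#'   \item{`"background-percentile"`}{the `p`-th percentile of all
#'     intensities plus `k` times the median absolute deviation
#'     (`k = 3` by default). With the default `p = 50` this is the robust
#'     median + 3 MAD rule: background pixels dominate typical SHG frames,
#'     so the median sits in the background mode and the MAD measures its
#'     spread.}
#' }
#'
#' @param image Numeric matrix of nonnegative intensities.
#' @param method `"background-percentile"` (default) or `"fixed"`.
#' @param value Threshold returned by the fixed method.
#' @param p Percentile in (0, 100) for the background method.
#' @param k MAD multiplier for the background method.
#' @return Nonnegative scalar threshold.
#' @examples
#' estimateNoiseThreshold(matrix(0, 32, 32))            # 0
#' estimateNoiseThreshold(matrix(1, 32, 32), "fixed", value = 10)
#' @export
estimateNoiseThreshold <- function(image,
                                   method = c("background-percentile", "fixed"),
                                   value = NULL, p = 50, k = 3) {
  method <- match.arg(method)
  if (length(image) == 0L) stop("empty image")
  if (method == "fixed") {
    if (is.null(value)) stop("method 'fixed' requires a value")
    return(as.numeric(value))
  }
  if (p <= 0 || p >= 100) stop("percentile must lie strictly between 0 and 100")
  base <- as.numeric(stats::quantile(image, p / 100, names = FALSE))
  max(0, base + k * stats::mad(image))
}

#' Per-cell SHG area fraction on a square grid
#'
#' The image is tiled with `cellPx` x `cellPx` cells (partial edge cells
#' dropped) and, per cell, the number of pixels strictly above `threshold`
#' divided by `cellPx^2` is recorded — a value in \[0, 1\], where 0 means
#' the cell holds no signal and 1 means every pixel does.
#'
#' @param image Numeric matrix.
#' @param grid A [GridSpec-class]; default 16-px cells.
#' @param threshold Intensity noise level; pixels must exceed it strictly.
#' @return An [AreaFractionMap-class].
#' @seealso [densityIndex()] for the grid-mean density parameter.
#' @export
areaFractionMap <- function(image, grid = gridSpec(), threshold = 0) {
  stopifnot(is.matrix(image), is(grid, "GridSpec"))
  c2 <- as.numeric(grid@cellPx)^2
  vals <- blockSums((image > threshold) * 1, grid@cellPx) / c2
  new("AreaFractionMap", values = vals, cellPx = grid@cellPx,
      noiseThreshold = as.numeric(threshold))
}
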