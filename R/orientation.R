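#' Classify grid cells as anisotropic, isotropic or dark
#'
#' Image-gradient (structure tensor) orientation analysis on a square grid.
#' Per cell:
#' \enumerate{
#'   \item cells whose mean intensity falls below `darkThresh` carry little
#'     or no signal and are labelled `dark`;
#'   \item otherwise intensity gradients are taken with Gaussian-derivative
#'     kernels (scale `sigma`, default 1 px) and the structure tensor — the
#'     outer product of the gradient smoothed (summed) over the cell — is
#'     formed. Its coherence `(l1 - l2) / (l1 + l2)` measures how strongly
#'     oriented the texture is: near 1 for parallel fibers, near 0 for
#'     isotropic texture. Cells at or above `coherenceThresh` are
#'     `anisotropic`, the rest `isotropic`;
#'   \item for anisotropic cells the preferred fiber orientation is the
#'     eigenvector of the smaller eigenvalue (fibers run perpendicular to
#'     the dominant intensity gradient), in degrees counterclockwise from
#'     the +x (column) axis, mod 180.
#' }
#' A constant bright cell has zero gradient everywhere; its coherence is
#' defined as 0 and it is labelled isotropic.
#'
#' @param image Numeric matrix, at least one full grid cell.
#' @param grid A [GridSpec-class]; default 16-px cells.
#' @param darkThresh Mean-intensity cutoff for dark cells. Defaults to the
#'   image's estimated noise threshold, see [estimateNoiseThreshold()].
#' @param coherenceThresh Coherence cutoff in (0, 1); default 0.5.
#' @param sigma Gaussian-derivative scale in pixels; default 1.
#' @return An [OrientationMap-class].
#' @seealso [countClasses()], [preferredOrientation()]
#' @export
classifyCells <- function(image, grid = gridSpec(),
                          darkThresh = estimateNoiseThreshold(image),
                          coherenceThresh = 0.5, sigma = 1) {
  stopifnot(is.matrix(image), is(grid, "GridSpec"))
  if (coherenceThresh <= 0 || coherenceThresh >= 1)
    stop("coherenceThresh must lie strictly in (0, 1)")
  g <- gaussianGradients(image, sigma)
  cp <- grid@cellPx
  Jxx <- blockSums(g$gx * g$gx, cp)
  Jyy <- blockSums(g$gy * g$gy, cp)
  Jxy <- blockSums(g$gx * g$gy, cp)
  meanI <- blockSums(image, cp) / as.numeric(cp)^2

  tr <- Jxx + Jyy
  disc <- sqrt((Jxx - Jyy)^2 + 4 * Jxy^2)
  ## cells with (numerically) zero gradient energy are isotropic by
  ## definition; the floor is set by the image intensity scale, so FFT
  ## round-off in the convolution never masquerades as structure
  eps <- (1e-8 * max(image, 1))^2 * as.numeric(cp)^2
  coherence <- ifelse(tr > eps, disc / tr, 0)
  ## dominant gradient direction, then + 90 deg for the fiber axis
  gradAngle <- 0.5 * atan2(2 * Jxy, Jxx - Jyy) * 180 / pi
  fiberAngle <- (gradAngle + 90) %% 180

  labels <- matrix("isotropic", nrow(Jxx), ncol(Jxx))
  labels[coherence >= coherenceThresh] <- "anisotropic"
  labels[meanI < darkThresh] <- "dark"
  ori <- fiberAngle
  ori[labels != "anisotropic"] <- NA_real_
  coherence[labels == "dark"] <- NA_real_
  new("OrientationMap", labels = labels, orientationDeg = ori,
      coherence = coherence, meanIntensity = meanI, cellPx = cp)
}

## Gaussian-derivative gradient fields; gy points along +y (up), so the
## row-wise derivative is negated (rows grow downward).
gaussianGradients <- function(image, sigma = 1) {
  r <- max(1L, ceiling(3 * sigma))
  t <- seq.int(-r, r)
  g <- exp(-t^2 / (2 * sigma^2)); g <- g / sum(g)
  dg <- -t / sigma^2 * exp(-t^2 / (2 * sigma^2))
  ## filter2 correlates; dg along columns for d/dx, along rows for d/d(row)
  kx <- outer(g, dg)     # rows: smoothing, cols: derivative
  ky <- outer(dg, g)
  gx <- EBImage::filter2(image, kx, boundary = "replicate")
  gRow <- EBImage::filter2(image, ky, boundary = "replicate")
  list(gx = gx, gy = -gRow)
}

#' @rdname countClasses
#' @export
setMethod("countClasses", "OrientationMap", function(x) {
  c(anisotropic = sum(x@labels == "anisotropic"),
    isotropic = sum(x@labels == "isotropic"),
    dark = sum(x@labels == "dark"))
})

#' @rdname preferredOrientation
#' @export
setMethod("preferredOrientation", "OrientationMap", function(x) {
  sel <- x@labels == "anisotropic"
  if (!any(sel)) return(NA_real_)
  axialMean(x@orientationDeg[sel], w = x@coherence[sel])
})
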