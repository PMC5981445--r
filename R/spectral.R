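#' Centered 2-D Fourier magnitude spectrum of an image region
#'
#' Computes `|FFT2(img)|`, shifted so the zero-frequency (DC) bin sits at
#' the geometric center. By default the DC term is then set to zero
#' (`dcExcluded`): the mean intensity would otherwise dominate both the
#' angular profile and the binarized-spectrum ellipse. A constant image
#' with DC excluded yields an identically zero spectrum; this is flagged in
#' the returned object (`degenerate`), not raised as an error.
#'
#' @param img Numeric matrix, at least 16 x 16.
#' @param window `"none"` (default) or `"hann"`; a Hann taper suppresses
#'   edge leakage at the cost of resolution.
#' @param dcExcluded Zero the DC bin before downstream use; default TRUE.
#' @return A [MagnitudeSpectrum-class].
#' @export
magnitudeSpectrum <- function(img, window = c("none", "hann"), dcExcluded = TRUE) {
  window <- match.arg(window)
  stopifnot(is.matrix(img))
  if (nrow(img) < 16L || ncol(img) < 16L) stop("region must be at least 16 x 16")
  if (window == "hann") {
    wr <- 0.5 * (1 - cos(2 * pi * (seq_len(nrow(img)) - 1) / (nrow(img) - 1)))
    wc <- 0.5 * (1 - cos(2 * pi * (seq_len(ncol(img)) - 1) / (ncol(img) - 1)))
    img <- img * outer(wr, wc)
  }
  amp <- fftShift(Mod(stats::fft(img)))
  ctr <- as.integer(c(floor(nrow(img) / 2) + 1L, floor(ncol(img) / 2) + 1L))
  if (dcExcluded) amp[ctr[1L], ctr[2L]] <- 0
  new("MagnitudeSpectrum", amplitude = amp, dcExcluded = dcExcluded,
      center = ctr, degenerate = all(amp == 0))
}

#' Radially integrated spectral strength versus orientation angle
#'
#' For each angular bin over \[0, 180) degrees a ray is cast from the
#' spectrum center and the amplitude is summed at unit radial steps from
#' `rMinPx` to the largest radius fully inside the spectrum, with bilinear
#' interpolation at each sample. Sampling rays (rather than summing raw
#' wedges) gives every bin the same number of samples. Angles follow the
#' package convention: degrees counterclockwise from the +x (column) axis.
#'
#' @param spectrum A [MagnitudeSpectrum-class].
#' @param rMinPx Innermost radius sampled (default 2, skipping the
#'   immediate DC neighborhood); must be >= 1 unless DC was excluded.
#' @param nBins Number of angular bins (>= 36; default 180, i.e. 1-degree
#'   bins centered on 0, 1, ..., 179 degrees).
#' @return An [AngularProfile-class]. An all-zero spectrum yields an
#'   all-zero profile.
#' @seealso [peakSpectralIntensity()]
#' @export
angularProfile <- function(spectrum, rMinPx = 2L, nBins = 180L) {
  stopifnot(is(spectrum, "MagnitudeSpectrum"))
  if (!spectrum@dcExcluded && rMinPx < 1L)
    stop("rMinPx must be >= 1 when the DC term is retained")
  amp <- spectrum@amplitude
  ctr <- spectrum@center
  rMax <- min(ctr[1L] - 1L, ctr[2L] - 1L,
              nrow(amp) - ctr[1L], ncol(amp) - ctr[2L]) - 1L
  if (rMax < rMinPx) stop("spectrum too small for the requested radial range")
  angles <- (seq_len(nBins) - 1L) * 180 / nBins
  radii <- seq.int(rMinPx, rMax)
  th <- angles * pi / 180
  ## ray sample positions: rows decrease upward (+y) => row = ctr - r sin
  rowPos <- outer(radii, sin(th), function(r, s) ctr[1L] - r * s)
  colPos <- outer(radii, cos(th), function(r, c) ctr[2L] + r * c)
  strength <- colSums(bilinear(amp, rowPos, colPos))
  new("AngularProfile", angles = angles, strength = strength,
      rRange = as.integer(c(rMinPx, rMax)))
}

## bilinear interpolation of matrix m at (possibly matrix-shaped) positions
bilinear <- function(m, r, c) {
  r0 <- floor(r); c0 <- floor(c)
  fr <- r - r0; fc <- c - c0
  idx <- function(i, j) m[cbind(as.vector(i), as.vector(j))]
  v <- (1 - fr) * (1 - fc) * idx(r0, c0) +
       (1 - fr) * fc       * idx(r0, c0 + 1) +
       fr       * (1 - fc) * idx(r0 + 1, c0) +
       fr       * fc       * idx(r0 + 1, c0 + 1)
  if (is.matrix(r)) matrix(v, nrow(r), ncol(r)) else v
}

#' Peak spectral intensity of an angular profile
#'
#' The maximum of the radially integrated strength over orientation angles
#' is the peak spectral intensity `Is`; ties are broken toward the smaller
#' angle. An all-zero profile gives `Is = 0`.
#'
#' @param profile An [AngularProfile-class].
#' @return List with elements `Is` (the peak strength) and `angleDeg`
#'   (the bin angle where it occurs).
#' @export
peakSpectralIntensity <- function(profile) {
  stopifnot(is(profile, "AngularProfile"))
  i <- which.max(profile@strength)  # first maximum = smallest angle on ties
  list(Is = profile@strength[i], angleDeg = profile@angles[i])
}

#' Binarize a magnitude spectrum relative to its maximum
#'
#' Low-intensity pixels are removed by max-normalizing the spectrum and
#' keeping pixels at or above the fraction `frac` of the maximum.
#'
#' @param spectrum A [MagnitudeSpectrum-class] with a positive maximum.
#' @param frac Relative threshold in (0, 1); default 0.1.
#' @return Logical matrix mask.
#' @export
binarizeSpectrum <- function(spectrum, frac = 0.1) {
  stopifnot(is(spectrum, "MagnitudeSpectrum"))
  if (frac <= 0 || frac >= 1) stop("frac must lie strictly in (0, 1)")
  mx <- max(spectrum@amplitude)
  if (mx == 0) stop("no signal to binarize")
  spectrum@amplitude / mx >= frac
}

#' Equivalent ellipse of a binary mask
#'
#' Fits the ellipse having the same second central moments as the set of
#' true pixels: the full axis lengths are `4 * sqrt(eigenvalue)` of the
#' 2 x 2 pixel-coordinate covariance (population divisor), which for a
#' filled ellipse recovers its exact axes. The anisotropy ratio is
#' `r = alpha / beta >= 1`. Fewer than 3 true pixels, or an exactly
#' collinear pixel set, is degenerate and raises an error.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return An [EllipseFit-class]. Orientation is the major-axis angle in
#'   degrees counterclockwise from +x, in \[0, 180); equal eigenvalues
#'   report orientation 0.
#' @export
fitSpectrumEllipse <- function(mask) {
  stopifnot(is.matrix(mask))
  px <- which(mask != 0, arr.ind = TRUE)
  if (nrow(px) < 3L) stop("degenerate mask: fewer than 3 pixels")
  x <- px[, 2L]          # +x along columns
  y <- -px[, 1L]         # +y upward (rows grow downward)
  n <- length(x)
  cx <- x - mean(x); cy <- y - mean(y)
  cov <- matrix(c(sum(cx * cx), sum(cx * cy),
                  sum(cx * cy), sum(cy * cy)) / n, 2L)
  e <- eigen(cov, symmetric = TRUE)
  if (e$values[2L] <= 1e-12 * max(e$values[1L], 1))
    stop("degenerate mask: collinear pixel set")
  alpha <- 4 * sqrt(e$values[1L])
  beta <- 4 * sqrt(e$values[2L])
  ori <- if (abs(e$values[1L] - e$values[2L]) <=
             1e-12 * max(e$values[1L], 1)) 0
         else (atan2(e$vectors[2L, 1L], e$vectors[1L, 1L]) * 180 / pi) %% 180
  new("EllipseFit", alpha = alpha, beta = beta,
      orientationDeg = ori, ratio = alpha / beta)
}

#' Spectral parameters Is and r of an image region
#'
#' Composition of the spectral stages with one configuration: magnitude
#' spectrum (DC excluded), angular profile and its peak `Is`, and the
#' binarized-spectrum equivalent-ellipse ratio `r`. Also reports the
#' real-space fiber orientation implied by the profile peak (fiber texture
#' concentrates spectral energy perpendicular to the fiber axis, so the
#' implied fiber angle is the peak angle + 90, mod 180).
#'
#' @param img Numeric matrix (the selected region).
#' @param frac Binarization threshold as a fraction of the spectrum
#'   maximum; default 0.1.
#' @param rMinPx,nBins Angular-profile options, see [angularProfile()].
#' @param window Window function, see [magnitudeSpectrum()].
#' @return List with `Is`, `r`, `peakAngleDeg` (frequency-domain),
#'   `fiberOrientationDeg` (real-space), `profile` and `ellipse`.
#' @examples
#' g <- outer(1:64, 1:64, function(i, j) 100 * (1 + sin(2 * pi * i / 8)))
#' p <- spectralParams(g)
#' p$Is > 0 && p$r > 5
#' @export
spectralParams <- function(img, frac = 0.1, rMinPx = 2L, nBins = 180L,
                           window = "none") {
  sp <- magnitudeSpectrum(img, window = window, dcExcluded = TRUE)
  prof <- angularProfile(sp, rMinPx = rMinPx, nBins = nBins)
  pk <- peakSpectralIntensity(prof)
  ell <- fitSpectrumEllipse(binarizeSpectrum(sp, frac = frac))
  list(Is = pk$Is, r = ell@ratio, peakAngleDeg = pk$angleDeg,
       fiberOrientationDeg = (pk$angleDeg + 90) %% 180,
       profile = prof, ellipse = ell)
}
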