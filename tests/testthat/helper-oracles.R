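## Independent oracles and small fixture builders used across the suite.

## Direct O(N^4) DFT magnitude by explicit summation (no fft), shifted so
## DC lands at (floor(n/2)+1, floor(m/2)+1), matching magnitudeSpectrum().
dftMagnitudeOracle <- function(img, dcExcluded = TRUE) {
  n <- nrow(img); m <- ncol(img)
  xs <- 0:(n - 1); ys <- 0:(m - 1)
  out <- matrix(0, n, m)
  for (u in 0:(n - 1)) for (v in 0:(m - 1)) {
    ph <- outer(xs * u / n, ys * v / m, "+")
    out[u + 1, v + 1] <- Mod(sum(img * exp(-2i * pi * ph)))
  }
  ## same quadrant swap as the implementation under test would produce,
  ## done by explicit index arithmetic on frequency numbers
  ru <- ((0:(n - 1)) + floor(n / 2)) %% n + 1
  rv <- ((0:(m - 1)) + floor(m / 2)) %% m + 1
  shifted <- matrix(0, n, m)
  shifted[ru, ] <- out
  shifted[, rv] <- shifted
  ctr <- c(floor(n / 2) + 1, floor(m / 2) + 1)
  if (dcExcluded) shifted[ctr[1], ctr[2]] <- 0
  shifted
}

## Sinusoidal grating: stripes run along thetaDeg (CCW from +x, y up),
## wavevector perpendicular to the stripes.
mkGrating <- function(n, period, thetaDeg, amp = 100) {
  th <- thetaDeg * pi / 180
  x <- matrix(rep(seq_len(n), each = n), n)
  y <- -matrix(rep(seq_len(n), n), n)
  u <- x * (-sin(th)) + y * cos(th)
  amp * (1 + sin(2 * pi * u / period))
}

## 90-degree counterclockwise rotation of an image matrix
rot90ccw <- function(m) {
  r <- t(m)[rev(seq_len(ncol(m))), , drop = FALSE]
  r
}

## circular (wrap-around) translation of an image
circShift <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(p) - 1 - dc) %% p) + 1,
    drop = FALSE]
}

## noiseless single-orientation fiber phantom used by recovery tests
cleanFiberConfig <- function(thetaDeg, seed, noiseSd = 0, framePx = 256L) {
  fiberPhantomConfig(framePx = framePx, thetaDeg = thetaDeg,
                     dispersionDeg = 0, punctateFraction = 0,
                     gapWidthPx = 0, noiseSd = noiseSd,
                     noiseMean = if (noiseSd > 0) 3 * noiseSd else 0,
                     seed = seed)
}
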