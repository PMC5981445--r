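#' Smallest difference between two axial angles
#'
#' Orientations of fibers are axial quantities: 10 deg and 190 deg denote
#' the same axis. This returns the smallest absolute difference mod 180,
#' always in \[0, 90\].
#'
#' @param a,b Angles in degrees.
#' @return Absolute axial difference in degrees.
#' @examples
#' angularDifference(179, 1)   # 2
#' @export
angularDifference <- function(a, b) {
  d <- abs(a - b) %% 180
  pmin(d, 180 - d)
}

## axial circular mean of angles (degrees, mod 180), optionally weighted
axialMean <- function(thetaDeg, w = NULL) {
  if (length(thetaDeg) == 0L) return(NA_real_)
  if (is.null(w)) w <- rep(1, length(thetaDeg))
  th2 <- thetaDeg * pi / 90  # doubled angle in radians
  ang <- atan2(sum(w * sin(th2)), sum(w * cos(th2))) * 90 / pi
  ang %% 180
}

## p-value display convention: 3 decimals, or 1 significant figure below 0.001
formatPValue <- function(p) {
  if (is.na(p)) return("NA")
  if (p >= 0.001) sprintf("%.3f", p) else formatC(signif(p, 1), format = "g")
}

## shift a DFT matrix so the DC bin lands at (floor(n/2)+1, floor(m/2)+1)
fftShift <- function(m) {
  n <- nrow(m); p <- ncol(m)
  ri <- c((floor(n / 2) + 1):n, seq_len(floor(n / 2)))
  ci <- c((floor(p / 2) + 1):p, seq_len(floor(p / 2)))
  m[ri, ci, drop = FALSE]
}

## sums of cellPx x cellPx blocks of a matrix; partial edge cells dropped
blockSums <- function(m, cellPx) {
  nr <- floor(nrow(m) / cellPx)
  nc <- floor(ncol(m) / cellPx)
  if (nr < 1L || nc < 1L) stop("image smaller than one grid cell")
  m <- m[seq_len(nr * cellPx), seq_len(nc * cellPx), drop = FALSE]
  gi <- rep(seq_len(nr), each = cellPx)
  gj <- rep(seq_len(nc), each = cellPx)
  out <- t(rowsum(t(rowsum(m, gi)), gj))
  dimnames(out) <- NULL
  out
}

## restore the RNG state on exit; used by seeded generators so that calling
## them does not disturb the caller's random stream
withLocalSeed <- function(seed, expr) {
  hadSeed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (hadSeed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (hadSeed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
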