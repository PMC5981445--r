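#' Configuration of a synthetic fiber phantom
#'
#' Describes a tendon-like field of quasi-parallel straight fibers rendered
#' as anti-aliased line segments with a Gaussian cross profile, with
#' optional fragmentation ("punctate" appearance, the SHG signature of
#' weakly cross-linked fibers), periodic dark inter-bundle gaps, circular
#' dark patches (structural damage), a detector background offset and
#' additive Gaussian noise.
#'
#' Defaults emulate a 100 x 100 um SHG field sampled at 512 x 512 px
#' (pixel size 100/512 ~ 0.195 um).
#'
#' @param framePx Image edge length in pixels; default 512.
#' @param pixelSizeUm Physical pixel size; default 100/512.
#' @param nFibers Number of fibers; default 30.
#' @param thetaDeg Mean fiber orientation, degrees CCW from +x in
#'   \[0, 180); default 30.
#' @param dispersionDeg SD of per-fiber orientation about `thetaDeg`;
#'   default 5.
#' @param fiberWidthPx Gaussian cross-profile sigma in pixels; default 2.5.
#' @param punctateFraction Fraction of each fiber's length blanked into
#'   fragments, in \[0, 1\]; default 0.5.
#' @param fragmentLenPx Length of one blanking unit along the fiber axis;
#'   default 24.
#' @param gapPeriodPx,gapWidthPx Periodic dark bands parallel to the mean
#'   fiber direction (inter-bundle gaps); defaults 128 and 16. Width 0
#'   disables gaps.
#' @param darkPatchFraction Expected fraction of the frame blanked by
#'   random circular patches; default 0 (used by the wet-damage effect).
#' @param amplitude Fiber peak intensity; default 1000.
#' @param noiseSd Additive Gaussian noise SD; default 30.
#' @param noiseMean Detector background offset added with the noise;
#'   default `3 * noiseSd`.
#' @param seed RNG seed controlling the fiber geometry (and, unless
#'   `noiseSeed` is set, the noise).
#' @param noiseSeed Separate seed for the noise draw, so a before/after
#'   pair can share geometry while observing independent noise; default
#'   `seed`.
#' @return A list of class `FiberPhantomConfig`.
#' @seealso [makeFiberImage()], [makeStack()], [applyEffect()]
#' @export
fiberPhantomConfig <- function(framePx = 512L, pixelSizeUm = 100 / 512,
                               nFibers = 30L, thetaDeg = 30,
                               dispersionDeg = 5, fiberWidthPx = 2.5,
                               punctateFraction = 0.5, fragmentLenPx = 24,
                               gapPeriodPx = 128, gapWidthPx = 16,
                               darkPatchFraction = 0,
                               amplitude = 1000, noiseSd = 30,
                               noiseMean = 3 * noiseSd,
                               seed = 1L, noiseSeed = seed) {
  cfg <- list(framePx = as.integer(framePx), pixelSizeUm = pixelSizeUm,
              nFibers = as.integer(nFibers), thetaDeg = thetaDeg %% 180,
              dispersionDeg = dispersionDeg, fiberWidthPx = fiberWidthPx,
              punctateFraction = punctateFraction,
              fragmentLenPx = fragmentLenPx,
              gapPeriodPx = gapPeriodPx, gapWidthPx = gapWidthPx,
              darkPatchFraction = darkPatchFraction,
              amplitude = amplitude, noiseSd = noiseSd,
              noiseMean = noiseMean,
              seed = as.integer(seed), noiseSeed = as.integer(noiseSeed))
  validatePhantomConfig(cfg)
  structure(cfg, class = "FiberPhantomConfig")
}

validatePhantomConfig <- function(cfg) {
  stopifnot(cfg$framePx >= 32L, cfg$nFibers >= 0L,
            cfg$dispersionDeg >= 0, cfg$fiberWidthPx > 0,
            cfg$fragmentLenPx > 0, cfg$gapPeriodPx > 0, cfg$gapWidthPx >= 0,
            cfg$noiseSd >= 0, cfg$noiseMean >= 0)
  if (cfg$punctateFraction < 0 || cfg$punctateFraction > 1)
    stop("punctateFraction must lie in [0, 1]")
  if (cfg$darkPatchFraction < 0 || cfg$darkPatchFraction >= 1)
    stop("darkPatchFraction must lie in [0, 1)")
  if (cfg$amplitude <= cfg$noiseSd)
    stop("amplitude must exceed noiseSd")
  invisible(cfg)
}

#' Structural-change effect applied to a phantom configuration
#'
#' Two named effects mirror the before/after contrasts the analysis is
#' designed to detect:
#' \describe{
#'   \item{`crosslinking`}{fibers become more continuous (punctate fraction
#'     reduced) and brighter, and inter-bundle gaps widen — the low-vacuum
#'     e-beam signature;}
#'   \item{`wet_damage`}{fiber orientation becomes disordered (dispersion
#'     increased) and dark patches appear — the wet-mode signature;}
#'   \item{`none`}{identity, for control pairs.}
#' }
#'
#' @param kind `"crosslinking"`, `"wet_damage"` or `"none"`.
#' @param intensityGain Multiplies the fiber amplitude (crosslinking
#'   default 1.25).
#' @param punctateReduction Subtracted from `punctateFraction`
#'   (crosslinking default 0.2).
#' @param gapWideningPx Added to `gapWidthPx` (crosslinking default 8).
#' @param dispersionIncreaseDeg Added to `dispersionDeg` (wet-damage
#'   default 30).
#' @param darkPatchFraction Added to the config's dark-patch coverage
#'   (wet-damage default 0.3).
#' @return A list of class `EffectSpec`.
#' @export
effectSpec <- function(kind = c("crosslinking", "wet_damage", "none"),
                       intensityGain = NULL, punctateReduction = NULL,
                       gapWideningPx = NULL, dispersionIncreaseDeg = NULL,
                       darkPatchFraction = NULL) {
  kind <- match.arg(kind)
  def <- switch(kind,
    crosslinking = list(intensityGain = 1.25, punctateReduction = 0.2,
                        gapWideningPx = 8, dispersionIncreaseDeg = 0,
                        darkPatchFraction = 0),
    wet_damage = list(intensityGain = 1, punctateReduction = 0,
                      gapWideningPx = 0, dispersionIncreaseDeg = 30,
                      darkPatchFraction = 0.3),
    none = list(intensityGain = 1, punctateReduction = 0, gapWideningPx = 0,
                dispersionIncreaseDeg = 0, darkPatchFraction = 0))
  pick <- function(user, d) if (is.null(user)) d else user
  eff <- list(kind = kind,
              intensityGain = pick(intensityGain, def$intensityGain),
              punctateReduction = pick(punctateReduction, def$punctateReduction),
              gapWideningPx = pick(gapWideningPx, def$gapWideningPx),
              dispersionIncreaseDeg = pick(dispersionIncreaseDeg,
                                           def$dispersionIncreaseDeg),
              darkPatchFraction = pick(darkPatchFraction, def$darkPatchFraction))
  if (kind == "none" &&
      (eff$intensityGain != 1 || eff$punctateReduction != 0 ||
       eff$gapWideningPx != 0 || eff$dispersionIncreaseDeg != 0 ||
       eff$darkPatchFraction != 0))
    stop("kind = 'none' requires all knobs at identity")
  structure(eff, class = "EffectSpec")
}

#' Apply an effect to a phantom configuration
#'
#' Returns the "after" configuration of a before/after pair. The geometry
#' seed is kept, so before and after phantoms share fiber positions and
#' angles (the same tissue region); fragment blanking draws from shared
#' uniforms, so fragments restored by a punctate reduction are a superset
#' of the surviving ones. `punctateFraction` is clipped to \[0, 1\] with a
#' warning when the reduction overshoots.
#'
#' @param config A `FiberPhantomConfig`.
#' @param effect An `EffectSpec`.
#' @return A new `FiberPhantomConfig`.
#' @export
applyEffect <- function(config, effect) {
  stopifnot(inherits(config, "FiberPhantomConfig"), inherits(effect, "EffectSpec"))
  if (effect$kind == "none") return(config)
  cfg <- unclass(config)
  pf <- cfg$punctateFraction - effect$punctateReduction
  if (pf < 0 || pf > 1) {
    warning("punctateFraction clipped to [0, 1]")
    pf <- min(1, max(0, pf))
  }
  cfg$punctateFraction <- pf
  cfg$amplitude <- cfg$amplitude * effect$intensityGain
  cfg$gapWidthPx <- cfg$gapWidthPx + effect$gapWideningPx
  cfg$dispersionDeg <- cfg$dispersionDeg + effect$dispersionIncreaseDeg
  cfg$darkPatchFraction <- min(0.99, cfg$darkPatchFraction + effect$darkPatchFraction)
  validatePhantomConfig(cfg)
  structure(cfg, class = "FiberPhantomConfig")
}

## Deterministic geometry draw: everything except the noise field.
## Fragment blanking is drawn as uniforms and thresholded against
## punctateFraction at render time, so configs differing only in
## punctateFraction produce nested blanking patterns.
phantomGeometry <- function(cfg) {
  withLocalSeed(cfg$seed, {
    N <- cfg$framePx
    thetas <- (cfg$thetaDeg + stats::rnorm(cfg$nFibers, 0, cfg$dispersionDeg)) %% 180
    offsets <- stats::runif(cfg$nFibers, -0.75 * N, 0.75 * N)
    alongShift <- stats::runif(cfg$nFibers, -0.5 * N, 0.5 * N)
    nSeg <- 2L * ceiling(1.6 * N / cfg$fragmentLenPx) + 1L
    fragU <- matrix(stats::runif(cfg$nFibers * nSeg), nrow = nSeg)
    fragPhase <- stats::runif(cfg$nFibers, 0, cfg$fragmentLenPx)
    gapPhase <- stats::runif(1, 0, cfg$gapPeriodPx)
    ## dark patches: Poisson-corrected count so expected coverage matches
    patchR <- 0.15 * N
    nPatch <- if (cfg$darkPatchFraction > 0)
      ceiling(-log(1 - cfg$darkPatchFraction) * N^2 / (pi * patchR^2)) else 0L
    patches <- if (nPatch > 0)
      cbind(row = stats::runif(nPatch, 1, N), col = stats::runif(nPatch, 1, N))
    else NULL
    list(thetas = thetas, offsets = offsets, alongShift = alongShift,
         fragU = fragU, fragPhase = fragPhase, gapPhase = gapPhase,
         patches = patches, patchR = patchR, nSeg = nSeg)
  })
}

## Render one slice from a geometry; fragJitter shifts the fragment phase
## (per-slice z decorrelation). Returns the noiseless fiber field plus masks.
renderSlice <- function(cfg, geom, fragJitter = 0) {
  N <- cfg$framePx
  img <- matrix(0, N, N)
  x <- matrix(rep(seq_len(N), each = N), N)  # column index
  y <- -matrix(rep(seq_len(N), N), N)        # +y up
  halfLen <- 0.75 * N
  segHalf <- (geom$nSeg - 1L) / 2L
  thMean <- cfg$thetaDeg * pi / 180
  cx0 <- N / 2; cy0 <- -N / 2
  for (i in seq_len(cfg$nFibers)) {
    th <- geom$thetas[i] * pi / 180
    dirx <- cos(th); diry <- sin(th)
    nx <- -sin(th); ny <- cos(th)
    cx <- cx0 + geom$offsets[i] * (-sin(thMean)) + geom$alongShift[i] * cos(thMean)
    cy <- cy0 + geom$offsets[i] * cos(thMean) + geom$alongShift[i] * sin(thMean)
    d <- (x - cx) * nx + (y - cy) * ny
    keepBand <- abs(d) < 5 * cfg$fiberWidthPx
    if (!any(keepBand)) next
    t <- (x - cx) * dirx + (y - cy) * diry
    prof <- exp(-d[keepBand]^2 / (2 * cfg$fiberWidthPx^2))
    tb <- t[keepBand]
    seg <- floor((tb + geom$fragPhase[i] + fragJitter) / cfg$fragmentLenPx)
    seg <- pmin(pmax(seg + segHalf + 1L, 1L), geom$nSeg)
    blanked <- geom$fragU[seg, i] < cfg$punctateFraction
    prof[blanked | abs(tb) > halfLen] <- 0
    contrib <- cfg$amplitude * prof
    cur <- img[keepBand]
    img[keepBand] <- pmax(cur, contrib)
  }
  fiberMask <- img > 0.2 * cfg$amplitude
  ## inter-bundle gaps: dark bands parallel to the mean fiber direction
  gapMask <- matrix(FALSE, N, N)
  if (cfg$gapWidthPx > 0) {
    u <- x * (-sin(thMean)) + y * cos(thMean)
    gapMask <- ((u - geom$gapPhase) %% cfg$gapPeriodPx) < cfg$gapWidthPx
    img[gapMask] <- 0
  }
  patchMask <- matrix(FALSE, N, N)
  if (!is.null(geom$patches)) {
    rowM <- matrix(rep(seq_len(N), N), N)
    for (k in seq_len(nrow(geom$patches))) {
      inside <- (rowM - geom$patches[k, "row"])^2 +
                (x - geom$patches[k, "col"])^2 < geom$patchR^2
      patchMask <- patchMask | inside
    }
    img[patchMask] <- 0
  }
  list(img = img, fiberMask = fiberMask, gapMask = gapMask, patchMask = patchMask)
}

#' Generate one synthetic fiber image with ground truth
#'
#' Deterministic given the config (geometry from `seed`, noise from
#' `noiseSeed`): fibers are rendered as straight anti-aliased segments with
#' a Gaussian cross profile, fragments are blanked according to
#' `punctateFraction`, inter-bundle gaps and dark patches are applied, and
#' the detector background (offset + Gaussian noise, clipped at zero,
#' rounded to integer counts) is added.
#'
#' @param config A `FiberPhantomConfig`, see [fiberPhantomConfig()].
#' @return List with `image` (framePx x framePx numeric matrix),
#'   `config`, and `truth` — a list carrying per-fiber `thetaDeg`, the
#'   noiseless `fiberMask`, `gapMask` and `patchMask`.
#' @examples
#' ph <- makeFiberImage(fiberPhantomConfig(framePx = 128, nFibers = 8, seed = 7))
#' dim(ph$image)
#' @export
makeFiberImage <- function(config) {
  stopifnot(inherits(config, "FiberPhantomConfig"))
  geom <- phantomGeometry(config)
  sl <- renderSlice(config, geom)
  img <- addNoise(sl$img, config, sliceIndex = 1L)
  list(image = img, config = config,
       truth = list(thetaDeg = geom$thetas, fiberMask = sl$fiberMask,
                    gapMask = sl$gapMask, patchMask = sl$patchMask))
}

addNoise <- function(img, cfg, sliceIndex = 1L) {
  if (cfg$noiseSd == 0 && cfg$noiseMean == 0) return(round(img))
  withLocalSeed((cfg$noiseSeed + 97561L * (sliceIndex - 1L)) %% .Machine$integer.max, {
    noise <- stats::rnorm(length(img), cfg$noiseMean, cfg$noiseSd)
    round(pmax(img + noise, 0))
  })
}

#' Generate a synthetic z-stack with ground truth
#'
#' Slices share one fiber geometry; per-slice variation comes from a small
#' jitter of the fragment phase along the fiber axis (z decorrelation of
#' the punctate pattern) and an independent noise draw per slice. The
#' default 31 slices at a 0.5 um step span 15 um axially.
#'
#' @param config A `FiberPhantomConfig`.
#' @param nSlices Number of slices; default 31.
#' @param zJitter SD (pixels) of the per-slice fragment-phase jitter;
#'   0 with `noiseSd = 0` makes all slices identical.
#' @param zStepUm Axial step in micrometers; default 0.5.
#' @return List with `stack` (an [ImageStack-class]), `config` and
#'   `truth` (as in [makeFiberImage()], from the first slice).
#' @export
makeStack <- function(config, nSlices = 31L, zJitter = 2, zStepUm = 0.5) {
  stopifnot(inherits(config, "FiberPhantomConfig"), nSlices >= 1L)
  geom <- phantomGeometry(config)
  jit <- withLocalSeed((config$seed + 131071L) %% .Machine$integer.max,
                       stats::rnorm(nSlices, 0, max(zJitter, 0)))
  if (zJitter == 0) jit <- rep(0, nSlices)
  slices <- vector("list", nSlices)
  truth <- NULL
  for (i in seq_len(nSlices)) {
    sl <- renderSlice(config, geom, fragJitter = jit[i])
    if (i == 1L)
      truth <- list(thetaDeg = geom$thetas, fiberMask = sl$fiberMask,
                    gapMask = sl$gapMask, patchMask = sl$patchMask)
    slices[[i]] <- addNoise(sl$img, config, sliceIndex = i)
  }
  vox <- array(unlist(slices, use.names = FALSE),
               dim = c(config$framePx, config$framePx, nSlices))
  list(stack = imageStack(vox, pixelSizeUm = config$pixelSizeUm,
                          zStepUm = zStepUm),
       config = config, truth = truth)
}

#' Simulate a before/after image pair
#'
#' The "before" phantom uses `config`; the "after" phantom uses
#' `applyEffect(config, effect)` with the same geometry seed (the same
#' tissue region) and an independent noise draw.
#'
#' @param config A `FiberPhantomConfig`.
#' @param effect An `EffectSpec`.
#' @param nSlices Slices per stack; default 1 (single optical section).
#' @param zJitter Passed to [makeStack()] when `nSlices > 1`.
#' @return List with `before` and `after`, each an [ImageStack-class],
#'   plus both configs.
#' @export
simulatePair <- function(config, effect, nSlices = 1L, zJitter = 2) {
  after <- applyEffect(config, effect)
  after$noiseSeed <- (after$noiseSeed + 500009L) %% .Machine$integer.max
  class(after) <- "FiberPhantomConfig"
  mk <- function(cfg) {
    if (nSlices == 1L) {
      ph <- makeFiberImage(cfg)
      imageStack(ph$image, pixelSizeUm = cfg$pixelSizeUm)
    } else {
      makeStack(cfg, nSlices = nSlices, zJitter = zJitter)$stack
    }
  }
  list(before = mk(config), after = mk(after),
       configBefore = config, configAfter = after)
}
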