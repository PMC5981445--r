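test_that("generation is deterministic given the seed and varies across seeds", {
  cfg <- fiberPhantomConfig(framePx = 128L, nFibers = 10L, seed = 5)
  a <- makeFiberImage(cfg)
  b <- makeFiberImage(cfg)
  expect_identical(a$image, b$image)
  expect_identical(a$truth$thetaDeg, b$truth$thetaDeg)
  c2 <- makeFiberImage(fiberPhantomConfig(framePx = 128L, nFibers = 10L, seed = 6))
  expect_false(identical(a$image, c2$image))
})

test_that("an empty noiseless config renders an all-zero image with Id = 0", {
  cfg <- fiberPhantomConfig(framePx = 64L, nFibers = 0L, noiseSd = 0,
                            noiseMean = 0, gapWidthPx = 0)
  ph <- makeFiberImage(cfg)
  expect_true(all(ph$image == 0))
  expect_equal(densityIndex(areaFractionMap(ph$image, threshold = 0)), 0)
})

test_that("both modules recover a clean phantom's orientation within 2 degrees", {
  ph <- makeFiberImage(cleanFiberConfig(30, seed = 12))
  expect_lte(angularDifference(
    preferredOrientation(classifyCells(ph$image, darkThresh = 1)), 30), 2)
  pk <- peakSpectralIntensity(angularProfile(magnitudeSpectrum(ph$image)))
  expect_lte(angularDifference((pk$angleDeg + 90) %% 180, 30), 2)
})

test_that("ground-truth masks are consistent with the rendered image", {
  cfg <- fiberPhantomConfig(framePx = 128L, nFibers = 10L, noiseSd = 0,
                            noiseMean = 0, seed = 9)
  ph <- makeFiberImage(cfg)
  ## every bright pixel outside gaps lies on the fiber mask
  bright <- ph$image > 0.5 * cfg$amplitude
  expect_true(all(ph$truth$fiberMask[bright]))
  expect_true(all(ph$image[ph$truth$gapMask] == 0))
})

test_that("stacks with zero jitter and zero noise have identical slices", {
  cfg <- fiberPhantomConfig(framePx = 64L, nFibers = 6L, noiseSd = 0,
                            noiseMean = 0, seed = 3)
  st <- makeStack(cfg, nSlices = 4L, zJitter = 0)$stack
  expect_identical(nSlices(st), 4L)
  for (i in 2:4) expect_identical(getSlice(st, i), getSlice(st, 1))
})

test_that("the default stack matches the acquisition geometry", {
  cfg <- fiberPhantomConfig(framePx = 64L, nFibers = 4L, seed = 1)
  st <- makeStack(cfg)$stack
  expect_identical(nSlices(st), 31L)
  expect_equal(zStepUm(st), 0.5)                  # 500 nm step
  expect_equal((31 - 1) * zStepUm(st), 15)        # 15 um axial span
})

test_that("per-slice density variability vanishes as z jitter goes to 0", {
  cfg <- fiberPhantomConfig(framePx = 128L, nFibers = 10L, noiseSd = 0,
                            noiseMean = 0, seed = 8)
  idOf <- function(st) vapply(seq_len(nSlices(st)), function(i)
    densityIndex(areaFractionMap(getSlice(st, i), threshold = 0)), numeric(1))
  sd0 <- sd(idOf(makeStack(cfg, nSlices = 6L, zJitter = 0)$stack))
  sd4 <- sd(idOf(makeStack(cfg, nSlices = 6L, zJitter = 6)$stack))
  expect_identical(sd0, 0)
  expect_gt(sd4, 0)
})

test_that("applyEffect with kind none is the identity", {
  cfg <- fiberPhantomConfig(seed = 2)
  expect_identical(applyEffect(cfg, effectSpec("none")), cfg)
  expect_error(effectSpec("none", intensityGain = 2), "identity")
})

test_that("crosslinking arithmetic on the config is exact, with clipping", {
  cfg <- fiberPhantomConfig(punctateFraction = 0.6, amplitude = 1000,
                            gapWidthPx = 16)
  out <- applyEffect(cfg, effectSpec("crosslinking", punctateReduction = 0.5,
                                     intensityGain = 1.3, gapWideningPx = 8))
  expect_equal(out$punctateFraction, 0.1)
  expect_equal(out$amplitude, 1300)
  expect_equal(out$gapWidthPx, 24)
  expect_warning(
    applyEffect(fiberPhantomConfig(punctateFraction = 0.3),
                effectSpec("crosslinking", punctateReduction = 0.5)),
    "clipped")
})

test_that("wet damage raises the dark-cell fraction markedly", {
  ## densely fibrous base frames (the analysis targets fiber-dominated
  ## areas); the dark threshold is the generator's known noise level
  rises <- vapply(1:8, function(seed) {
    cfg <- fiberPhantomConfig(framePx = 256L, nFibers = 40L,
                              punctateFraction = 0.1, gapWidthPx = 8,
                              seed = seed)
    thr <- cfg$noiseMean + 3 * cfg$noiseSd
    pair <- simulatePair(cfg, effectSpec("wet_damage"))
    darkFrac <- function(stk)
      mean(classifyCells(getSlice(stk, 1), darkThresh = thr)@labels == "dark")
    darkFrac(pair$after) - darkFrac(pair$before)
  }, numeric(1))
  expect_gte(mean(rises), 0.2)
  expect_true(all(rises > 0))
})

test_that("config validation rejects out-of-range parameters", {
  expect_error(fiberPhantomConfig(punctateFraction = 1.5), "punctateFraction")
  expect_error(fiberPhantomConfig(amplitude = 10, noiseSd = 20), "amplitude")
  expect_error(fiberPhantomConfig(dispersionDeg = -1))
})

test_that("same geometry seed with a new noise seed changes only the noise", {
  cfg1 <- fiberPhantomConfig(framePx = 64L, nFibers = 5L, seed = 4, noiseSeed = 4)
  cfg2 <- fiberPhantomConfig(framePx = 64L, nFibers = 5L, seed = 4, noiseSeed = 99)
  a <- makeFiberImage(cfg1); b <- makeFiberImage(cfg2)
  expect_identical(a$truth$fiberMask, b$truth$fiberMask)
  expect_false(identical(a$image, b$image))
  ## structural content nearly unchanged
  expect_lt(abs(mean(a$image) - mean(b$image)) / mean(a$image), 0.05)
})
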