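test_that("FFT magnitude agrees with the direct DFT oracle to 1e-9", {
  for (seed in 1:3) {
    set.seed(seed)
    img <- matrix(runif(32 * 32) * 50, 32, 32)
    got <- magnitudeSpectrum(img)@amplitude
    want <- dftMagnitudeOracle(img)
    expect_lt(max(abs(got - want)) / max(want), 1e-9)
  }
})

test_that("a constant image is all DC: excluded, the spectrum is zero and flagged", {
  sp <- magnitudeSpectrum(matrix(4, 32, 32))
  expect_true(sp@degenerate)
  expect_true(all(sp@amplitude == 0))
  spIn <- magnitudeSpectrum(matrix(4, 32, 32), dcExcluded = FALSE)
  expect_false(spIn@degenerate)
  expect_equal(sum(spIn@amplitude > 0), 1)
  expect_equal(spIn@amplitude[spIn@center[1], spIn@center[2]], 4 * 32 * 32)
})

test_that("a row-wise sinusoid puts symmetric peaks on the vertical frequency axis", {
  n <- 64
  img <- 100 * (1 + sin(2 * pi * seq_len(n) / 8))  # varies along rows
  img <- matrix(rep(img, n), n)
  sp <- magnitudeSpectrum(img)
  ctr <- sp@center
  pk <- which(sp@amplitude > 0.5 * max(sp@amplitude), arr.ind = TRUE)
  expect_identical(nrow(pk), 2L)
  expect_true(all(pk[, 2] == ctr[2]))              # on the vertical axis
  expect_setequal(pk[, 1] - ctr[1], c(-8L, 8L))    # radius n/period = 8
  prof <- angularProfile(sp)
  expect_equal(peakSpectralIntensity(prof)$angleDeg, 90)
})

test_that("the magnitude spectrum is invariant to circular translation", {
  set.seed(5)
  img <- matrix(runif(64 * 64), 64, 64) + mkGrating(64, 9.7, 40)
  a0 <- magnitudeSpectrum(img)@amplitude
  a1 <- magnitudeSpectrum(circShift(img, 13, -21))@amplitude
  expect_lt(max(abs(a0 - a1)) / max(a0), 1e-9)
})

test_that("Hermitian point symmetry holds about the center", {
  set.seed(6)
  img <- matrix(runif(32 * 32), 32, 32)
  amp <- magnitudeSpectrum(img, dcExcluded = FALSE)@amplitude
  ctr <- c(17, 17)
  for (d in list(c(1, 3), c(-5, 2), c(7, -7), c(0, 11))) {
    expect_equal(amp[ctr[1] + d[1], ctr[2] + d[2]],
                 amp[ctr[1] - d[1], ctr[2] - d[2]], tolerance = 1e-9)
  }
})

test_that("angular profile of an all-zero spectrum is zero with Is = 0", {
  sp <- magnitudeSpectrum(matrix(4, 32, 32))  # degenerate
  prof <- angularProfile(sp)
  expect_true(all(prof@strength == 0))
  expect_equal(peakSpectralIntensity(prof)$Is, 0)
})

test_that("profile argmax sits at the grating's frequency-space angle", {
  ## stripes along 0 deg -> wavevector at 90 deg in frequency space
  g <- mkGrating(64, 8, 0)
  prof <- angularProfile(magnitudeSpectrum(g))
  expect_equal(peakSpectralIntensity(prof)$angleDeg, 90)
  ## stripes along 90 deg -> energy at 0 deg
  g2 <- mkGrating(64, 8, 90)
  prof2 <- angularProfile(magnitudeSpectrum(g2))
  expect_equal(peakSpectralIntensity(prof2)$angleDeg, 0)
})

test_that("white noise gives a nearly flat profile (max/mean <= 1.2 seed-averaged)", {
  ratios <- vapply(1:50, function(seed) {
    set.seed(seed)
    img <- matrix(runif(64 * 64), 64, 64)
    prof <- angularProfile(magnitudeSpectrum(img))
    max(prof@strength) / mean(prof@strength)
  }, numeric(1))
  expect_lte(mean(ratios), 1.2)
})

test_that("peak picking takes the max, breaking ties toward smaller angles", {
  prof <- new("AngularProfile", angles = seq(0, 179, length.out = 36),
              strength = c(1, 5, 3, rep(0, 32), 5), rRange = c(2L, 10L))
  pk <- peakSpectralIntensity(prof)
  expect_equal(pk$Is, 5)
  expect_equal(pk$angleDeg, prof@angles[2])  # not the tied later bin
})

test_that("Is is homogeneous of degree 1 in image intensity", {
  g <- mkGrating(64, 7.3, 25)
  p1 <- peakSpectralIntensity(angularProfile(magnitudeSpectrum(g)))
  p2 <- peakSpectralIntensity(angularProfile(magnitudeSpectrum(2 * g)))
  expect_equal(p2$Is, 2 * p1$Is, tolerance = 1e-12)
  expect_equal(p1$angleDeg, p2$angleDeg)
})

test_that("binarization keeps exactly the pixels at or above frac of max", {
  sp <- magnitudeSpectrum(mkGrating(64, 7.3, 25) + 5)
  mask <- binarizeSpectrum(sp, 0.1)
  want <- sp@amplitude >= 0.1 * max(sp@amplitude)
  expect_identical(mask, want)
  ## single nonzero pixel: retained at any frac
  amp <- matrix(0, 32, 32); amp[4, 9] <- 3
  spOne <- new("MagnitudeSpectrum", amplitude = amp, dcExcluded = TRUE,
               center = c(17L, 17L), degenerate = FALSE)
  for (fr in c(0.001, 0.5, 0.999))
    expect_identical(which(binarizeSpectrum(spOne, fr)), which(amp > 0))
  ## frac -> 0+ approaches the full support of the spectrum
  grows <- sum(binarizeSpectrum(sp, 1e-12))
  expect_gte(grows, sum(mask))
  expect_true(all(binarizeSpectrum(sp, 1e-12)[sp@amplitude >= 1e-6 * max(sp@amplitude)]))
})

test_that("binarizing an all-zero spectrum is an error", {
  sp <- magnitudeSpectrum(matrix(4, 32, 32))
  expect_error(binarizeSpectrum(sp), "no signal")
})

test_that("ellipse of a filled disk has ratio 1 within discretization", {
  n <- 101
  d <- outer(seq_len(n) - 51, seq_len(n) - 51, function(i, j) i^2 + j^2)
  fit <- fitSpectrumEllipse(d <= 40^2)
  expect_lt(fit@ratio, 1.02)
  expect_gte(fit@ratio, 1)
})

test_that("ellipse of a 3x21 rectangle matches hand-enumerated moments", {
  mask <- matrix(FALSE, 30, 40)
  mask[10:12, 11:31] <- TRUE
  fit <- fitSpectrumEllipse(mask)
  ## population variances of 21 and 3 consecutive integers: (k^2-1)/12
  expect_equal(fit@alpha, 4 * sqrt((21^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(fit@beta, 4 * sqrt((3^2 - 1) / 12), tolerance = 1e-12)
  expect_equal(fit@ratio, sqrt((21^2 - 1) / (3^2 - 1)), tolerance = 1e-12)
  expect_equal(fit@orientationDeg, 0)  # long axis along +x
})

test_that("rotating a mask by 90 degrees preserves the ratio, shifts orientation", {
  mask <- matrix(FALSE, 40, 40)
  mask[18:22, 5:35] <- TRUE
  f0 <- fitSpectrumEllipse(mask)
  f90 <- fitSpectrumEllipse(rot90ccw(mask))
  expect_equal(f90@ratio, f0@ratio, tolerance = 1e-9)
  expect_equal(angularDifference(f90@orientationDeg, f0@orientationDeg + 90), 0,
               tolerance = 1e-6)
})

test_that("degenerate masks are rejected", {
  m <- matrix(FALSE, 20, 20)
  m[3, 3] <- TRUE; m[9, 9] <- TRUE
  expect_error(fitSpectrumEllipse(m), "fewer than 3")
  m[15, 15] <- TRUE  # three exactly collinear points
  expect_error(fitSpectrumEllipse(m), "collinear")
})

test_that("spectralParams on isotropic noise gives r near 1 (seed-averaged)", {
  rs <- vapply(1:20, function(seed) {
    set.seed(seed)
    spectralParams(matrix(runif(64 * 64), 64, 64))$r
  }, numeric(1))
  expect_gte(mean(rs), 1)
  expect_lte(mean(rs), 1.3)
})

test_that("spectralParams on an off-grid grating is strongly anisotropic", {
  g <- mkGrating(64, 7.3, 30)
  p <- spectralParams(g)
  expect_gte(p$r, 5)
  ## profile peak perpendicular to the stripes, i.e. implied fiber angle ~ 30
  expect_lte(angularDifference(p$fiberOrientationDeg, 30), 2)
})

test_that("spectralParams propagates the degenerate-input error", {
  expect_error(spectralParams(matrix(4, 32, 32)), "no signal")
})

test_that("Is and r are invariant to circular translation of the region", {
  img <- mkGrating(64, 7.3, 55) + 10
  p0 <- spectralParams(img)
  p1 <- spectralParams(circShift(img, 7, 19))
  expect_lt(abs(p1$Is - p0$Is) / p0$Is, 1e-6)
  expect_lt(abs(p1$r - p0$r) / p0$r, 1e-6)
})

test_that("r is invariant under intensity scaling (relative binarization)", {
  img <- mkGrating(64, 7.3, 55) + 10
  expect_equal(spectralParams(3.7 * img)$r, spectralParams(img)$r,
               tolerance = 1e-12)
})

test_that("90-degree image rotation rotates the profile argmax and keeps r", {
  img <- mkGrating(64, 7.3, 20) + 10
  p0 <- spectralParams(img)
  p90 <- spectralParams(rot90ccw(img))
  expect_lte(angularDifference(p90$fiberOrientationDeg,
                               p0$fiberOrientationDeg + 90), 2)
  expect_lt(abs(p90$r - p0$r) / p0$r, 0.05)
})
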