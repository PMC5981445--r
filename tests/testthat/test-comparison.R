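test_that("a stack of identical slices summarizes to single-slice values", {
  ph <- makeFiberImage(fiberPhantomConfig(framePx = 128L, nFibers = 10L, seed = 2))
  vox <- array(rep(ph$image, 3), c(128, 128, 3))
  st <- imageStack(vox)
  sm <- summarizeStack(st)
  expect_identical(sm@nSlices, 3L)
  expect_equal(sd(sm@perSlice$Id), 0)
  expect_equal(sd(sm@perSlice$Is), 0)
  thr <- sm@perSlice$threshold[1]
  expect_equal(sm@Id, densityIndex(areaFractionMap(ph$image, threshold = thr)))
})

test_that("stack summaries are plain means of per-slice values", {
  ## two slices engineered to Id = 0.25 and 0.5 at a fixed threshold
  mk <- function(frac) {
    img <- matrix(0, 64, 64)
    img[seq_len(64 * 64 * frac)] <- 500
    img
  }
  st <- imageStack(array(c(mk(0.25) + mkGrating(64, 7.3, 30),
                           mk(0.5) + mkGrating(64, 7.3, 30)), c(64, 64, 2)))
  sm <- summarizeStack(st, thresholdMethod = "fixed", thresholdValue = 250)
  expect_equal(sm@Id, 0.375, tolerance = 1e-12)
  expect_equal(sm@Id, mean(sm@perSlice$Id), tolerance = 1e-15)
  expect_equal(sm@Is, mean(sm@perSlice$Is), tolerance = 1e-15)
  expect_equal(sm@r, mean(sm@perSlice$r), tolerance = 1e-15)
})

test_that("an 8-slice summary equals the mean of per-slice runs", {
  res <- makeStack(fiberPhantomConfig(framePx = 128L, nFibers = 10L, seed = 6),
                   nSlices = 8L, zJitter = 3)
  sm <- summarizeStack(res$stack)
  roi <- centeredRoi(res$stack)
  perSlice <- vapply(1:8, function(i) {
    sl <- getSlice(res$stack, i)
    thr <- estimateNoiseThreshold(sl)
    roiImg <- sl[roi@row0 + seq_len(roi@height), roi@col0 + seq_len(roi@width)]
    c(densityIndex(areaFractionMap(sl, threshold = thr)),
      spectralParams(roiImg)$Is)
  }, numeric(2))
  expect_equal(sm@Id, mean(perSlice[1, ]), tolerance = 1e-12)
  expect_equal(sm@Is, mean(perSlice[2, ]), tolerance = 1e-12)
})

test_that("percent changes follow the relative-change definition", {
  mkSum <- function(Id, Is, r) new("StackSummary", Id = Id, Is = Is, r = r,
                                   nSlices = 1L, perSlice = data.frame())
  b <- mkSum(0.5, 200, 2)
  expect_equal(unname(percentChange(b, b)), c(0, 0, 0))
  expect_equal(percentChange(b, mkSum(0.5, 200, 3))[["dr"]], 50)
  expect_equal(percentChange(b, mkSum(0.5, 150, 2))[["dIs"]], -25)
  expect_error(percentChange(mkSum(0, 200, 2), b), "undefined relative change")
})

test_that("group summaries use the sample SD and match brute force", {
  g <- groupSummary(c(1, 1, 1))
  expect_equal(unlist(g), c(mean = 1, sd = 0, n = 3))
  g2 <- groupSummary(c(0, 2))
  expect_equal(g2$sd, sqrt(2), tolerance = 1e-15)
  set.seed(31)
  x <- rnorm(11)
  g3 <- groupSummary(x)
  expect_equal(g3$sd, sqrt(sum((x - mean(x))^2) / (length(x) - 1)),
               tolerance = 1e-15)
  expect_error(groupSummary(5), "at least 2")
})

test_that("summary-statistics t test equals t.test on the raw samples", {
  set.seed(17)
  for (i in 1:5) {
    a <- rnorm(3 + i, mean = 2); b <- rnorm(4, mean = 0)
    got <- studentsTTest(mean(a), sd(a), length(a), mean(b), sd(b), length(b))
    ref <- t.test(a, b, var.equal = TRUE)
    expect_equal(got@t, unname(ref$statistic), tolerance = 1e-12)
    expect_equal(got@df, unname(ref$parameter), tolerance = 1e-12)
    expect_equal(got@p, ref$p.value, tolerance = 1e-12)
    ## raw-sample entry point gives the identical result
    raw <- studentsTTest(a = a, b = b)
    expect_equal(raw@t, got@t, tolerance = 1e-15)
    ## Welch variant matches t.test default
    w <- studentsTTest(mean(a), sd(a), length(a), mean(b), sd(b), length(b),
                       method = "welch")
    refW <- t.test(a, b)
    expect_equal(w@p, refW$p.value, tolerance = 1e-12)
    expect_equal(w@df, unname(refW$parameter), tolerance = 1e-12)
  }
})

test_that("swapping groups negates t and preserves p", {
  g1 <- studentsTTest(10.14, 5.83, 3, -3.01, 1.64, 3)
  g2 <- studentsTTest(-3.01, 1.64, 3, 10.14, 5.83, 3)
  expect_equal(g1@t, -g2@t, tolerance = 1e-15)
  expect_equal(g1@p, g2@p, tolerance = 1e-15)
})

test_that("p decreases monotonically in the mean separation", {
  deltas <- seq(0.5, 8, by = 0.5)
  ps <- vapply(deltas, function(d)
    studentsTTest(d, 2, 3, 0, 2, 3)@p, numeric(1))
  expect_true(all(diff(ps) < 0))
})

test_that("degenerate zero-variance groups are handled as documented", {
  same <- studentsTTest(5, 0, 3, 5, 0, 3)
  expect_equal(same@t, 0); expect_equal(same@p, 1)
  expect_false(same@degenerate)
  diffm <- studentsTTest(5, 0, 3, 4, 0, 3)
  expect_equal(diffm@p, 0)
  expect_true(diffm@degenerate)
  expect_error(studentsTTest(1, 1, 1, 0, 1, 3), "n >= 2")
})

test_that("identical group summaries give t = 0, p = 1", {
  g <- studentsTTest(3.2, 1.1, 4, 3.2, 1.1, 4)
  expect_equal(g@t, 0)
  expect_equal(g@p, 1)
})
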