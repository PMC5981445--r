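#' Stack-averaged quantitative parameters Id, Is and r
#'
#' Measures, slice by slice, the density `Id` over the full grid, and the
#' peak spectral intensity `Is` and ellipse ratio `r` over the selected
#' region, then averages each parameter across the z-stack.
#'
#' @param stack An [ImageStack-class].
#' @param grid A [GridSpec-class] for the area-fraction grid.
#' @param roi An [RoiRect-class] for the spectral parameters; default the
#'   largest centered square, see [centeredRoi()].
#' @param thresholdScope `"slice"` estimates the noise threshold per slice
#'   (default); `"stack"` estimates it once from all voxels.
#' @param thresholdMethod,thresholdValue Passed to
#'   [estimateNoiseThreshold()] (`thresholdValue` only for `"fixed"`).
#' @param frac,rMinPx,nBins,window Spectral options, see [spectralParams()].
#' @return A [StackSummary-class]; per-slice values are kept in the
#'   `perSlice` slot.
#' @export
summarizeStack <- function(stack, grid = gridSpec(), roi = centeredRoi(stack),
                           thresholdScope = c("slice", "stack"),
                           thresholdMethod = "background-percentile",
                           thresholdValue = NULL,
                           frac = 0.1, rMinPx = 2L, nBins = 180L,
                           window = "none") {
  stopifnot(is(stack, "ImageStack"))
  thresholdScope <- match.arg(thresholdScope)
  ns <- nSlices(stack)
  stackThr <- if (thresholdScope == "stack")
    estimateNoiseThreshold(matrix(voxels(stack), nrow = dim(stack)[1L]),
                           method = thresholdMethod, value = thresholdValue)
  per <- lapply(seq_len(ns), function(i) {
    sl <- getSlice(stack, i)
    thr <- if (thresholdScope == "slice")
      estimateNoiseThreshold(sl, method = thresholdMethod, value = thresholdValue)
    else stackThr
    afm <- areaFractionMap(sl, grid = grid, threshold = thr)
    sp <- spectralParams(cropSlice(sl, roi), frac = frac, rMinPx = rMinPx,
                         nBins = nBins, window = window)
    data.frame(slice = i, Id = densityIndex(afm), Is = sp$Is, r = sp$r,
               threshold = thr)
  })
  per <- do.call(rbind, per)
  new("StackSummary", Id = mean(per$Id), Is = mean(per$Is), r = mean(per$r),
      nSlices = as.integer(ns), perSlice = per)
}

#' Percent change of the stack parameters, after versus before
#'
#' `100 * (after - before) / before` for each of `Id`, `Is` and `r`.
#' Undefined (and an error) when a before value is zero.
#'
#' @param before,after [StackSummary-class] objects for the image pair.
#' @return Named numeric vector `c(dId, dIs, dr)`, in percent; a ratio
#'   moving from 2.0 to 3.0, for instance, is a +50 percent change.
#' @export
percentChange <- function(before, after) {
  stopifnot(is(before, "StackSummary"), is(after, "StackSummary"))
  b <- c(Id = before@Id, Is = before@Is, r = before@r)
  a <- c(Id = after@Id, Is = after@Is, r = after@r)
  if (any(b == 0)) stop("undefined relative change: a before value is zero")
  ch <- 100 * (a - b) / b
  names(ch) <- c("dId", "dIs", "dr")
  ch
}

#' Mean, sample SD and n of a group of percent changes
#'
#' @param changes Numeric vector, length >= 2.
#' @return Named list `mean`, `sd` (divisor n - 1), `n`.
#' @export
groupSummary <- function(changes) {
  if (length(changes) < 2L) stop("a group needs at least 2 values")
  list(mean = mean(changes), sd = stats::sd(changes), n = length(changes))
}

#' Unpaired two-tailed Student's t test from summaries or raw samples
#'
#' Pooled-variance two-sample t test (the classic Student test for small
#' samples), computable directly from printed group summaries
#' (mean, SD, n): \deqn{t = (m_A - m_B) / (s_p \sqrt{1/n_A + 1/n_B}),\quad
#' s_p^2 = \frac{(n_A-1)s_A^2 + (n_B-1)s_B^2}{n_A + n_B - 2},}
#' with `df = nA + nB - 2` and a two-tailed p value. A Welch variant
#' (Satterthwaite df, no pooling) is available via `method = "welch"`.
#'
#' Degenerate inputs: both SDs zero with equal means gives `t = 0, p = 1`;
#' both SDs zero with unequal means gives `p = 0` with the `degenerate`
#' flag set.
#'
#' @param meanA,sdA,nA Summary of group A, or — if `a` is given — ignored.
#' @param meanB,sdB,nB Summary of group B.
#' @param a,b Optional raw sample vectors; when supplied, their
#'   mean/SD/n are used (identical results to passing the summaries).
#' @param method `"pooled"` (default) or `"welch"`.
#' @return A [GroupComparison-class].
#' @examples
#' # density changed +10.14 +/- 5.83 % (n = 3) with e-beam exposure versus
#' # -3.01 +/- 1.64 % (n = 3) without:
#' studentsTTest(10.14, 5.83, 3, -3.01, 1.64, 3)
#' @export
studentsTTest <- function(meanA, sdA, nA, meanB, sdB, nB,
                          a = NULL, b = NULL,
                          method = c("pooled", "welch")) {
  method <- match.arg(method)
  if (!is.null(a)) { meanA <- mean(a); sdA <- stats::sd(a); nA <- length(a) }
  if (!is.null(b)) { meanB <- mean(b); sdB <- stats::sd(b); nB <- length(b) }
  if (nA < 2L || nB < 2L) stop("each group needs n >= 2")
  if (sdA < 0 || sdB < 0) stop("SDs must be nonnegative")

  degenerate <- FALSE
  if (sdA == 0 && sdB == 0) {
    if (meanA == meanB) { t <- 0; p <- 1 }
    else { t <- sign(meanA - meanB) * Inf; p <- 0; degenerate <- TRUE }
    df <- nA + nB - 2
  } else if (method == "pooled") {
    df <- nA + nB - 2
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / df
    t <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
    p <- 2 * stats::pt(-abs(t), df)
  } else {
    vA <- sdA^2 / nA; vB <- sdB^2 / nB
    t <- (meanA - meanB) / sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
    p <- 2 * stats::pt(-abs(t), df)
  }
  new("GroupComparison", meanA = as.numeric(meanA), sdA = as.numeric(sdA),
      nA = as.integer(nA), meanB = as.numeric(meanB), sdB = as.numeric(sdB),
      nB = as.integer(nB), t = as.numeric(t), df = as.numeric(df),
      p = as.numeric(p), method = method, degenerate = degenerate)
}
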