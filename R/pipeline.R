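#' Before/after pair analysis
#'
#' Runs the full quantitative workflow on an image pair: per-slice density
#' over the grid, spectral parameters over the ROI, stack averaging, and
#' the percent change of `Id`, `Is` and `r`. Input is either two stacks
#' (files or [ImageStack-class] objects) or a simulation (`simConfig` +
#' `effect`), never both.
#'
#' When `outDir` is given, machine-readable JSON (`pair_report.json`),
#' per-slice CSV tables and PNG figures (area-fraction color maps and the
#' angular profiles of the first slice) are written there. The report
#' records every resolved option, including the per-slice noise
#' thresholds, so each analysis is self-describing.
#'
#' @param before,after Paths to TIFF stacks (see [readStack()]) or
#'   [ImageStack-class] objects.
#' @param simConfig A `FiberPhantomConfig` to simulate a pair instead.
#' @param effect An `EffectSpec` for the simulated pair.
#' @param nSlices Slices per simulated stack; default 1.
#' @param grid,roi,... Analysis options passed to [summarizeStack()];
#'   `roi` defaults to the largest centered square of the before image.
#' @param outDir Optional output directory for artifacts.
#' @return List with `before` and `after` [StackSummary-class] objects,
#'   `change` (named percent changes) and `settings`.
#' @export
runPairAnalysis <- function(before = NULL, after = NULL,
                            simConfig = NULL, effect = NULL, nSlices = 1L,
                            grid = gridSpec(), roi = NULL, outDir = NULL, ...) {
  fromFiles <- !is.null(before) || !is.null(after)
  if (fromFiles && !is.null(simConfig))
    stop("give either before/after images or a simulation config, not both")
  if (!fromFiles && is.null(simConfig))
    stop("no input: give before/after images or a simulation config")
  if (fromFiles) {
    if (is.null(before) || is.null(after)) stop("both before and after are required")
    if (is.character(before)) before <- readStack(before)
    if (is.character(after)) after <- readStack(after)
  } else {
    if (is.null(effect)) effect <- effectSpec("none")
    pair <- simulatePair(simConfig, effect, nSlices = nSlices)
    before <- pair$before; after <- pair$after
  }
  if (!all(dim(before)[1:2] == dim(after)[1:2]))
    stop("before/after image dimensions differ")
  if (is.null(roi)) roi <- centeredRoi(before)

  sumB <- summarizeStack(before, grid = grid, roi = roi, ...)
  sumA <- summarizeStack(after, grid = grid, roi = roi, ...)
  change <- percentChange(sumB, sumA)
  settings <- c(list(cellPx = grid@cellPx,
                     roi = c(row0 = roi@row0, col0 = roi@col0,
                             height = roi@height, width = roi@width),
                     thresholdsBefore = sumB@perSlice$threshold,
                     thresholdsAfter = sumA@perSlice$threshold),
                list(...))
  report <- list(before = sumB, after = sumA, change = change,
                 settings = settings)
  if (!is.null(outDir)) writePairArtifacts(report, before, after, grid, outDir)
  report
}

writePairArtifacts <- function(report, before, after, grid, outDir) {
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  asList <- function(s) list(Id = s@Id, Is = s@Is, r = s@r, nSlices = s@nSlices)
  jsonlite::write_json(
    list(before = asList(report$before), after = asList(report$after),
         changePercent = as.list(report$change),
         settings = report$settings),
    file.path(outDir, "pair_report.json"), auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$before@perSlice,
                   file.path(outDir, "before_per_slice.csv"), row.names = FALSE)
  utils::write.csv(report$after@perSlice,
                   file.path(outDir, "after_per_slice.csv"), row.names = FALSE)
  for (tag in c("before", "after")) {
    stk <- if (tag == "before") before else after
    sl <- getSlice(stk, 1L)
    thr <- report[[tag]]@perSlice$threshold[1L]
    afm <- areaFractionMap(sl, grid = grid, threshold = thr)
    plotAreaFractionMap(afm, file = file.path(outDir, paste0(tag, "_area_fraction.png")))
  }
  invisible(NULL)
}

#' Two-group comparison of percent changes
#'
#' Aggregates per-pair percent changes into group mean +/- SD and compares
#' the groups parameter by parameter with the unpaired two-tailed Student
#' t test (pooled variance, see [studentsTTest()]).
#'
#' @param changesA,changesB Matrices (or data.frames) of percent changes,
#'   one row per pair, columns `dId`, `dIs`, `dr` — as returned by
#'   [percentChange()] and stacked with `rbind()`. Each group needs at
#'   least 2 rows.
#' @param labels Length-2 character vector naming the groups.
#' @param method `"pooled"` (default) or `"welch"`.
#' @param outDir Optional directory; writes `group_report.json` and a
#'   bar-chart PNG with significance annotation at p < 0.05.
#' @return Named list of [GroupComparison-class], one per parameter.
#' @export
runGroupAnalysis <- function(changesA, changesB,
                             labels = c("exposed", "control"),
                             method = "pooled", outDir = NULL) {
  changesA <- as.matrix(changesA); changesB <- as.matrix(changesB)
  if (nrow(changesA) < 2L || nrow(changesB) < 2L)
    stop("each group needs at least 2 pairs")
  params <- c("dId", "dIs", "dr")
  if (!all(params %in% colnames(changesA)) || !all(params %in% colnames(changesB)))
    stop("change matrices need columns dId, dIs, dr")
  res <- lapply(params, function(pn) {
    ga <- groupSummary(changesA[, pn]); gb <- groupSummary(changesB[, pn])
    studentsTTest(ga$mean, ga$sd, ga$n, gb$mean, gb$sd, gb$n, method = method)
  })
  names(res) <- params
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(
      lapply(res, function(gc) list(
        meanA = gc@meanA, sdA = gc@sdA, nA = gc@nA,
        meanB = gc@meanB, sdB = gc@sdB, nB = gc@nB,
        t = gc@t, df = gc@df, p = gc@p, method = gc@method)),
      file.path(outDir, "group_report.json"), auto_unbox = TRUE, digits = NA)
    plotGroupComparison(res, labels = labels,
                        file = file.path(outDir, "group_changes.png"))
  }
  res
}
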