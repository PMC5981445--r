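#' Color map of an area-fraction grid
#'
#' @param map An [AreaFractionMap-class].
#' @param file Optional PNG path; when given the plot goes to that file.
#' @param main Plot title.
#' @return Invisibly, the map.
#' @export
plotAreaFractionMap <- function(map, file = NULL, main = "SHG area fraction") {
  stopifnot(is(map, "AreaFractionMap"))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 600)
    on.exit(grDevices::dev.off())
  }
  v <- map@values
  graphics::image(t(v)[, nrow(v):1, drop = FALSE], zlim = c(0, 1),
                  col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, main = main, useRaster = TRUE)
  graphics::mtext(sprintf("Id = %.3f", mean(v)), side = 1, line = 1)
  invisible(map)
}

#' Orientation-tick overlay of a classified grid
#'
#' Anisotropic cells get a tick along the preferred fiber orientation;
#' dark cells are filled cyan, isotropic cells purple.
#'
#' @param om An [OrientationMap-class].
#' @param file Optional PNG path.
#' @param main Plot title.
#' @return Invisibly, the map.
#' @export
plotOrientationMap <- function(om, file = NULL, main = "Preferred fiber orientation") {
  stopifnot(is(om, "OrientationMap"))
  if (!is.null(file)) {
    grDevices::png(file, width = 640, height = 640)
    on.exit(grDevices::dev.off())
  }
  d <- dim(om@labels)
  graphics::plot(NA, xlim = c(0, d[2L]), ylim = c(0, d[1L]), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  for (i in seq_len(d[1L])) for (j in seq_len(d[2L])) {
    cx <- j - 0.5; cy <- d[1L] - i + 0.5
    lab <- om@labels[i, j]
    if (lab == "dark") {
      graphics::rect(j - 1, cy - 0.5, j, cy + 0.5, col = "cyan", border = NA)
    } else if (lab == "isotropic") {
      graphics::rect(j - 1, cy - 0.5, j, cy + 0.5, col = "mediumpurple1", border = NA)
    } else {
      a <- om@orientationDeg[i, j] * pi / 180
      graphics::segments(cx - 0.45 * cos(a), cy - 0.45 * sin(a),
                         cx + 0.45 * cos(a), cy + 0.45 * sin(a), lwd = 2)
    }
  }
  graphics::box()
  invisible(om)
}

#' Bar chart of group percent changes with significance annotation
#'
#' Mean +/- SD bars per parameter and group; comparisons at p < 0.05 are
#' starred, others marked n.s.
#'
#' @param comparisons Named list of [GroupComparison-class]
#'   (`dId`, `dIs`, `dr`), as returned by [runGroupAnalysis()].
#' @param labels Group names (length 2).
#' @param file Optional PNG path.
#' @return Invisibly, the comparisons.
#' @export
plotGroupComparison <- function(comparisons, labels = c("exposed", "control"),
                                file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 720, height = 520)
    on.exit(grDevices::dev.off())
  }
  means <- rbind(vapply(comparisons, function(g) g@meanA, numeric(1)),
                 vapply(comparisons, function(g) g@meanB, numeric(1)))
  sds <- rbind(vapply(comparisons, function(g) g@sdA, numeric(1)),
               vapply(comparisons, function(g) g@sdB, numeric(1)))
  nice <- c(dId = "Id", dIs = "Is", dr = "r")[names(comparisons)]
  ylim <- range(0, means - sds, means + sds)
  ylim <- ylim + c(-0.1, 0.22) * diff(ylim)
  bp <- graphics::barplot(means, beside = TRUE, names.arg = nice,
                          col = c("firebrick", "steelblue"),
                          ylim = ylim, ylab = "change (%)")
  graphics::arrows(bp, means - sds, bp, means + sds, angle = 90, code = 3,
                   length = 0.05)
  graphics::legend("topright", legend = labels,
                   fill = c("firebrick", "steelblue"), bty = "n")
  top <- apply(means + sds, 2, max)
  for (k in seq_along(comparisons)) {
    mark <- if (comparisons[[k]]@p < 0.05) "*" else "n.s."
    graphics::text(mean(bp[, k]), top[k] + 0.08 * diff(ylim), mark, cex = 1.3)
  }
  graphics::abline(h = 0)
  invisible(comparisons)
}
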