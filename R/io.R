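#' Read an image stack from a multi-page grayscale TIFF
#'
#' Each TIFF page becomes one slice. Physical metadata (pixel size, z step,
#' intensity scale) are taken from the JSON sidecar written by
#' [writeStack()] (`<path>.json`) when present, otherwise from the
#' defaults given here.
#'
#' Integer-valued data written by [writeStack()] round-trip exactly; other
#' data round-trip to 32-bit storage precision (relative error below 1e-9).
#'
#' @param path Path to a single- or multi-page grayscale TIFF.
#' @param pixelSizeUm,zStepUm Fallback metadata when no sidecar exists.
#' @return An [ImageStack-class].
#' @seealso [writeStack()]
#' @export
readStack <- function(path, pixelSizeUm = 1, zStepUm = 0.5) {
  if (!file.exists(path)) stop("file not found: ", path)
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar)) meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)

  asIs <- !is.null(meta) && identical(meta$storage, "uint16")
  pages <- tiff::readTIFF(path, all = TRUE, as.is = asIs)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) == 0L) stop("no pages in TIFF: ", path)
  mats <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) {
      same <- vapply(seq_len(dim(p)[3L]),
                     function(k) all(p[, , k] == p[, , 1L]), logical(1))
      if (!all(same)) stop("non-grayscale TIFF page")
      p <- p[, , 1L]
    }
    if (length(dim(p)) != 2L || any(dim(p) == 0L)) stop("zero-size or malformed page")
    p
  })
  vox <- array(unlist(mats, use.names = FALSE),
               dim = c(dim(mats[[1L]]), length(mats)))
  scale <- if (!is.null(meta$scale)) meta$scale else 1
  if (!asIs && scale != 1) vox <- vox * scale
  imageStack(vox,
             pixelSizeUm = if (!is.null(meta$pixelSizeUm)) meta$pixelSizeUm else pixelSizeUm,
             zStepUm = if (!is.null(meta$zStepUm)) meta$zStepUm else zStepUm)
}

#' Write an image stack to a multi-page TIFF with a JSON sidecar
#'
#' Intensities are stored without rescaling of their meaning: integer data
#' with a maximum below 65536 go to a 16-bit container and are recovered
#' bit-exactly; anything else goes to a 32-bit container after division by
#' a power-of-two scale recorded in the sidecar, recovering values to
#' better than 1e-9 relative error. The sidecar (`<path>.json`) also
#' records `pixelSizeUm` and `zStepUm`.
#'
#' @param stack An [ImageStack-class].
#' @param path Output TIFF path; the sidecar is written to `<path>.json`.
#' @return `path`, invisibly.
#' @export
writeStack <- function(stack, path) {
  stopifnot(is(stack, "ImageStack"))
  v <- voxels(stack)
  isInt <- all(v == round(v))
  if (isInt && max(v) <= 65535) {
    storage <- "uint16"; scale <- 1
    pages <- lapply(seq_len(dim(v)[3L]), function(i) v[, , i] / 65535)
    bits <- 16L
  } else {
    storage <- "scaled32"
    mx <- max(v)
    scale <- if (mx <= 1) 1 else 2^ceiling(log2(mx))
    pages <- lapply(seq_len(dim(v)[3L]), function(i) v[, , i] / scale)
    bits <- 32L
  }
  tiff::writeTIFF(pages, path, bits.per.sample = bits, compression = "none",
                  reduce = FALSE)
  jsonlite::write_json(
    list(storage = storage, scale = scale,
         pixelSizeUm = pixelSizeUm(stack), zStepUm = zStepUm(stack)),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname cropStack
#' @export
setMethod("cropStack", signature("ImageStack", "RoiRect"), function(x, roi) {
  d <- dim(x@voxels)
  if (roi@row0 + roi@height > d[1L] || roi@col0 + roi@width > d[2L])
    stop("ROI extends outside the image")
  v <- x@voxels[roi@row0 + seq_len(roi@height),
                roi@col0 + seq_len(roi@width), , drop = FALSE]
  imageStack(v, pixelSizeUm = x@pixelSizeUm, zStepUm = x@zStepUm)
})

## extract the ROI of a single 2-D slice (internal)
cropSlice <- function(img, roi) {
  if (roi@row0 + roi@height > nrow(img) || roi@col0 + roi@width > ncol(img))
    stop("ROI extends outside the image")
  img[roi@row0 + seq_len(roi@height), roi@col0 + seq_len(roi@width), drop = FALSE]
}

#' Largest centered square ROI admitted by an image
#'
#' Convenience for selecting the spectral-analysis region: a centered
#' square whose side is the largest multiple of `multiple` not exceeding
#' `min(rows, cols)` (and at most `maxSide`).
#'
#' @param img A matrix or [ImageStack-class].
#' @param maxSide Optional cap on the side length.
#' @param multiple Side length is rounded down to a multiple of this.
#' @return An [RoiRect-class].
#' @export
centeredRoi <- function(img, maxSide = Inf, multiple = 2L) {
  d <- if (is(img, "ImageStack")) dim(img)[1:2] else dim(img)
  side <- min(d[1L], d[2L], maxSide)
  side <- (side %/% multiple) * multiple
  roiRect((d[1L] - side) %/% 2, (d[2L] - side) %/% 2, side, side)
}
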