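# Classical segmentation of the peripheral-arcade region (SEG-PA) and the
# perilesional dark halo (SEG-DH). All operations are pure and
# deterministic. Default parameters (binarization window/offset, ring
# radii, region-growing tolerance, equalization tiles/clip) were fixed once
# on phantom renders and are exposed in `morphoParams()`.

#' Default parameters for the classical segmentation algorithms
#'
#' Ring radii are specified at the 304 x 304 reference scale and rescaled
#' proportionally to the image side at run time.
#'
#' @param window odd local-statistics window for vessel binarization (px).
#' @param offset binarization offset as a fraction of the local range.
#' @param ringOutward,ringInward ring half-widths at 304 px scale.
#' @param tolerance region-growing intensity tolerance (intensity units).
#' @param searchOutward outer radius of the dark-halo search annulus at
#'   304 px scale.
#' @param clipLimit,nTiles contrast-limited equalization settings.
#' @param hypoMargin the halo is hypointense by definition: the grown region
#'   is restricted to pixels at least this far below the median enhanced
#'   intensity.
#' @return Named list of parameters.
#' @export
morphoParams <- function(window = 15L, offset = 0.05, ringOutward = 5L,
                         ringInward = 5L, tolerance = 0.15,
                         searchOutward = 30L, clipLimit = 2, nTiles = 8L,
                         hypoMargin = 0.05) {
  list(window = as.integer(window), offset = offset,
       ringOutward = as.integer(ringOutward),
       ringInward = as.integer(ringInward), tolerance = tolerance,
       searchOutward = as.integer(searchOutward),
       clipLimit = clipLimit, nTiles = as.integer(nTiles),
       hypoMargin = hypoMargin)
}

scaleRadius <- function(r, n) max(1L, as.integer(round(r * n / 304)))

#' Binarize vessels by local-mean thresholding
#'
#' A pixel is foreground iff its intensity strictly exceeds the local mean
#' over a \code{window x window} neighbourhood (truncated at the border)
#' minus \code{offset} times the local intensity range. The result is
#' restricted to the given region mask; pixels outside are 0.
#'
#' @param enface numeric matrix in \code{[0,1]}.
#' @param mask 0/1 region within which to evaluate (typically the dilated
#'   CNV mask).
#' @param window odd integer >= 3.
#' @param offset fraction of the local range subtracted from the local mean.
#' @return 0/1 matrix: vessel pixels inside \code{mask}.
#' @export
binarizeVessels <- function(enface, mask, window = 15L, offset = 0.05) {
  assertImage(enface); assertMask(mask)
  assertSameShape(enface, mask)
  window <- as.integer(window)
  if (window < 3L || window %% 2L == 0L) stop("window must be odd and >= 3")
  st <- .local_stats(enface, window)
  thr <- st$mean - offset * (st$max - st$min)
  # strict exceedance with a small numerical guard so that constant regions
  # (integral-image rounding) never binarize to vessels
  (enface > thr + 1e-9) * mask
}

#' Invert a binary image within a mask
#'
#' Inside the mask the foreground/background are swapped (vessels become
#' spaces); outside the mask everything is 0.
#'
#' @param binary,mask 0/1 matrices of equal shape.
#' @return 0/1 matrix.
#' @export
invertWithinMask <- function(binary, mask) {
  assertMask(binary, "binary"); assertMask(mask)
  assertSameShape(binary, mask)
  (1 - binary) * mask
}

#' Ring mask straddling a lesion boundary
#'
#' \code{dilate(mask, disk(outward)) AND NOT erode(mask, disk(inward))}: a
#' band of width about \code{outward + inward} centred on the mask boundary.
#'
#' @param mask 0/1 matrix.
#' @param outward dilation radius (>= 1).
#' @param inward erosion radius (>= 0); 0 restricts the ring to the outside
#'   of the mask.
#' @return 0/1 matrix.
#' @export
ringMask <- function(mask, outward, inward = outward) {
  assertMask(mask)
  if (outward < 1) stop("outward radius must be >= 1")
  if (inward < 0) stop("inward radius must be >= 0")
  if (sum(mask) == 0) return(mask * 0)
  dilateMask(mask, as.integer(outward)) * (1 - erodeMask(mask, as.integer(inward)))
}

#' SEG-PA: extract the peripheral-arcade region
#'
#' Pipeline: binarize vessels within the dilated CNV mask, invert within
#' that region so inter-vessel spaces become foreground, then multiply by a
#' ring mask straddling the lesion margin. The output marks exactly the
#' non-vessel pixels within the marginal ring.
#'
#' @param enface outer-retina grid in \code{[0,1]}.
#' @param mask 0/1 CNV mask of equal shape.
#' @param params list from \code{\link{morphoParams}}.
#' @return 0/1 peripheral-arcade mask.
#' @export
segPA <- function(enface, mask, params = morphoParams()) {
  assertImage(enface); assertMask(mask)
  assertSameShape(enface, mask)
  n <- nrow(enface)
  ro <- scaleRadius(params$ringOutward, n)
  ri <- scaleRadius(params$ringInward, n)
  region <- dilateMask(mask, ro)
  vessels <- binarizeVessels(enface, region, params$window, params$offset)
  spaces <- invertWithinMask(vessels, region)
  ringMask(mask, ro, ri) * spaces
}

#' Contrast-limited local histogram equalization of the choriocapillaris
#'
#' Wraps \code{EBImage::clahe}; output clipped to \code{[0,1]}. Constant
#' images pass through unchanged.
#'
#' @param enface numeric matrix in \code{[0,1]}.
#' @param nTiles tiles per side.
#' @param clipLimit contrast limit.
#' @return Enhanced matrix in \code{[0,1]}.
#' @export
enhanceChoroid <- function(enface, nTiles = 8L, clipLimit = 2) {
  assertImage(enface)
  if (max(enface) - min(enface) < 1e-12) return(enface)
  out <- EBImage::clahe(EBImage::Image(t(enface)), nx = nTiles, ny = nTiles,
                        limit = clipLimit)
  clip01(t(EBImage::imageData(out)))
}

#' Seeded region growing
#'
#' Grows a 4-connected region from the seed set: a candidate pixel is
#' accepted when its intensity differs from the current region mean by at
#' most \code{tolerance}. The mean is by default the running mean of all
#' accepted pixels (\code{criterion = "running"}); \code{"fixed"} keeps the
#' mean of the seed set. Deterministic: the queue is FIFO, seeds and
#' neighbours are processed in row-major order, and each pixel is examined
#' at most once.
#'
#' @param image numeric matrix.
#' @param seeds integer matrix with columns \code{row}, \code{col}
#'   (0-based), all within bounds.
#' @param tolerance intensity tolerance >= 0.
#' @param criterion \code{"running"} or \code{"fixed"} mean.
#' @return 0/1 matrix containing all seed pixels.
#' @export
regionGrow <- function(image, seeds, tolerance,
                       criterion = c("running", "fixed")) {
  criterion <- match.arg(criterion)
  if (is.null(dim(seeds)) || nrow(seeds) == 0) stop("seed set must be non-empty")
  if (tolerance < 0) stop("tolerance must be >= 0")
  seeds <- seeds[order(seeds[, 1], seeds[, 2]), , drop = FALSE]
  .region_grow(image, matrix(as.integer(seeds), ncol = 2),
               tolerance, criterion == "running") * 1
}

# Outer boundary seeds of a mask: its 8-connected contour shifted one pixel
# outward, i.e. dilate(mask, 1) minus the mask.
maskBoundarySeeds <- function(mask) {
  b <- dilateMask(mask, 1L) * (1 - mask)
  which(b == 1, arr.ind = TRUE) - 1L
}

#' SEG-DH: extract the perilesional dark halo
#'
#' The CNV mask boundary (offset one pixel outward) seeds a region-growing
#' pass over the contrast-enhanced choriocapillaris channel; the grown
#' region is restricted to an annular search region outside the lesion and
#' to hypointense pixels (below the median enhanced intensity), since the
#' halo is by definition a dark region.
#'
#' @param choroid choriocapillaris grid in \code{[0,1]}.
#' @param mask non-empty 0/1 CNV mask of equal shape.
#' @param params list from \code{\link{morphoParams}}.
#' @return 0/1 dark-halo mask, disjoint from \code{mask}.
#' @export
segDH <- function(choroid, mask, params = morphoParams()) {
  assertImage(choroid); assertMask(mask)
  assertSameShape(choroid, mask)
  if (sum(mask) == 0) stop("CNV mask is empty")
  enhanced <- enhanceChoroid(choroid, params$nTiles, params$clipLimit)
  seeds <- maskBoundarySeeds(mask)
  grown <- regionGrow(enhanced, seeds, params$tolerance, "running")
  search <- ringMask(mask, scaleRadius(params$searchOutward, nrow(choroid)), 0L)
  hypo <- (enhanced < stats::median(enhanced) - params$hypoMargin) * 1
  grown * (1 - mask) * search * hypo
}
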