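#' Paired OCTA en-face images
#'
#' Container for one co-registered pair of en-face projections: the
#' outer-retina slab (where the CNV vascular network is visible) and the
#' choriocapillaris slab (where the perilesional dark halo is visible).
#' Both grids are numeric matrices in \code{[0,1]} with identical shape;
#' origin top-left, row-major.
#'
#' @slot outerRetina numeric matrix in \code{[0,1]}.
#' @slot choriocapillaris numeric matrix in \code{[0,1]}, same shape.
#' @slot subjectId character scalar grouping images from one patient.
#' @slot imageId character scalar unique within a dataset.
#'
#' @exportClass EnFacePair
#' @aliases EnFacePair-class
setClass("EnFacePair",
  representation(outerRetina = "matrix", choriocapillaris = "matrix",
                 subjectId = "character", imageId = "character"))

setValidity("EnFacePair", function(object) {
  msg <- character()
  if (!identical(dim(object@outerRetina), dim(object@choriocapillaris)))
    msg <- c(msg, "outer-retina and choriocapillaris grids differ in shape")
  for (nm in c("outerRetina", "choriocapillaris")) {
    g <- slot(object, nm)
    if (!is.numeric(g) || anyNA(g) || min(g) < 0 || max(g) > 1)
      msg <- c(msg, paste0(nm, " must be numeric in [0,1] without NAs"))
  }
  if (length(object@subjectId) != 1 || length(object@imageId) != 1)
    msg <- c(msg, "subjectId and imageId must be scalars")
  if (length(msg)) msg else TRUE
})

#' Construct an EnFacePair
#'
#' @param outerRetina,choriocapillaris numeric matrices in \code{[0,1]} with
#'   identical shape.
#' @param subjectId,imageId identifier strings.
#' @return An \linkS4class{EnFacePair}.
#' @export
#' @examples
#' p <- EnFacePair(matrix(0, 8, 8), matrix(1, 8, 8), "s1", "i1")
#' dim(outerRetina(p))
EnFacePair <- function(outerRetina, choriocapillaris,
                       subjectId = "s1", imageId = "i1") {
  new("EnFacePair", outerRetina = outerRetina,
      choriocapillaris = choriocapillaris,
      subjectId = as.character(subjectId), imageId = as.character(imageId))
}

#' Phantom generator configuration
#'
#' Parameters controlling one synthetic OCTA en-face pair: lesion geometry,
#' which of the five activity features are rendered, texture/noise levels and
#' the seed. The lesion (including its halo annulus and vessel thickening)
#' must fit inside the image; all intensity parameters keep pixels in
#' \code{[0,1]}; identical config + seed regenerates bit-identical output.
#'
#' @slot imageSize integer, pixels per side (default 304).
#' @slot lesionCenter numeric length-2, 0-based \code{(row, col)} pixel
#'   coordinate of the lesion centre.
#' @slot lesionRadius numeric, lesion radius in pixels.
#' @slot featureToggles named logical of length 5 in \code{octaFeatures()}
#'   order; \code{shape} = TRUE renders the compact sea-fan lesion,
#'   FALSE the sparse filamentous form.
#' @slot vesselWidth numeric, drawn vessel thickness in pixels.
#' @slot nSpokes integer >= 3, number of radial vessels.
#' @slot haloWidth numeric, dark-halo annulus width in pixels.
#' @slot haloContrast numeric in (0,1), multiplicative darkening inside the
#'   halo annulus on the choriocapillaris channel.
#' @slot noiseSigma numeric >= 0, additive Gaussian noise sd.
#' @slot backgroundTextureScale numeric, correlation length (pixels) of the
#'   band-pass background capillary texture.
#' @slot seed integer master seed.
#'
#' @exportClass PhantomConfig
#' @aliases PhantomConfig-class
setClass("PhantomConfig",
  representation(imageSize = "integer", lesionCenter = "numeric",
                 lesionRadius = "numeric", featureToggles = "logical",
                 vesselWidth = "numeric", nSpokes = "integer",
                 haloWidth = "numeric", haloContrast = "numeric",
                 noiseSigma = "numeric", backgroundTextureScale = "numeric",
                 seed = "integer"))

setValidity("PhantomConfig", function(object) {
  msg <- character()
  n <- object@imageSize
  if (length(n) != 1 || n < 16) msg <- c(msg, "imageSize must be a single value >= 16")
  if (object@lesionRadius <= 0) msg <- c(msg, "lesionRadius must be positive")
  if (object@vesselWidth <= 0) msg <- c(msg, "vesselWidth must be positive")
  if (object@haloWidth <= 0) msg <- c(msg, "haloWidth must be positive")
  if (object@nSpokes < 3) msg <- c(msg, "nSpokes must be >= 3")
  if (object@haloContrast <= 0 || object@haloContrast >= 1)
    msg <- c(msg, "haloContrast must lie in (0, 1)")
  if (object@noiseSigma < 0) msg <- c(msg, "noiseSigma must be >= 0")
  if (!identical(sort(names(object@featureToggles)), sort(OCTA_FEATURES)))
    msg <- c(msg, "featureToggles must be named by octaFeatures()")
  # lesion + halo + vessel thickening must fit with margin
  margin <- object@lesionRadius + object@haloWidth +
    ceiling(object@vesselWidth / 2) + 1
  ctr <- object@lesionCenter
  if (length(ctr) != 2) msg <- c(msg, "lesionCenter must have length 2")
  else if (any(ctr - margin < 0) || any(ctr + margin > n - 1))
    msg <- c(msg, "lesion geometry (radius + halo + vessel width) exceeds image bounds")
  if (length(msg)) msg else TRUE
})

#' Construct a PhantomConfig
#'
#' Defaults emulate a 6 x 6 mm^2 en-face scan sampled at 304 x 304 with a
#' central lesion of radius 60 px (about 1.2 mm). See
#' \linkS4class{PhantomConfig} for slot meanings.
#'
#' @param imageSize pixels per side.
#' @param lesionCenter 0-based \code{(row, col)}; default image centre.
#' @param lesionRadius lesion radius, pixels.
#' @param featureToggles named logical over \code{octaFeatures()}.
#' @param vesselWidth,nSpokes,haloWidth,haloContrast,noiseSigma,backgroundTextureScale
#'   see class documentation.
#' @param seed integer master seed.
#' @return A validated \linkS4class{PhantomConfig}.
#' @export
#' @examples
#' cfg <- phantomConfig(imageSize = 128, lesionRadius = 25, haloWidth = 6)
#' cfg
phantomConfig <- function(imageSize = 304L,
                          lesionCenter = NULL,
                          lesionRadius = 60,
                          featureToggles = setNames(rep(TRUE, 5), octaFeatures()),
                          vesselWidth = 3,
                          nSpokes = 10L,
                          haloWidth = 12,
                          haloContrast = 0.5,
                          noiseSigma = 0.03,
                          backgroundTextureScale = 4,
                          seed = 1L) {
  if (is.null(lesionCenter)) lesionCenter <- rep((imageSize - 1) / 2, 2)
  toggles <- setNames(rep(FALSE, 5), OCTA_FEATURES)
  toggles[names(featureToggles)] <- as.logical(featureToggles)
  new("PhantomConfig", imageSize = as.integer(imageSize),
      lesionCenter = as.numeric(lesionCenter),
      lesionRadius = as.numeric(lesionRadius),
      featureToggles = toggles, vesselWidth = as.numeric(vesselWidth),
      nSpokes = as.integer(nSpokes), haloWidth = as.numeric(haloWidth),
      haloContrast = as.numeric(haloContrast),
      noiseSigma = as.numeric(noiseSigma),
      backgroundTextureScale = as.numeric(backgroundTextureScale),
      seed = as.integer(seed))
}

#' One synthetic OCTA sample with ground truth
#'
#' Output of \code{\link{generatePhantomPair}}: the rendered
#' \linkS4class{EnFacePair} plus exact ground-truth masks for the CNV lesion,
#' the peripheral-arcade inter-vessel spaces and the dark-halo annulus, and
#' the five activity labels implied by the toggles used to draw the image.
#'
#' @slot pair an \linkS4class{EnFacePair}.
#' @slot gtCnvMask,gtPaMask,gtDhMask binary matrices (0/1), same shape as
#'   the image grids; the dark-halo mask is disjoint from the CNV mask, the
#'   arcade mask lies in a band around the lesion margin.
#' @slot labels named integer vector (0/1) over \code{octaFeatures()}.
#'
#' @exportClass PhantomSample
#' @aliases PhantomSample-class
setClass("PhantomSample",
  representation(pair = "EnFacePair", gtCnvMask = "matrix",
                 gtPaMask = "matrix", gtDhMask = "matrix",
                 labels = "integer"))

setValidity("PhantomSample", function(object) {
  msg <- character()
  d <- dim(object@pair@outerRetina)
  for (nm in c("gtCnvMask", "gtPaMask", "gtDhMask")) {
    g <- slot(object, nm)
    if (!identical(dim(g), d)) msg <- c(msg, paste0(nm, " shape differs from image"))
    if (!all(g %in% c(0, 1))) msg <- c(msg, paste0(nm, " must be binary"))
  }
  if (any(object@gtDhMask * object@gtCnvMask == 1))
    msg <- c(msg, "dark-halo mask must be disjoint from the CNV mask")
  if (!identical(sort(names(object@labels)), sort(OCTA_FEATURES)) ||
      !all(object@labels %in% c(0L, 1L)))
    msg <- c(msg, "labels must be 0/1 named by octaFeatures()")
  if (length(msg)) msg else TRUE
})

## ---- generics & accessors -------------------------------------------------

#' @describeIn EnFacePair outer-retina grid
#' @param x object.
#' @export
setGeneric("outerRetina", function(x) standardGeneric("outerRetina"))
#' @describeIn EnFacePair choriocapillaris grid
#' @export
setGeneric("choriocapillaris", function(x) standardGeneric("choriocapillaris"))
#' @describeIn EnFacePair subject identifier
#' @export
setGeneric("subjectId", function(x) standardGeneric("subjectId"))
#' @describeIn EnFacePair image identifier
#' @export
setGeneric("imageId", function(x) standardGeneric("imageId"))
#' @describeIn PhantomSample ground-truth CNV mask
#' @export
setGeneric("cnvMask", function(x) standardGeneric("cnvMask"))
#' @describeIn PhantomSample ground-truth peripheral-arcade mask
#' @export
setGeneric("paMask", function(x) standardGeneric("paMask"))
#' @describeIn PhantomSample ground-truth dark-halo mask
#' @export
setGeneric("dhMask", function(x) standardGeneric("dhMask"))
#' @describeIn PhantomSample activity-criterion labels
#' @export
setGeneric("activityLabels", function(x) standardGeneric("activityLabels"))
#' @describeIn PhantomSample the en-face pair
#' @export
setGeneric("enfacePair", function(x) standardGeneric("enfacePair"))

#' @rdname EnFacePair
#' @export
setMethod("outerRetina", "EnFacePair", function(x) x@outerRetina)
#' @rdname EnFacePair
#' @export
setMethod("choriocapillaris", "EnFacePair", function(x) x@choriocapillaris)
#' @rdname EnFacePair
#' @export
setMethod("subjectId", "EnFacePair", function(x) x@subjectId)
#' @rdname EnFacePair
#' @export
setMethod("imageId", "EnFacePair", function(x) x@imageId)
#' @rdname PhantomSample
#' @param x a \linkS4class{PhantomSample}.
#' @export
setMethod("outerRetina", "PhantomSample", function(x) x@pair@outerRetina)
#' @rdname PhantomSample
#' @export
setMethod("choriocapillaris", "PhantomSample", function(x) x@pair@choriocapillaris)
#' @rdname PhantomSample
#' @export
setMethod("subjectId", "PhantomSample", function(x) x@pair@subjectId)
#' @rdname PhantomSample
#' @export
setMethod("imageId", "PhantomSample", function(x) x@pair@imageId)
#' @rdname PhantomSample
#' @export
setMethod("cnvMask", "PhantomSample", function(x) x@gtCnvMask)
#' @rdname PhantomSample
#' @export
setMethod("paMask", "PhantomSample", function(x) x@gtPaMask)
#' @rdname PhantomSample
#' @export
setMethod("dhMask", "PhantomSample", function(x) x@gtDhMask)
#' @rdname PhantomSample
#' @export
setMethod("activityLabels", "PhantomSample", function(x) x@labels)
#' @rdname PhantomSample
#' @export
setMethod("enfacePair", "PhantomSample", function(x) x@pair)

setMethod("show", "EnFacePair", function(object) {
  d <- dim(object@outerRetina)
  cat(sprintf("EnFacePair %s/%s: %d x %d, outer-retina [%.2f, %.2f], choriocapillaris [%.2f, %.2f]\n",
              object@subjectId, object@imageId, d[1], d[2],
              min(object@outerRetina), max(object@outerRetina),
              min(object@choriocapillaris), max(object@choriocapillaris)))
})

setMethod("show", "PhantomConfig", function(object) {
  on <- names(object@featureToggles)[object@featureToggles]
  cat(sprintf("PhantomConfig: %d x %d, lesion r=%.0f at (%.0f, %.0f), %d spokes, seed %d\n",
              object@imageSize, object@imageSize, object@lesionRadius,
              object@lesionCenter[1], object@lesionCenter[2],
              object@nSpokes, object@seed))
  cat("  features on:", if (length(on)) paste(on, collapse = ", ") else "none", "\n")
})

setMethod("show", "PhantomSample", function(object) {
  cat(sprintf("PhantomSample %s/%s: CNV %d px, PA %d px, DH %d px; labels: %s\n",
              subjectId(object), imageId(object),
              sum(object@gtCnvMask), sum(object@gtPaMask), sum(object@gtDhMask),
              paste(names(object@labels), object@labels, sep = "=", collapse = " ")))
})
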