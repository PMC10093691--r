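# Synthetic OCTA en-face phantom generator.
#
# The phantom emulates a 6 x 6 mm^2 en-face pair with a central CNV lesion
# whose five activity features can be toggled independently:
#   * base lesion: nSpokes straight radial vessels (always drawn); with the
#     shape toggle off these sparse radial strands are the ill-defined,
#     filamentous presentation (label 0 for the shape head);
#   * shape: compact sea-fan — interior haze fill plus a dense marginal
#     fringe of short radial vessels;
#   * anastomosis_loops: circumferential arcs linking adjacent spokes at
#     mid-radius;
#   * branch: short high-curvature twigs sprouting from the spokes (the
#     only stochastic skeleton component);
#   * peripheral_arcade: a near-closed circumferential arc with four gaps
#     just inside the lesion margin, linking the vessel termini;
#   * dark_halo: multiplicative darkening of the choriocapillaris texture
#     in an annulus of width haloWidth around the lesion.
#
# All vessels are rasterized with Bresenham polylines and thickened by
# binary dilation with a disk of radius floor(vesselWidth/2), so every
# ground-truth pixel count is exact. Randomness (textures, twigs, noise) is
# split into fixed per-component sub-streams derived from the single seed,
# which makes each toggle change the image only inside that feature's
# support region.

# Band-pass (difference-of-Gaussians) noise texture, standardized.
bandpassTexture <- function(n, scale, seed) {
  z <- withSeed(seed, matrix(rnorm(n * n), n, n))
  lo <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(z)), sigma = scale)))
  hi <- t(EBImage::imageData(EBImage::gblur(EBImage::Image(t(z)), sigma = 2 * scale)))
  b <- lo - hi
  (b - mean(b)) / stats::sd(b)
}

# Skeleton pixel sets for one lesion; everything except the branch twigs is
# deterministic in the config. Returns 0-based pixel coordinate matrices.
phantomSkeleton <- function(config, branchSeed) {
  ctr <- config@lesionCenter; r <- config@lesionRadius
  nS <- config@nSpokes
  ang <- 2 * pi * (seq_len(nS) - 1) / nS
  tip <- function(a, rad) c(ctr[1] + rad * sin(a), ctr[2] + rad * cos(a))
  spokes <- do.call(rbind, lapply(ang, function(a)
    bresenhamLine(ctr[1], ctr[2], tip(a, r)[1], tip(a, r)[2])))
  arcPoints <- function(rad, a0, a1, step = 3 * pi / 180) {
    aa <- seq(a0, a1, by = step)
    if (tail(aa, 1) != a1) aa <- c(aa, a1)
    cbind(row = round(ctr[1] + rad * sin(aa)), col = round(ctr[2] + rad * cos(aa)))
  }
  fringe <- NULL
  if (config@featureToggles[["shape"]]) {
    off <- pi / nS * c(-0.66, 0.66)
    fringe <- do.call(rbind, lapply(ang, function(a) rbind(
      bresenhamLine(tip(a + off[1], 0.62 * r)[1], tip(a + off[1], 0.62 * r)[2],
                    tip(a + off[1], r)[1], tip(a + off[1], r)[2]),
      bresenhamLine(tip(a + off[2], 0.62 * r)[1], tip(a + off[2], 0.62 * r)[2],
                    tip(a + off[2], r)[1], tip(a + off[2], r)[2]))))
  }
  loops <- NULL
  if (config@featureToggles[["anastomosis_loops"]]) {
    keep <- seq(1, nS, by = 2)   # connect every other pair of spokes
    loops <- do.call(rbind, lapply(ang[keep], function(a)
      arcPoints(0.6 * r, a, a + 2 * pi / nS)))
  }
  arcade <- NULL
  if (config@featureToggles[["peripheral_arcade"]]) {
    rad <- r - max(2, config@vesselWidth)
    gap <- 12 * pi / 180
    g0 <- pi / 4 + c(0, pi / 2, pi, 3 * pi / 2)   # four gaps
    segs <- cbind(start = g0 + gap, end = g0[c(2, 3, 4, 1)] + 2 * pi * c(0, 0, 0, 1) - gap)
    arcade <- do.call(rbind, lapply(seq_len(4), function(i)
      arcPoints(rad, segs[i, 1], segs[i, 2])))
  }
  twigs <- NULL
  if (config@featureToggles[["branch"]]) {
    twigs <- withSeed(branchSeed, {
      m <- max(4L, round(1.5 * nS))
      do.call(rbind, lapply(seq_len(m), function(i) {
        a <- ang[sample.int(nS, 1)]
        t0 <- runif(1, 0.35, 0.85)
        base <- tip(a, t0 * r)
        len <- r / 6
        a1 <- a + sample(c(-1, 1), 1) * runif(1, pi / 5, pi / 2.2)
        a2 <- a1 + sample(c(-1, 1), 1) * runif(1, pi / 4, pi / 2)
        p1 <- base + len * c(sin(a1), cos(a1))
        p2 <- p1 + 0.7 * len * c(sin(a2), cos(a2))
        rasterPolyline(rbind(base, p1, p2))
      }))
    })
  }
  list(spokes = spokes, fringe = fringe, loops = loops,
       arcade = arcade, twigs = twigs)
}

#' Generate one synthetic OCTA en-face pair with ground truth
#'
#' Renders the outer-retina and choriocapillaris channels described by a
#' \linkS4class{PhantomConfig} together with exact ground-truth masks and
#' the activity labels implied by the feature toggles. Identical config and
#' seed give bit-identical output.
#'
#' @param config a \linkS4class{PhantomConfig}.
#' @param subjectIdent,imageIdent identifiers stamped on the sample.
#' @param gain multiplicative intensity gain (per-subject acquisition
#'   effect; applied before noise and clipping).
#' @return A \linkS4class{PhantomSample}.
#' @export
#' @examples
#' s <- generatePhantomPair(phantomConfig(imageSize = 96, lesionRadius = 20,
#'                                        haloWidth = 5, seed = 7))
#' s
generatePhantomPair <- function(config, subjectIdent = "s1", imageIdent = "i1",
                                gain = 1) {
  validObject(config)
  n <- config@imageSize
  seeds <- deriveSeeds(config@seed, 5L)  # bg outer, bg choroid, twigs, noise outer, noise choroid
  sk <- phantomSkeleton(config, seeds[3])
  skel <- matrix(0, n, n)
  for (part in sk) if (!is.null(part)) skel <- paintPixels(skel, part)
  vr <- floor(config@vesselWidth / 2)
  vessels <- dilateMask(skel, vr)

  shapeOn <- config@featureToggles[["shape"]]
  gtCnv <- if (shapeOn) {
    diskMask(n, config@lesionCenter[1], config@lesionCenter[2], config@lesionRadius)
  } else {
    dilateMask(skel, vr + 2L)
  }

  # outer-retina channel: background capillary texture (amplitude <= 0.25 of
  # the vessel intensity 0.9), optional interior haze, vessels, noise
  z <- bandpassTexture(n, config@backgroundTextureScale, seeds[1])
  outer <- pmin(pmax(0.1 + 0.045 * z, 0), 0.225)
  if (shapeOn) outer[gtCnv == 1] <- 0.35
  outer[vessels == 1] <- 0.9
  outer <- outer * gain
  if (config@noiseSigma > 0)
    outer <- outer + config@noiseSigma *
      withSeed(seeds[4], matrix(rnorm(n * n), n, n))
  outer <- clip01(outer)

  # choriocapillaris channel: granular texture, darkened inside the halo
  haloR <- round(config@haloWidth)
  annulus <- dilateMask(gtCnv, haloR) * (1 - gtCnv)
  gtDh <- if (config@featureToggles[["dark_halo"]]) annulus else matrix(0, n, n)
  z2 <- bandpassTexture(n, max(1.5, config@backgroundTextureScale / 2), seeds[2])
  choroid <- pmin(pmax(0.55 + 0.1 * z2, 0.3), 0.8)
  choroid[gtDh == 1] <- choroid[gtDh == 1] * config@haloContrast
  choroid <- choroid * gain
  if (config@noiseSigma > 0)
    choroid <- choroid + config@noiseSigma *
      withSeed(seeds[5], matrix(rnorm(n * n), n, n))
  choroid <- clip01(choroid)

  # ground-truth peripheral-arcade region: inter-vessel spaces in a band
  # straddling the lesion margin
  ringR <- max(2L, round(5 * n / 304))
  ring <- ringMask(gtCnv, ringR, ringR)
  gtPa <- ring * (1 - vessels)

  labels <- setNames(as.integer(config@featureToggles[OCTA_FEATURES]), OCTA_FEATURES)
  new("PhantomSample",
      pair = EnFacePair(outer, choroid, subjectIdent, imageIdent),
      gtCnvMask = gtCnv, gtPaMask = gtPa, gtDhMask = gtDh, labels = labels)
}

#' Generate a phantom dataset with subject structure
#'
#' Draws per-image activity labels i.i.d. from the requested prevalences,
#' applies per-subject effects (intensity gain and lesion-radius offset, so
#' subject-wise cross-validation differs meaningfully from image-wise), and
#' optionally writes images, masks, a label CSV and a JSON manifest to
#' \code{dir}.
#'
#' @param nSubjects number of subjects (>= 1).
#' @param imagesPerSubject images per subject (>= 1).
#' @param prevalence numeric length 5 in \code{[0,1]} (recycled if scalar),
#'   per-feature presence probability in \code{octaFeatures()} order.
#' @param baseConfig template \linkS4class{PhantomConfig}; per-image toggles,
#'   seeds, centre jitter and subject effects are filled in.
#' @param seed master seed for the whole dataset.
#' @param dir output directory; when \code{NULL} nothing is written.
#' @param keepSamples return the rendered \linkS4class{PhantomSample}s.
#' @return A list with \code{config}, \code{samples} (data.frame manifest:
#'   ids, paths when written, labels) and, when \code{keepSamples},
#'   \code{phantoms} (list of \linkS4class{PhantomSample}).
#' @export
generatePhantomDataset <- function(nSubjects, imagesPerSubject = 1L,
                                   prevalence = rep(0.5, 5),
                                   baseConfig = phantomConfig(),
                                   seed = 1L, dir = NULL, keepSamples = TRUE) {
  if (nSubjects < 1 || imagesPerSubject < 1)
    stop("nSubjects and imagesPerSubject must be >= 1")
  if (length(prevalence) == 1) prevalence <- rep(prevalence, 5)
  if (length(prevalence) != 5 || any(prevalence < 0) || any(prevalence > 1))
    stop("prevalence must be five probabilities in [0, 1]")
  prevalence <- setNames(as.numeric(prevalence), OCTA_FEATURES)
  nTot <- nSubjects * imagesPerSubject
  n <- baseConfig@imageSize

  rng <- withSeed(seed, list(
    imgSeeds = sample.int(.Machine$integer.max - 1L, nTot),
    gains = runif(nSubjects, 0.9, 1.1),
    radMult = runif(nSubjects, 0.85, 1.15),
    toggles = matrix(rbinom(nTot * 5, 1, rep(prevalence, each = nTot)), nTot, 5,
                     dimnames = list(NULL, OCTA_FEATURES)),
    jitter = matrix(runif(nTot * 2, -1, 1), nTot, 2)))

  margin0 <- baseConfig@lesionRadius * 1.15 + baseConfig@haloWidth +
    ceiling(baseConfig@vesselWidth / 2) + 2
  slack <- max(0, floor((n - 1) / 2 - margin0))
  if (!is.null(dir)) dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  rows <- vector("list", nTot); phantoms <- vector("list", nTot)
  k <- 0L
  for (s in seq_len(nSubjects)) {
    sid <- sprintf("s%03d", s)
    for (im in seq_len(imagesPerSubject)) {
      k <- k + 1L
      iid <- sprintf("%s_i%02d", sid, im)
      ctr <- (n - 1) / 2 + round(rng$jitter[k, ] * min(slack, round(0.05 * n)))
      cfg <- phantomConfig(
        imageSize = n, lesionCenter = ctr,
        lesionRadius = baseConfig@lesionRadius * rng$radMult[s],
        featureToggles = rng$toggles[k, ] == 1,
        vesselWidth = baseConfig@vesselWidth, nSpokes = baseConfig@nSpokes,
        haloWidth = baseConfig@haloWidth, haloContrast = baseConfig@haloContrast,
        noiseSigma = baseConfig@noiseSigma,
        backgroundTextureScale = baseConfig@backgroundTextureScale,
        seed = rng$imgSeeds[k])
      ph <- generatePhantomPair(cfg, sid, iid, gain = rng$gains[s])
      rec <- c(list(subject_id = sid, image_id = iid),
               as.list(activityLabels(ph)))
      if (!is.null(dir)) {
        paths <- file.path(dir, paste0(iid, c("_outer.png", "_choroid.png",
                                              "_cnv.png", "_pa.png", "_dh.png")))
        writeEnFace(enfacePair(ph), paths[1], paths[2])
        writeMask(cnvMask(ph), paths[3])
        writeMask(paMask(ph), paths[4])
        writeMask(dhMask(ph), paths[5])
        rec <- c(rec, list(outer_path = paths[1], choroid_path = paths[2],
                           cnv_mask_path = paths[3], pa_mask_path = paths[4],
                           dh_mask_path = paths[5]))
      }
      rows[[k]] <- as.data.frame(rec)
      if (keepSamples) phantoms[[k]] <- ph
    }
  }
  samples <- do.call(rbind, rows)
  manifest <- list(config = configAsList(baseConfig), seed = seed,
                   prevalence = as.list(prevalence), samples = samples)
  if (!is.null(dir)) {
    writeLabels(samples, file.path(dir, "labels.csv"))
    writeManifest(manifest, file.path(dir, "manifest.json"))
    # writeManifest relativizes paths in place; re-read absolute for caller
    manifest$samples <- samples
  }
  if (keepSamples) manifest$phantoms <- phantoms
  manifest
}

configAsList <- function(config) {
  list(image_size = config@imageSize,
       lesion_center = config@lesionCenter,
       lesion_radius = config@lesionRadius,
       feature_toggles = as.list(config@featureToggles),
       vessel_width = config@vesselWidth, n_spokes = config@nSpokes,
       halo_width = config@haloWidth, halo_contrast = config@haloContrast,
       noise_sigma = config@noiseSigma,
       background_texture_scale = config@backgroundTextureScale,
       seed = config@seed)
}
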