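# On-disk conventions shared by every module: 8-bit grayscale PNG (default)
# or TIFF for images, PNG {0,255} for masks, CSV for labels, JSON manifests.

readGray <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop("unsupported image format: .", ext))
  if (length(dim(img)) == 3) {
    # accidental RGB(A): unweighted mean of the colour channels
    img <- apply(img[, , seq_len(min(3, dim(img)[3])), drop = FALSE], c(1, 2), mean)
  }
  if (length(dim(img)) != 2) stop("image is not 2-D grayscale: ", path)
  clip01(img)
}

writeGray <- function(grid, path) {
  storage.mode(grid) <- "double"
  assertImage(grid)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    png = png::writePNG(grid, path),
    tif = ,
    tiff = tiff::writeTIFF(grid, path, bits.per.sample = 8L),
    stop("unsupported image format: .", ext))
  invisible(path)
}

#' Read a co-registered en-face pair from disk
#'
#' Loads the outer-retina and choriocapillaris channels, converting
#' accidental RGB inputs to grayscale by unweighted channel mean and
#' rescaling integer pixel depths to \code{[0,1]}.
#'
#' @param pathOuter,pathChoroid PNG or TIFF files.
#' @param subjectId,imageId identifiers attached to the pair.
#' @return An \linkS4class{EnFacePair}.
#' @export
readEnFace <- function(pathOuter, pathChoroid, subjectId = "s1", imageId = "i1") {
  o <- readGray(pathOuter)
  ch <- readGray(pathChoroid)
  if (!identical(dim(o), dim(ch)))
    stop("channel shape mismatch: ", paste(dim(o), collapse = "x"), " vs ",
         paste(dim(ch), collapse = "x"))
  EnFacePair(o, ch, subjectId, imageId)
}

#' Write an en-face pair to disk
#'
#' @param pair an \linkS4class{EnFacePair}.
#' @param pathOuter,pathChoroid output PNG/TIFF paths.
#' @return The two paths, invisibly.
#' @export
writeEnFace <- function(pair, pathOuter, pathChoroid) {
  writeGray(outerRetina(pair), pathOuter)
  writeGray(choriocapillaris(pair), pathChoroid)
  invisible(c(pathOuter, pathChoroid))
}

#' Read / write binary masks
#'
#' Masks are stored as PNG (or TIFF) with values \{0, 255\}; on reading,
#' pixels are thresholded at 128 so that antialiased or rescaled inputs
#' still load. The write-then-read round trip is the identity.
#'
#' @param path image file.
#' @return \code{readMask}: a 0/1 numeric matrix.
#' @export
readMask <- function(path) {
  g <- readGray(path)
  (g >= 128 / 255) * 1
}

#' @rdname readMask
#' @param mask a 0/1 numeric matrix.
#' @export
writeMask <- function(mask, path) {
  assertMask(mask)
  writeGray(mask, path)
}

#' Read / write activity-label tables
#'
#' The CSV schema is fixed:
#' \code{subject_id,image_id,branch,shape,anastomosis_loops,peripheral_arcade,dark_halo}
#' with each criterion coded 0/1. Row order is preserved.
#'
#' @param path CSV file.
#' @return \code{readLabels}: a data.frame with the columns above.
#' @export
readLabels <- function(path) {
  df <- read.csv(path, colClasses = c(subject_id = "character",
                                      image_id = "character"))
  need <- c("subject_id", "image_id", OCTA_FEATURES)
  missing <- setdiff(need, names(df))
  if (length(missing)) stop("label file misses column(s): ",
                            paste(missing, collapse = ", "))
  df <- df[, need, drop = FALSE]
  for (f in OCTA_FEATURES) {
    if (nrow(df) && !all(df[[f]] %in% c(0L, 1L)))
      stop("label column '", f, "' has values outside {0, 1}")
    df[[f]] <- as.integer(df[[f]])
  }
  df
}

#' @rdname readLabels
#' @param labels data.frame in the schema above.
#' @export
writeLabels <- function(labels, path) {
  need <- c("subject_id", "image_id", OCTA_FEATURES)
  missing <- setdiff(need, names(labels))
  if (length(missing)) stop("label table misses column(s): ",
                            paste(missing, collapse = ", "))
  write.csv(labels[, need, drop = FALSE], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' The manifest is a JSON file listing the generating configuration and one
#' record per sample (\code{subject_id}, \code{image_id}, image and mask
#' paths, labels). Re-loading a manifest reconstructs the dataset: paths are
#' stored relative to the manifest's directory.
#'
#' @param path JSON file.
#' @return \code{readManifest}: a list with elements \code{config} and
#'   \code{samples} (a data.frame).
#' @export
readManifest <- function(path) {
  m <- jsonlite::read_json(path, simplifyVector = TRUE)
  m$samples <- as.data.frame(m$samples)
  base <- dirname(normalizePath(path))
  for (col in intersect(c("outer_path", "choroid_path", "cnv_mask_path",
                          "pa_mask_path", "dh_mask_path"), names(m$samples))) {
    rel <- !startsWith(m$samples[[col]], "/")
    m$samples[[col]][rel] <- file.path(base, m$samples[[col]][rel])
  }
  m
}

#' @rdname readManifest
#' @param manifest list with \code{config} and \code{samples}.
#' @export
writeManifest <- function(manifest, path) {
  base <- normalizePath(dirname(path))
  for (col in intersect(c("outer_path", "choroid_path", "cnv_mask_path",
                          "pa_mask_path", "dh_mask_path"),
                        names(manifest$samples)))
    manifest$samples[[col]] <- sub(paste0("^", base, "/?"), "",
                                   manifest$samples[[col]])
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Load the samples listed in a manifest
#'
#' @param manifest result of \code{\link{readManifest}} (or the in-memory
#'   manifest returned by \code{\link{generatePhantomDataset}}).
#' @return A list of \linkS4class{PhantomSample} objects (ground-truth PA/DH
#'   masks are included when their paths are present in the manifest).
#' @export
loadManifestSamples <- function(manifest) {
  df <- manifest$samples
  lapply(seq_len(nrow(df)), function(i) {
    pair <- readEnFace(df$outer_path[i], df$choroid_path[i],
                       df$subject_id[i], df$image_id[i])
    lab <- setNames(as.integer(df[i, OCTA_FEATURES]), OCTA_FEATURES)
    d <- dim(outerRetina(pair))
    pa <- if ("pa_mask_path" %in% names(df)) readMask(df$pa_mask_path[i])
          else matrix(0, d[1], d[2])
    dh <- if ("dh_mask_path" %in% names(df)) readMask(df$dh_mask_path[i])
          else matrix(0, d[1], d[2])
    new("PhantomSample", pair = pair, gtCnvMask = readMask(df$cnv_mask_path[i]),
        gtPaMask = pa, gtDhMask = dh, labels = lab)
  })
}
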