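# Integer rasterization used by the phantom generator. Lines are drawn with
# Bresenham's algorithm (no anti-aliasing) so the set of foreground pixels —
# and hence every ground-truth pixel count — is exactly reproducible.

#' Rasterize a line segment (Bresenham)
#'
#' @param r0,c0,r1,c1 0-based integer endpoints (row, col).
#' @return Integer matrix with columns \code{row}, \code{col}, one pixel per
#'   line step, endpoints included.
#' @export
#' @examples
#' bresenhamLine(0, 0, 3, 5)
bresenhamLine <- function(r0, c0, r1, c1) {
  r0 <- as.integer(round(r0)); c0 <- as.integer(round(c0))
  r1 <- as.integer(round(r1)); c1 <- as.integer(round(c1))
  dr <- abs(r1 - r0); dc <- abs(c1 - c0)
  sr <- if (r0 < r1) 1L else -1L
  sc <- if (c0 < c1) 1L else -1L
  err <- dc - dr
  n <- dr + dc + 1L
  rows <- integer(n); cols <- integer(n)
  r <- r0; c <- c0; i <- 0L
  repeat {
    i <- i + 1L; rows[i] <- r; cols[i] <- c
    if (r == r1 && c == c1) break
    e2 <- 2L * err
    if (e2 > -dr) { err <- err - dr; c <- c + sc }
    if (e2 < dc) { err <- err + dc; r <- r + sr }
  }
  cbind(row = rows[seq_len(i)], col = cols[seq_len(i)])
}

# Rasterize a polyline through the given vertices; duplicate pixels at the
# joints are removed, preserving first-visit order.
rasterPolyline <- function(verts) {
  px <- do.call(rbind, lapply(seq_len(nrow(verts) - 1), function(i) {
    bresenhamLine(verts[i, 1], verts[i, 2], verts[i + 1, 1], verts[i + 1, 2])
  }))
  px[!duplicated(px), , drop = FALSE]
}

# Set pixels (0-based row/col pairs) in a matrix, discarding out-of-bounds.
paintPixels <- function(grid, px, value = 1) {
  keep <- px[, 1] >= 0 & px[, 1] < nrow(grid) & px[, 2] >= 0 & px[, 2] < ncol(grid)
  grid[px[keep, , drop = FALSE] + 1L] <- value
  grid
}

#' Disk structuring element
#'
#' Pixels at Euclidean distance \code{<= r + 0.5} from the centre of a
#' \code{(2r+1) x (2r+1)} kernel. For \code{r = 1} this is the full 3 x 3
#' square (the 8-neighbourhood); for larger radii it approximates a disk.
#'
#' @param r integer radius >= 0.
#' @return 0/1 matrix of size \code{2r+1}.
#' @export
#' @examples
#' diskElement(1)
diskElement <- function(r) {
  r <- as.integer(r)
  if (r < 0) stop("radius must be >= 0")
  d <- seq(-r, r)
  outer(d, d, function(i, j) (i^2 + j^2 <= (r + 0.5)^2) * 1)
}

#' Binary dilation / erosion with a disk element
#'
#' Thin wrappers over \code{EBImage} morphology using
#' \code{\link{diskElement}} kernels, on row-major 0/1 matrices.
#'
#' @param mask 0/1 matrix.
#' @param r integer radius; \code{r = 0} returns the mask unchanged.
#' @return 0/1 matrix.
#' @export
dilateMask <- function(mask, r) {
  assertMask(mask)
  if (r == 0) return(mask)
  t(EBImage::imageData(EBImage::dilate(EBImage::Image(t(mask)), diskElement(r)))) * 1
}

#' @rdname dilateMask
#' @export
erodeMask <- function(mask, r) {
  assertMask(mask)
  if (r == 0) return(mask)
  t(EBImage::imageData(EBImage::erode(EBImage::Image(t(mask)), diskElement(r)))) * 1
}

# Filled disk mask: pixels with (row - cr)^2 + (col - cc)^2 <= rad^2.
diskMask <- function(n, cr, cc, rad) {
  rr <- matrix(seq_len(n) - 1, n, n)
  cc2 <- matrix(seq_len(n) - 1, n, n, byrow = TRUE)
  ((rr - cr)^2 + (cc2 - cc)^2 <= rad^2) * 1
}
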