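# Shape descriptors on binary masks: Crofton perimeter, feret diameter,
# moment-based aspect ratio. All operate on logical matrices in pixel units;
# callers convert with their pixel size.

#' Crofton perimeter of a binary mask
#'
#' Cauchy-Crofton estimate from boundary-intercept counts along four line
#' directions (0, 45, 90, 135 degrees): `P = pi/4 * sum_theta W_theta`
#' where `W_theta` is the number of chords times the line spacing. Unlike
#' naive pixel-edge counting (which inflates the perimeter of a disk by
#' 4/pi and biases its circularity to about 0.62) this estimator is
#' asymptotically exact for smooth convex shapes.
#'
#' @param mask Logical (or 0/1) matrix.
#' @return Perimeter in pixel units.
#' @examples
#' m <- outer(1:101, 1:101, function(i, j) (i - 51)^2 + (j - 51)^2 <= 40^2)
#' crofton_perimeter(m) / (2 * pi * 40)  # ~ 1
#' @export
crofton_perimeter <- function(mask) {
  b <- matrix(0L, nrow(mask) + 2L, ncol(mask) + 2L)
  b[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- as.integer(mask != 0)
  nr <- nrow(b); nc <- ncol(b)
  c0   <- sum(b[, -1L] != b[, -nc])                       # along rows
  c90  <- sum(b[-1L, ] != b[-nr, ])                       # along columns
  c45  <- sum(b[-1L, -1L] != b[-nr, -nc])                 # main diagonals
  c135 <- sum(b[-1L, -nc] != b[-nr, -1L])                 # anti-diagonals
  W <- c(c0 / 2, c90 / 2, (c45 / 2) / sqrt(2), (c135 / 2) / sqrt(2))
  pi * sum(W) / 4
}

#' Circularity from area and perimeter
#'
#' `4 * pi * area / perimeter^2`: 1 for a circle, `pi/4` for a square,
#' smaller for irregular or elongated shapes.
#'
#' @param area,perimeter Positive scalars in consistent units.
#' @return Dimensionless circularity.
#' @export
circularity <- function(area, perimeter) {
  stopifnot(area > 0, perimeter > 0)
  4 * pi * area / perimeter^2
}

# Convex-hull points (pixel centres) of a mask; Nx2 matrix (x = col, y = row).
mask_hull <- function(mask) {
  ij <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(ij)) stop("empty mask")
  pts <- cbind(x = ij[, 2L], y = ij[, 1L])
  if (nrow(pts) > 2L) pts[grDevices::chull(pts), , drop = FALSE] else pts
}

#' Maximum feret (caliper) diameter of a mask
#'
#' Largest pairwise distance between pixel centres, computed on the convex
#' hull, together with the orientation of that maximal chord.
#'
#' @param mask Logical matrix.
#' @return List with `length` (pixels) and `angle` (degrees in `[0, 180)`,
#'   measured from the +x axis toward +y).
#' @export
max_feret <- function(mask) {
  h <- mask_hull(mask)
  n <- nrow(h)
  if (n == 1L) return(list(length = 1, angle = 0))
  dx <- outer(h[, 1L], h[, 1L], "-")
  dy <- outer(h[, 2L], h[, 2L], "-")
  d2 <- dx^2 + dy^2
  i <- which.max(d2)
  ang <- (atan2(dy[i], dx[i]) * 180 / pi) %% 180
  list(length = sqrt(d2[i]), angle = ang)
}

# Aspect ratio (major/minor) of the inertia-equivalent ellipse. The 1/12
# term is the variance of a unit pixel, which keeps one-pixel-thin shapes
# finite.
moment_aspect_ratio <- function(mask) {
  ij <- which(mask != 0, arr.ind = TRUE)
  if (!nrow(ij)) stop("empty mask")
  x <- ij[, 2L]; y <- ij[, 1L]
  cxx <- stats::var(x) * (length(x) - 1) / length(x) + 1 / 12
  cyy <- stats::var(y) * (length(y) - 1) / length(y) + 1 / 12
  cxy <- if (length(x) > 1)
    stats::cov(x, y) * (length(x) - 1) / length(x) else 0
  tr <- cxx + cyy; det <- cxx * cyy - cxy^2
  l1 <- tr / 2 + sqrt(max(tr^2 / 4 - det, 0))
  l2 <- tr / 2 - sqrt(max(tr^2 / 4 - det, 0))
  sqrt(l1 / max(l2, 1e-12))
}

# Centroid of a labelled region in pixel coordinates (x = col, y = row).
mask_centroid <- function(mask) {
  ij <- which(mask != 0, arr.ind = TRUE)
  c(x = mean(ij[, 2L]), y = mean(ij[, 1L]))
}
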