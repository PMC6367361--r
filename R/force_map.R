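# Force maps: grids of force-distance curves, per-pixel Hertz fitting into
# stiffness / setpoint-height images, and per-cell mechanics extraction.

#' Force map: a spatial grid of force-distance curves
#'
#' @param curves List of [force_curve()] objects in row-major order
#'   (row 1 left-to-right, then row 2, ...).
#' @param shape Integer `(rows, cols)`; `prod(shape)` must equal
#'   `length(curves)`.
#' @param extent_um Physical edge lengths `(height, width)` in um (a scalar
#'   is recycled).
#' @return An object of class `force_map`.
#' @export
force_map <- function(curves, shape = c(64, 64), extent_um = 100) {
  shape <- as.integer(shape)
  if (length(curves) == 0L) stop("a force map needs at least one curve")
  if (prod(shape) != length(curves))
    stop("length(curves) must equal prod(shape)")
  if (!all(vapply(curves, inherits, logical(1), "force_curve")))
    stop("all elements must be force_curve objects")
  k <- vapply(curves, `[[`, numeric(1), "spring_constant")
  sp <- vapply(curves, `[[`, numeric(1), "setpoint")
  if (stats::sd(k) > 0 || stats::sd(sp) > 0)
    stop("all curves of a map must share acquisition settings")
  extent_um <- rep_len(extent_um, 2L)
  structure(list(curves = curves, shape = shape, extent_um = extent_um),
            class = "force_map")
}

#' @export
print.force_map <- function(x, ...) {
  cat(sprintf("Force map: %d x %d curves over %g x %g um\n",
              x$shape[1L], x$shape[2L], x$extent_um[1L], x$extent_um[2L]))
  invisible(x)
}

#' Fit every curve of a force map into stiffness and height images
#'
#' Runs [fit_hertz()] on each pixel's extend segment. The setpoint-height
#' image records the piezo z of the last extend sample (the position at
#' which the setpoint force was reached). Pixels whose fit does not
#' converge, or whose curve shows no contact, are flagged in the quality
#' image and carry `NA` modulus; they are excluded from downstream
#' statistics. If more than half of the pixels fail, a warning reports the
#' count.
#'
#' @param fmap A [force_map()].
#' @param tip A [tip_model()].
#' @param options Fit options passed to [fit_hertz()].
#' @return An object of class `stiffness_map` with matrices `E_image` (Pa),
#'   `setpoint_height_image` (um), `quality_image` (logical), and
#'   `pixel_size` (um).
#' @export
build_stiffness_map <- function(fmap, tip = tip_model(), options = list()) {
  stopifnot(inherits(fmap, "force_map"))
  nr <- fmap$shape[1L]; nc <- fmap$shape[2L]
  E <- matrix(NA_real_, nr, nc)
  h <- matrix(NA_real_, nr, nc)
  q <- matrix(FALSE, nr, nc)
  for (i in seq_along(fmap$curves)) {
    cv <- fmap$curves[[i]]
    r <- (i - 1L) %/% nc + 1L
    c <- (i - 1L) %% nc + 1L
    h[r, c] <- max(cv$z_extend)
    ft <- tryCatch(fit_hertz(cv, tip, options), error = function(e) NULL)
    if (!is.null(ft) && ft$converged && is.finite(ft$E) && ft$E > 0) {
      E[r, c] <- ft$E
      q[r, c] <- TRUE
    }
  }
  nbad <- sum(!q)
  if (nbad > length(q) / 2)
    warning(sprintf("%d of %d pixels failed to fit", nbad, length(q)))
  structure(list(E_image = E, setpoint_height_image = h, quality_image = q,
                 pixel_size = fmap$extent_um[2L] / nc),
            class = "stiffness_map")
}

#' @export
print.stiffness_map <- function(x, ...) {
  cat(sprintf("Stiffness map %d x %d (pixel %g um): median E = %.3g Pa, %d invalid pixel(s)\n",
              nrow(x$E_image), ncol(x$E_image), x$pixel_size,
              stats::median(x$E_image, na.rm = TRUE), sum(!x$quality_image)))
  invisible(x)
}

#' @export
plot.stiffness_map <- function(x, which = c("E", "height"), ...) {
  which <- match.arg(which)
  img <- if (which == "E") x$E_image else map_topography(x)
  graphics::image(t(img[nrow(img):1, ]), axes = FALSE, useRaster = TRUE,
                  main = if (which == "E") "Young's modulus (Pa)"
                         else "setpoint height topography (um)", ...)
  invisible(x)
}

#' Setpoint-height topography of a stiffness map
#'
#' The stored setpoint-height image is the piezo extension at which the
#' setpoint force was reached; tall cells make contact earlier, so their
#' setpoint z is *smaller*. This helper converts to a topography (um above
#' the lowest point) in which cells are elevated, the form expected by
#' [segment_height_map()].
#'
#' @param smap A `stiffness_map`.
#' @return Numeric matrix of relative heights (um).
#' @export
map_topography <- function(smap) {
  h <- smap$setpoint_height_image
  max(h, na.rm = TRUE) - h
}

#' Per-cell mechanics from a stiffness map and segmentation
#'
#' For every label, the mean Young's modulus and mean setpoint height over
#' the label's *valid* (converged) pixels, plus the footprint area. Labels
#' without any valid pixel are flagged (`valid = FALSE`) so that downstream
#' statistics can drop them.
#'
#' @param smap A `stiffness_map`.
#' @param mask A `seg_mask` (or integer label matrix) of the same shape.
#' @return A data frame with columns `label`, `mean_E` (Pa),
#'   `mean_setpoint_height` (um), `area` (um^2), `n_pixels`,
#'   `n_valid_pixels`, `valid`.
#' @export
extract_cell_mechanics <- function(smap, mask) {
  lab <- unclass(mask)
  stopifnot(all(dim(lab) == dim(smap$E_image)))
  labs <- sort(unique(lab[lab > 0]))
  px_area <- smap$pixel_size^2
  out <- lapply(labs, function(l) {
    sel <- lab == l
    ok <- sel & smap$quality_image & is.finite(smap$E_image)
    data.frame(label = l,
               mean_E = if (any(ok)) mean(smap$E_image[ok]) else NA_real_,
               mean_setpoint_height =
                 if (any(ok)) mean(smap$setpoint_height_image[ok]) else NA_real_,
               area = sum(sel) * px_area,
               n_pixels = sum(sel), n_valid_pixels = sum(ok),
               valid = any(ok))
  })
  do.call(rbind, out)
}

#' Pearson correlation between paired image profiles
#'
#' Correlation of two pixel profiles (e.g. setpoint height vs Young's
#' modulus sampled along the same line across a cell).
#'
#' @param height_profile,E_profile Equal-length numeric vectors (>= 3) with
#'   nonzero variance.
#' @return Pearson correlation coefficient.
#' @export
profile_correlation <- function(height_profile, E_profile) {
  stopifnot(length(height_profile) == length(E_profile),
            length(height_profile) >= 3L)
  if (stats::sd(height_profile) == 0 || stats::sd(E_profile) == 0)
    stop("undefined correlation: a profile has zero variance")
  stats::cor(height_profile, E_profile)
}
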