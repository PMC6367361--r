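# Fluorescence morphometrics: periphery bands, region intensities, cell
# shape descriptors, stress-fibre metrics and circular orientation
# statistics.

#' Fluorescence cell record
#'
#' Bundles a (manually drawn) single-cell mask with its fluorescence
#' channels.
#'
#' @param mask Logical matrix: the cell footprint (single connected label).
#' @param channels Named list of numeric matrices (e.g. `actin`, `tubulin`),
#'   all the same shape as the mask.
#' @param pixel_size Pixel edge in um.
#' @return An object of class `fluor_cell`.
#' @export
fluor_cell <- function(mask, channels, pixel_size) {
  mask <- mask != 0
  stopifnot(is.matrix(mask), any(mask), pixel_size > 0)
  for (ch in channels)
    if (!all(dim(ch) == dim(mask))) stop("channel shape must match mask")
  structure(list(mask = mask, channels = channels, pixel_size = pixel_size),
            class = "fluor_cell")
}

#' Peripheral band of a cell mask
#'
#' The cell footprint minus its erosion by a disc of radius `width`; i.e. a
#' band of the requested thickness lining the cell border, the region that
#' holds most of the peripheral actin cytoskeleton. If the erosion empties
#' the mask (cell smaller than the band) the whole cell is returned.
#'
#' @param mask Logical matrix (cell footprint).
#' @param width Band thickness in um (default 4).
#' @param pixel_size Pixel edge in um.
#' @return Logical matrix: the band. `width = 0` gives an empty band.
#' @export
periphery_band <- function(mask, width = 4, pixel_size = 1) {
  mask <- mask != 0
  stopifnot(width >= 0, pixel_size > 0)
  if (width == 0) return(mask & FALSE)
  r <- round(width / pixel_size)
  if (r < 1) return(mask & FALSE)
  brush <- EBImage::makeBrush(2L * r + 1L, shape = "disc")
  er <- as.matrix(EBImage::erode(EBImage::Image(mask * 1), brush)) > 0.5
  if (!any(er)) return(mask)
  mask & !er
}

#' Intensity statistics over a region
#'
#' @param image Numeric matrix (arbitrary intensity units).
#' @param region Logical matrix, same shape, non-empty.
#' @return List with `integrated_intensity` (sum over region) and
#'   `median_intensity` (even counts average the central pair).
#' @export
region_intensity <- function(image, region) {
  region <- region != 0
  stopifnot(all(dim(image) == dim(region)))
  if (!any(region)) stop("empty region")
  v <- image[region]
  list(integrated_intensity = sum(v), median_intensity = stats::median(v))
}

#' Cell shape descriptors
#'
#' Area, maximum feret (caliper) diameter, roundness, aspect ratio and
#' circularity of a cell footprint. Definitions follow common image-analysis
#' conventions: `roundness = 4 * area / (pi * max_feret^2)`;
#' `aspect_ratio` = major/minor axis ratio of the inertia-equivalent
#' ellipse; `circularity = 4 * pi * area / perimeter^2` with a Crofton
#' perimeter.
#'
#' @param mask Logical matrix, non-empty.
#' @param pixel_size Pixel edge in um.
#' @return List of class `cell_shape`: `area` (um^2), `max_feret` (um),
#'   `feret_angle` (deg), `roundness`, `aspect_ratio`, `circularity`.
#' @export
cell_shape <- function(mask, pixel_size = 1) {
  mask <- mask != 0
  if (!any(mask)) stop("empty mask")
  area <- sum(mask) * pixel_size^2
  fer <- max_feret(mask)
  fer_um <- fer$length * pixel_size
  per <- crofton_perimeter(mask) * pixel_size
  structure(list(area = area, max_feret = fer_um, feret_angle = fer$angle,
                 roundness = 4 * area / (pi * fer_um^2),
                 aspect_ratio = moment_aspect_ratio(mask),
                 circularity = circularity(area, per)),
            class = "cell_shape")
}

#' @export
print.cell_shape <- function(x, ...) {
  cat(sprintf(
    "Cell shape: area %.4g um^2, max feret %.4g um, roundness %.3f, AR %.3f, circularity %.3f\n",
    x$area, x$max_feret, x$roundness, x$aspect_ratio, x$circularity))
  invisible(x)
}

#' Per-fibre geometry and intensity
#'
#' For each (manually segmented) stress-fibre mask: length = maximum feret
#' diameter, feret angle = orientation of that maximal chord (degrees in
#' `[0, 180)`), plus integrated and mean intensity of the fibre pixels in
#' the supplied channel.
#'
#' @param fibres List of logical matrices (one mask per fibre, non-empty).
#' @param channel Numeric matrix, same shape as the masks.
#' @param pixel_size Pixel edge in um.
#' @return Data frame with one row per fibre: `fibre`, `length` (um),
#'   `feret_angle` (deg), `integrated_intensity`, `mean_intensity`. The
#'   number of rows is the per-cell fibre count.
#' @export
fiber_metrics <- function(fibres, channel, pixel_size = 1) {
  rows <- lapply(seq_along(fibres), function(i) {
    m <- fibres[[i]] != 0
    if (!any(m)) stop(sprintf("fibre mask %d is empty", i))
    fer <- max_feret(m)
    v <- channel[m]
    data.frame(fibre = i, length = fer$length * pixel_size,
               feret_angle = fer$angle,
               integrated_intensity = sum(v), mean_intensity = mean(v))
  })
  do.call(rbind, rows)
}

#' Circular standard deviation of fibre orientations
#'
#' `sqrt(-2 * log(Rbar))` where `Rbar` is the mean resultant length of unit
#' vectors at the given angles (converted to radians). In `"raw"` mode the
#' angles are used as-is (period 360 degrees). In `"axial"` mode they are
#' doubled first and the result halved - the correct treatment for
#' orientations with period 180 degrees, where e.g. 10 and 170 degrees are
#' nearly parallel fibres.
#'
#' @param angles Numeric vector of angles in degrees, length >= 2.
#' @param mode `"raw"` (default) or `"axial"`.
#' @return Circular standard deviation in radians (of the doubled-angle
#'   distribution halved, in axial mode).
#' @examples
#' angle_dispersion(c(0, 90))            # sqrt(-2*log(sqrt(2)/2)) ~ 0.8326
#' angle_dispersion(c(10, 170), "axial") # small: near-parallel orientations
#' @export
angle_dispersion <- function(angles, mode = c("raw", "axial")) {
  mode <- match.arg(mode)
  if (length(angles) < 2L) stop("need at least 2 angles")
  mult <- if (mode == "axial") 2 else 1
  th <- angles * mult * pi / 180
  R <- sqrt(mean(cos(th))^2 + mean(sin(th))^2)
  R <- min(R, 1)
  sqrt(-2 * log(max(R, .Machine$double.xmin))) / mult
}
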