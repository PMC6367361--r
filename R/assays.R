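# Colony-forming, impedance (cell index) and migration assay quantification.

# ---- rigid image resampling -------------------------------------------------

#' Rigid transform of an image (rotation about centre + translation)
#'
#' Bilinear resampling of a matrix or H x W x 3 RGB array under a rigid
#' transform: rotate by `angle_deg` (counter-clockwise, about the image
#' centre), then shift by `shift` pixels `(rows, cols)`. Out-of-frame
#' samples take `fill`.
#'
#' @param img Numeric matrix or 3-channel array, values in any range.
#' @param angle_deg Rotation in degrees.
#' @param shift Length-2 numeric `(drow, dcol)`.
#' @param fill Fill value for pixels mapped from outside the source.
#' @return Transformed image of the same shape.
#' @export
transform_image <- function(img, angle_deg = 0, shift = c(0, 0), fill = 1) {
  if (length(dim(img)) == 3L) {
    out <- img
    for (ch in seq_len(dim(img)[3L]))
      out[, , ch] <- transform_image(img[, , ch], angle_deg, shift, fill)
    return(out)
  }
  nr <- nrow(img); nc <- ncol(img)
  cr <- (nr + 1) / 2; cc <- (nc + 1) / 2
  th <- angle_deg * pi / 180
  # inverse map: output pixel -> source coordinate
  r_out <- matrix(rep(seq_len(nr), nc), nr, nc) - cr - shift[1L]
  c_out <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cc - shift[2L]
  r_src <- cos(th) * r_out + sin(th) * c_out + cr
  c_src <- -sin(th) * r_out + cos(th) * c_out + cc
  r0 <- floor(r_src); c0 <- floor(c_src)
  fr <- r_src - r0; fc <- c_src - c0
  getpx <- function(r, c) {
    ok <- r >= 1 & r <= nr & c >= 1 & c <= nc
    v <- matrix(fill, nr, nc)
    v[ok] <- img[cbind(r[ok], c[ok])]
    v
  }
  getpx(r0, c0) * (1 - fr) * (1 - fc) + getpx(r0 + 1, c0) * fr * (1 - fc) +
    getpx(r0, c0 + 1) * (1 - fr) * fc + getpx(r0 + 1, c0 + 1) * fr * fc
}

# Normalised cross-correlation via FFT; returns best integer shift of b
# relative to a and the correlation coefficient there.
fft_shift_correlation <- function(a, b) {
  a <- a - mean(a); b <- b - mean(b)
  den <- sqrt(sum(a^2) * sum(b^2))
  if (den == 0) return(list(shift = c(0, 0), cor = 0))
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) /
    length(a)
  i <- which.max(cc)
  r <- (i - 1) %% nrow(a); c <- (i - 1) %/% nrow(a)
  if (r > nrow(a) / 2) r <- r - nrow(a)
  if (c > ncol(a) / 2) c <- c - ncol(a)
  list(shift = c(r, c), cor = max(cc) / den)
}

#' Register a plate photograph to the reference image
#'
#' Finds the rigid transform (rotation about the image centre plus integer
#' translation) that maximises the normalised intensity correlation between
#' the grayscale versions of `img` and `ref`, by an exhaustive rotation scan
#' (coarse then refined to 0.1 degree) with FFT cross-correlation for the
#' translation at each angle. The reference's manually labelled region of
#' interest, if given as a polygon, is mapped onto `img`.
#'
#' @param img,ref Grayscale matrices or H x W x 3 RGB arrays of equal shape.
#' @param roi Optional reference ROI polygon, an N x 2 matrix of `(row, col)`
#'   vertices.
#' @param rotation_range Half-width of the rotation scan in degrees
#'   (default 10).
#' @param coarse_step Coarse scan step in degrees (default 0.5).
#' @param min_correlation Registration-failure threshold on the correlation
#'   peak (default 0.2).
#' @return List with `angle` (degrees: rotate `ref` by this to match `img`),
#'   `shift` (pixels, rows/cols), `correlation`, and `roi_mask` (logical
#'   matrix, only if `roi` supplied).
#' @export
register_to_reference <- function(img, ref, roi = NULL, rotation_range = 10,
                                  coarse_step = 0.5, min_correlation = 0.2) {
  g <- function(x) if (length(dim(x)) == 3L)
    (x[, , 1L] + x[, , 2L] + x[, , 3L]) / 3 else x
  gi <- g(img); gr <- g(ref)
  stopifnot(all(dim(gi) == dim(gr)))
  scan <- function(angles) {
    best <- list(cor = -Inf)
    for (a in angles) {
      rot <- transform_image(gr, a, c(0, 0), fill = mean(gr))
      m <- fft_shift_correlation(gi, rot)
      if (m$cor > best$cor) best <- list(cor = m$cor, angle = a, shift = m$shift)
    }
    best
  }
  best <- scan(seq(-rotation_range, rotation_range, by = coarse_step))
  best <- scan(seq(best$angle - coarse_step, best$angle + coarse_step, by = 0.1))
  if (best$cor < min_correlation)
    stop(sprintf("registration failure: correlation peak %.3f below %.2f",
                 best$cor, min_correlation))
  out <- list(angle = best$angle, shift = best$shift, correlation = best$cor)
  if (!is.null(roi)) {
    rm0 <- polygon_mask(roi, dim(gi))
    rot <- transform_image(rm0 * 1, best$angle, best$shift, fill = 0)
    out$roi_mask <- rot > 0.5
  }
  out
}

#' Rasterise a polygon into a logical mask
#'
#' Even-odd rule point-in-polygon test on pixel centres.
#'
#' @param poly N x 2 matrix of `(row, col)` vertices.
#' @param dim Target `(rows, cols)`.
#' @return Logical matrix.
#' @export
polygon_mask <- function(poly, dim) {
  nr <- dim[1L]; nc <- dim[2L]
  py <- poly[, 1L]; px <- poly[, 2L]
  n <- length(px)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  inside <- matrix(FALSE, nr, nc)
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((py[i] > ys) != (py[j] > ys)) &
      (xs < (px[j] - px[i]) * (ys - py[i]) / (py[j] - py[i]) + px[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}

#' Fraction of a region covered by stained colonies
#'
#' Converts the RGB plate photograph to CIE Lab (sRGB input, D65 white
#' point) and segments colony pixels as those whose b channel falls below
#' the threshold - trypan-blue-stained colonies sit far on the blue side of
#' the b axis while the plate background is near-neutral. The covered
#' fraction is colony pixels / ROI pixels.
#'
#' @param img H x W x 3 RGB array with values in `[0, 1]`.
#' @param roi Logical matrix (region of interest), non-empty.
#' @param threshold Fixed Lab b-channel threshold; default -32, the b value
#'   of a half-coverage blend on the package's synthetic plates (so a pixel
#'   counts as colony when it is majority-stained); override for your
#'   stain/camera.
#' @return List of class `colony_result`: `covered_fraction` in `[0, 1]`,
#'   `threshold`, `n_roi`.
#' @export
colony_covered_fraction <- function(img, roi, threshold = -32) {
  stopifnot(length(dim(img)) == 3L, dim(img)[3L] == 3L)
  roi <- roi != 0
  if (!any(roi)) stop("empty ROI")
  rgb <- cbind(as.vector(img[, , 1L])[roi], as.vector(img[, , 2L])[roi],
               as.vector(img[, , 3L])[roi])
  lab <- grDevices::convertColor(rgb, from = "sRGB", to = "Lab")
  structure(list(covered_fraction = mean(lab[, 3L] < threshold),
                 threshold = threshold, n_roi = sum(roi)),
            class = "colony_result")
}

#' @export
print.colony_result <- function(x, ...) {
  cat(sprintf("Colony coverage: %.1f%% of %d ROI pixels (Lab b < %g)\n",
              100 * x$covered_fraction, x$n_roi, x$threshold))
  invisible(x)
}

# ---- impedance --------------------------------------------------------------

#' Impedance time series of one well
#'
#' @param times Strictly increasing sampling times (h).
#' @param impedance Well impedance at each time.
#' @param blank Cell-free (background) impedance: scalar or per-time vector.
#' @param nominal Nominal impedance value, > 0.
#' @param matrigel Logical: Matrigel-coated well (invasion assay)?
#' @param t_treat Treatment time (h), or `NA`.
#' @return An object of class `impedance_series`.
#' @export
impedance_series <- function(times, impedance, blank, nominal,
                             matrigel = FALSE, t_treat = NA_real_) {
  stopifnot(length(times) == length(impedance), all(diff(times) > 0))
  if (!(nominal > 0)) stop("`nominal` must be > 0")
  blank <- rep_len(blank, length(times))
  structure(list(times = times, impedance = impedance, blank = blank,
                 nominal = nominal, matrigel = matrigel, t_treat = t_treat),
            class = "impedance_series")
}

#' Cell index of an impedance series
#'
#' `CI(t) = (Z(t) - Z_blank(t)) / Z_nominal`, the unitless adherent-cell
#' coverage measure of impedance-based real-time cell analysis.
#'
#' @param series An [impedance_series()].
#' @return Numeric vector of CI values, one per time point.
#' @examples
#' s <- impedance_series(1:16, rep(20, 16), blank = 10, nominal = 15)
#' cell_index(s)[1]  # 2/3
#' @export
cell_index <- function(series) {
  stopifnot(inherits(series, "impedance_series"))
  (series$impedance - series$blank) / series$nominal
}

#' Normalise a cell-index series to 1 at the treatment time
#'
#' `CI(t) / CI(t_treat)`; the value at the treatment time is exactly 1.
#' When `t_treat` falls between samples, `CI(t_treat)` is obtained by
#' linear interpolation. The normalised CI of a Matrigel-coated well is the
#' relative invasiveness rate at each time point.
#'
#' @param ci Numeric CI vector (e.g. from [cell_index()]).
#' @param times Sampling times (h), same length.
#' @param t_treat Treatment time (h), within the sampled range.
#' @return Normalised CI vector.
#' @export
normalize_ci <- function(ci, times, t_treat) {
  stopifnot(length(ci) == length(times))
  if (t_treat < min(times) || t_treat > max(times))
    stop("`t_treat` outside the series")
  ref <- stats::approx(times, ci, xout = t_treat)$y
  if (ref == 0) stop("CI at treatment time is zero; cannot normalise")
  ci / ref
}

#' Relative invasiveness of a Matrigel-coated well
#'
#' Convenience wrapper: cell index normalised to 1 at the treatment time,
#' for a well annotated as Matrigel-coated.
#'
#' @param series An [impedance_series()] with `matrigel = TRUE` and a
#'   `t_treat`.
#' @return Normalised CI vector (the invasiveness rate over time).
#' @export
relative_invasiveness <- function(series) {
  if (!isTRUE(series$matrigel))
    stop("relative invasiveness is defined for matrigel-coated wells")
  normalize_ci(cell_index(series), series$times, series$t_treat)
}

# ---- migration tracks -------------------------------------------------------

#' Cell migration track
#'
#' @param id Cell identifier.
#' @param times Sampling times (h), increasing, length >= 2.
#' @param x,y Positions (um).
#' @return An object of class `cell_track`.
#' @export
cell_track <- function(id, times, x, y) {
  stopifnot(length(times) >= 2L, all(diff(times) > 0),
            length(x) == length(times), length(y) == length(times))
  structure(list(id = id, times = times, x = x, y = y), class = "cell_track")
}

#' Motility summary of a set of tracks
#'
#' Per cell: mean speed = path length / elapsed time (um/h). Across all
#' steps of all cells: a rose histogram of step directions (default 12 bins
#' of 30 degrees, the first centred on +x) weighted by step speed, and the
#' summary vector `sum(displacements) / sum(path lengths)` - magnitude 1
#' for perfectly straight common motion, 0 for balanced motion, and always
#' at most 1 by the triangle inequality.
#'
#' @param tracks List of [cell_track()] objects.
#' @param n_bins Number of rose bins (default 12).
#' @param summary_mode `"pooled"` (default: one ratio over all steps) or
#'   `"per_cell"` (average of per-cell summary vectors).
#' @return List of class `motility_summary`: `speeds` (data frame `id`,
#'   `speed`), `rose` (data frame `angle_mid`, `weight`), `summary_vector`
#'   (length-2), `summary_magnitude`.
#' @export
track_motility <- function(tracks, n_bins = 12,
                           summary_mode = c("pooled", "per_cell")) {
  summary_mode <- match.arg(summary_mode)
  stopifnot(length(tracks) >= 1L)
  width <- 360 / n_bins
  rose_w <- numeric(n_bins)
  disp <- c(0, 0); path <- 0
  per_cell <- matrix(NA_real_, length(tracks), 2L)
  speeds <- data.frame(id = character(0), speed = numeric(0))
  for (i in seq_along(tracks)) {
    tr <- tracks[[i]]
    dt <- diff(tr$times)
    if (sum(dt) <= 0) stop("zero elapsed time")
    dx <- diff(tr$x); dy <- diff(tr$y)
    steps <- sqrt(dx^2 + dy^2)
    speeds <- rbind(speeds, data.frame(id = as.character(tr$id),
                                       speed = sum(steps) / sum(dt)))
    moved <- steps > 0
    if (any(moved)) {
      ang <- atan2(dy[moved], dx[moved]) * 180 / pi
      bin <- floor(((ang + width / 2) %% 360) / width) + 1L
      w <- (steps / dt)[moved]
      rose_w[seq_len(n_bins)] <- rose_w + vapply(seq_len(n_bins), function(b)
        sum(w[bin == b]), numeric(1))
    }
    disp <- disp + c(sum(dx), sum(dy))
    path <- path + sum(steps)
    per_cell[i, ] <- if (sum(steps) > 0)
      c(sum(dx), sum(dy)) / sum(steps) else c(0, 0)
  }
  sv <- if (summary_mode == "pooled") {
    if (path > 0) disp / path else c(0, 0)
  } else colMeans(per_cell)
  structure(list(speeds = speeds,
                 rose = data.frame(angle_mid = (seq_len(n_bins) - 1L) * width,
                                   weight = rose_w),
                 summary_vector = sv,
                 summary_magnitude = sqrt(sum(sv^2)),
                 summary_mode = summary_mode),
            class = "motility_summary")
}

#' @export
print.motility_summary <- function(x, ...) {
  cat(sprintf("Motility: %d cell(s), mean speed %.3g um/h, |summary vector| = %.3f (%s)\n",
              nrow(x$speeds), mean(x$speeds$speed), x$summary_magnitude,
              x$summary_mode))
  invisible(x)
}

#' Rose diagram of step directions
#'
#' Polar bar chart of the speed-weighted direction histogram from
#' [track_motility()].
#'
#' @param x A `motility_summary`.
#' @param ... Passed to [graphics::polygon()].
#' @export
rose_plot <- function(x, ...) {
  stopifnot(inherits(x, "motility_summary"))
  w <- x$rose$weight
  r <- if (max(w) > 0) w / max(w) else w
  graphics::plot(NA, xlim = c(-1, 1), ylim = c(-1, 1), asp = 1, axes = FALSE,
                 xlab = "", ylab = "", main = "step-direction rose (speed-weighted)")
  half <- pi * (360 / nrow(x$rose)) / 360
  for (i in seq_along(r)) {
    a <- x$rose$angle_mid[i] * pi / 180
    aa <- seq(a - half, a + half, length.out = 16)
    graphics::polygon(c(0, r[i] * cos(aa)), c(0, r[i] * sin(aa)),
                      col = "steelblue", ...)
  }
  invisible(x)
}

#' Wound-closure statistics from imported open-area fractions
#'
#' The open-wound-area percentages themselves come from the wound-healing
#' software; this helper only aggregates them. Per well, closure =
#' `f0 - f24` (percentage points); negative closure (wound widening) is
#' allowed and flagged.
#'
#' @param fractions_t0,fractions_t24 Paired percentages in `[0, 100]`,
#'   equal length.
#' @param group Optional grouping factor for summaries.
#' @return List with `wells` (data frame `f0`, `f24`, `closure`, `widened`)
#'   and `summary` (per-group mean/median/sd of closure).
#' @export
wound_open_fraction_stats <- function(fractions_t0, fractions_t24,
                                      group = NULL) {
  if (length(fractions_t0) != length(fractions_t24))
    stop("unpaired input: t0 and t24 must have equal length")
  stopifnot(all(fractions_t0 >= 0 & fractions_t0 <= 100),
            all(fractions_t24 >= 0 & fractions_t24 <= 100))
  closure <- fractions_t0 - fractions_t24
  if (is.null(group)) group <- rep("all", length(closure))
  wells <- data.frame(group = group, f0 = fractions_t0, f24 = fractions_t24,
                      closure = closure, widened = closure < 0)
  agg <- do.call(rbind, lapply(split(wells$closure, wells$group), function(v)
    data.frame(n = length(v), mean = mean(v), median = stats::median(v),
               sd = stats::sd(v))))
  agg$group <- rownames(agg); rownames(agg) <- NULL
  list(wells = wells, summary = agg[, c("group", "n", "mean", "median", "sd")])
}
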