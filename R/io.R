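# File interfaces: plain-text force-curve directories, float/label TIFFs
# with JSON sidecars, and the CSV schemas for tracks and impedance wells.

#' Write / read a force map as a plain-text directory
#'
#' The native curve container is a directory holding one two-column TSV per
#' curve (`curve_0001.tsv`, ... with columns `z_um`, `force_nN`, row-major
#' grid order) and a `meta.json` sidecar with the acquisition settings
#' (`spring_constant`, `setpoint`, `speed`, `shape`, `extent_um`) and the
#' per-curve map positions.
#'
#' @param fmap A [force_map()].
#' @param dir Directory to create/fill.
#' @return `dir`, invisibly (`write`); a [force_map()] (`read`).
#' @export
write_force_map <- function(fmap, dir) {
  stopifnot(inherits(fmap, "force_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cv1 <- fmap$curves[[1L]]
  meta <- list(spring_constant = cv1$spring_constant, setpoint = cv1$setpoint,
               speed = cv1$speed, shape = fmap$shape,
               extent_um = fmap$extent_um,
               positions = t(vapply(fmap$curves, `[[`, numeric(2), "position")))
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  for (i in seq_along(fmap$curves)) {
    cv <- fmap$curves[[i]]
    utils::write.table(
      data.frame(z_um = cv$z_extend, force_nN = cv$force_extend),
      file.path(dir, sprintf("curve_%04d.tsv", i)),
      sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(dir)
}

#' @rdname write_force_map
#' @export
read_force_map <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "meta.json"),
                              simplifyVector = TRUE)
  files <- sort(list.files(dir, pattern = "^curve_\\d+\\.tsv$",
                           full.names = TRUE))
  curves <- lapply(seq_along(files), function(i) {
    d <- utils::read.table(files[i], header = TRUE, sep = "\t")
    pos <- if (!is.null(meta$positions)) as.numeric(meta$positions[i, ])
           else c(NA_real_, NA_real_)
    force_curve(d$z_um, d$force_nN, spring_constant = meta$spring_constant,
                setpoint = meta$setpoint, speed = meta$speed, position = pos)
  })
  force_map(curves, shape = unlist(meta$shape),
            extent_um = unlist(meta$extent_um))
}

#' Write / read a floating-point image as TIFF with a JSON sidecar
#'
#' 32-bit float TIFF plus `<file>.json` carrying `pixel_size` and any extra
#' metadata (e.g. `wavelength`, `alpha` for phase images). TIFF samples are
#' stored affinely rescaled to `[0, 1]`; the sidecar records `offset` and
#' `scale` so reading restores physical units (`value = sample * scale +
#' offset`).
#'
#' @param img Numeric matrix.
#' @param path TIFF path.
#' @param pixel_size um per pixel.
#' @param ... Further scalar metadata stored in the sidecar.
#' @return `path` invisibly (`write`); a list `(image, meta)` (`read`).
#' @export
write_float_tiff <- function(img, path, pixel_size, ...) {
  offset <- min(img)
  scale <- max(img) - offset
  if (scale == 0) scale <- 1
  tiff::writeTIFF((img - offset) / scale, path, bits.per.sample = 32L)
  jsonlite::write_json(c(list(pixel_size = pixel_size, offset = offset,
                              scale = scale), list(...)),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_float_tiff
#' @export
read_float_tiff <- function(path) {
  img <- tiff::readTIFF(path, as.is = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  list(image = img * meta$scale + meta$offset, meta = meta)
}

#' Write / read a label mask as 16-bit TIFF
#'
#' Labels (0 background, 1..n) stored losslessly as 16-bit integers.
#'
#' @param mask Integer label matrix (`seg_mask` or plain), labels < 65536.
#' @param path TIFF path.
#' @return `path` invisibly (`write`); a `seg_mask` (`read`).
#' @export
write_mask_tiff <- function(mask, path) {
  lab <- unclass(mask)
  stopifnot(max(lab) < 65536L)
  tiff::writeTIFF(lab / 65535, path, bits.per.sample = 16L)
  invisible(path)
}

#' @rdname write_mask_tiff
#' @export
read_mask_tiff <- function(path) {
  img <- tiff::readTIFF(path)
  new_seg_mask(matrix(as.integer(round(img * 65535)), nrow(img), ncol(img)))
}

#' Read cell tracks from CSV
#'
#' Expected columns: `track_id`, `t_h`, `x_um`, `y_um`.
#'
#' @param path CSV path.
#' @return List of [cell_track()] objects.
#' @export
read_tracks_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("track_id", "t_h", "x_um", "y_um")
  if (!all(need %in% names(d)))
    stop("track CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$track_id), function(g) {
    g <- g[order(g$t_h), ]
    cell_track(g$track_id[1L], g$t_h, g$x_um, g$y_um)
  })
}

#' Write cell tracks to CSV
#'
#' @param tracks List of [cell_track()] objects.
#' @param path CSV path.
#' @export
write_tracks_csv <- function(tracks, path) {
  d <- do.call(rbind, lapply(tracks, function(tr)
    data.frame(track_id = tr$id, t_h = tr$times, x_um = tr$x, y_um = tr$y)))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' Read an impedance well table from CSV
#'
#' Expected columns: `time_h`, `well`, `impedance`; one series per well.
#'
#' @param path CSV path.
#' @param blank Cell-free impedance (scalar or per-time), passed through.
#' @param nominal Nominal impedance value.
#' @param matrigel Named logical vector (by well) or scalar.
#' @param t_treat Treatment time (h).
#' @return Named list of [impedance_series()].
#' @export
read_impedance_csv <- function(path, blank, nominal, matrigel = FALSE,
                               t_treat = NA_real_) {
  d <- utils::read.csv(path)
  need <- c("time_h", "well", "impedance")
  if (!all(need %in% names(d)))
    stop("impedance CSV must have columns: ", paste(need, collapse = ", "))
  lapply(split(d, d$well), function(g) {
    g <- g[order(g$time_h), ]
    mg <- if (length(matrigel) > 1L) isTRUE(matrigel[[as.character(g$well[1L])]])
          else isTRUE(matrigel)
    impedance_series(g$time_h, g$impedance, blank = blank, nominal = nominal,
                     matrigel = mg, t_treat = t_treat)
  })
}

#' Median Young's modulus per cell line from converted curve directories
#'
#' Batch runner for benchmarking against published per-line medians: each
#' named directory (one per cell line, in the plain-text schema of
#' [write_force_map()]) is fitted pixel-by-pixel, segmented on the
#' setpoint-height topography, and reduced to the median of the per-cell
#' mean moduli.
#'
#' @param dirs Named character vector of force-map directories.
#' @param tip A [tip_model()].
#' @return Named numeric vector of median per-cell `mean_E` (Pa).
#' @export
untreated_line_medians <- function(dirs, tip = tip_model()) {
  vapply(dirs, function(d) {
    smap <- build_stiffness_map(read_force_map(d), tip)
    mask <- segment_height_map(map_topography(smap))
    rec <- extract_cell_mechanics(smap, mask)
    stats::median(rec$mean_E[rec$valid], na.rm = TRUE)
  }, numeric(1))
}
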