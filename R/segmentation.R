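# Watershed segmentation of AFM setpoint-height topographies and QPI
# dry-mass images, plus a replayable manual-correction edit script.

# Robust background surface: plane fitted to the lowest-decile pixels.
# Returns list(plane = matrix, mad = residual MAD of those pixels).
background_plane <- function(img, decile = 0.1) {
  nr <- nrow(img); nc <- ncol(img)
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  low <- img <= stats::quantile(img, decile, names = FALSE)
  df <- data.frame(v = img[low], x = xs[low], y = ys[low])
  fit <- stats::lm(v ~ x + y, data = df)
  plane <- matrix(stats::predict(fit, data.frame(x = as.vector(xs),
                                                 y = as.vector(ys))), nr, nc)
  list(plane = plane, mad = stats::mad(stats::residuals(fit)))
}

relabel_consecutive <- function(lab) {
  u <- sort(unique(lab[lab > 0]))
  if (!length(u)) return(lab)
  out <- lab
  out[lab > 0] <- match(lab[lab > 0], u)
  out
}

new_seg_mask <- function(lab, provenance = "automatic") {
  lab <- relabel_consecutive(lab)
  storage.mode(lab) <- "integer"
  structure(lab, provenance = provenance, class = c("seg_mask", "matrix", "array"))
}

#' @export
print.seg_mask <- function(x, ...) {
  cat(sprintf("Segmentation mask %d x %d: %d cell(s) [%s]\n",
              nrow(x), ncol(x), max(x), attr(x, "provenance")))
  invisible(x)
}

#' Segment a setpoint-height topography into cells
#'
#' Pipeline: Gaussian smoothing; robust background removal (plane fitted to
#' the lowest-decile pixels, foreground = height above plane + `offset_mad`
#' background MADs); watershed of the smoothed height restricted to the
#' foreground, with basins whose summit rises less than `hmax` um above a
#' shared saddle merged (h-maxima style seeding); optional manual
#' corrections applied last via [apply_mask_edits()].
#'
#' @param height Numeric matrix of heights (um), cells elevated above the
#'   substrate. See [map_topography()] for converting setpoint-z images.
#' @param manual_corrections Optional edit script, see [apply_mask_edits()].
#' @param sigma Gaussian smoothing sigma in pixels (default 1).
#' @param offset_mad Foreground threshold in background MADs above the
#'   fitted plane (default 3).
#' @param hmax Minimum summit prominence in um for a basin to stand alone
#'   (default 0.5, below typical cell height and above map noise).
#' @param min_height Absolute floor on the foreground threshold (um above
#'   the background plane, default 0.5): pixels lower than this are
#'   substrate even when the background noise estimate is tiny.
#' @param min_area Minimum object area in pixels (default 5); smaller
#'   fragments are dropped.
#' @return A `seg_mask`: integer label matrix (0 background, 1..n cells)
#'   with a `provenance` attribute. An image with no foreground yields an
#'   empty mask, not an error.
#' @export
segment_height_map <- function(height, manual_corrections = NULL, sigma = 1,
                               offset_mad = 3, hmax = 0.5, min_area = 5,
                               min_height = 0.5) {
  stopifnot(is.matrix(height), all(is.finite(height)))
  sm <- if (sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(height), sigma = sigma))
  else height
  bg <- background_plane(sm)
  rel <- sm - bg$plane
  fg <- rel > max(offset_mad * bg$mad, min_height, 1e-9)
  if (!any(fg)) return(new_seg_mask(matrix(0L, nrow(height), ncol(height))))
  relief <- rel
  relief[!fg] <- 0
  lab <- as.matrix(EBImage::watershed(EBImage::Image(relief), tolerance = hmax,
                                      ext = 1))
  lab <- drop_small_labels(lab, min_area)
  mask <- new_seg_mask(lab)
  if (!is.null(manual_corrections))
    mask <- apply_mask_edits(mask, manual_corrections)
  mask
}

drop_small_labels <- function(lab, min_area) {
  if (min_area <= 1) return(lab)
  tab <- tabulate(lab[lab > 0])
  small <- which(tab > 0 & tab < min_area)
  if (length(small)) lab[lab %in% small] <- 0L
  lab
}

#' Apply a replayable manual-correction script to a segmentation mask
#'
#' Manual corrections are expressed as an ordered list of directives rather
#' than destructive pixel painting, so a corrected segmentation can be
#' replayed exactly. Supported directives (each a list):
#' \describe{
#'   \item{merge}{`list(op = "merge", labels = c(a, b, ...))` - combine labels.}
#'   \item{delete}{`list(op = "delete", label = k)` - set label to background.}
#'   \item{split}{`list(op = "split", label = k, seeds = cbind(row, col))` -
#'     partition the label's pixels by nearest seed point.}
#' }
#' Labels are renumbered consecutively after the script runs.
#'
#' @param mask A `seg_mask` or integer label matrix.
#' @param edits List of directives, applied in order.
#' @return A `seg_mask` with provenance `"manually corrected"`.
#' @export
apply_mask_edits <- function(mask, edits) {
  lab <- unclass(mask)
  for (e in edits) {
    op <- match.arg(e$op, c("merge", "delete", "split"))
    if (op == "merge") {
      keep <- min(e$labels)
      lab[lab %in% e$labels] <- keep
    } else if (op == "delete") {
      lab[lab == e$label] <- 0L
    } else {
      px <- which(lab == e$label, arr.ind = TRUE)
      if (!nrow(px)) next
      seeds <- e$seeds
      d2 <- outer(px[, 1L], seeds[, 1L], "-")^2 +
            outer(px[, 2L], seeds[, 2L], "-")^2
      assign_to <- max(lab) + max.col(-d2, ties.method = "first")
      lab[px] <- assign_to
    }
  }
  new_seg_mask(lab, provenance = "manually corrected")
}

#' Segment a dry-mass image with watershed and region merging
#'
#' Thresholds the mass image above background, seeds a watershed at local
#' maxima (summit prominence `hmax`), then merges adjacent basins while the
#' ridge (saddle) density between them exceeds `merge_fraction` times the
#' lower of the two peak densities - shallow internal maxima of a single
#' cell are thereby absorbed.
#'
#' @param mass A [drymass_image()] or numeric matrix (pg/um^2).
#' @param threshold Foreground threshold; default `NULL` estimates it as the
#'   robust background plane plus `offset_mad` image-wide MADs of the
#'   plane residuals (the MAD is robust to the minority of cell pixels).
#' @param offset_mad Threshold offset in background MADs (default 4).
#' @param sigma Gaussian smoothing sigma in pixels (default 1).
#' @param hmax Watershed summit prominence in mass-density units
#'   (default 0.05).
#' @param merge_fraction Saddle/peak ratio above which two basins are merged
#'   (default 0.7).
#' @param min_area Minimum object area in pixels (default 5).
#' @return A `seg_mask`; a blank image yields 0 labels.
#' @export
segment_qpi <- function(mass, threshold = NULL, offset_mad = 4, sigma = 1,
                        hmax = 0.05, merge_fraction = 0.7, min_area = 5) {
  img <- if (inherits(mass, "drymass_image")) mass$mass else mass
  stopifnot(is.matrix(img))
  sm <- if (sigma > 0)
    as.matrix(EBImage::gblur(EBImage::Image(img), sigma = sigma))
  else img
  if (is.null(threshold)) {
    bg <- background_plane(sm)
    noise <- stats::mad(sm - bg$plane)
    thr_img <- bg$plane + max(offset_mad * noise, 1e-9)
  } else thr_img <- matrix(threshold, nrow(sm), ncol(sm))
  fg <- sm > thr_img
  if (!any(fg)) return(new_seg_mask(matrix(0L, nrow(img), ncol(img))))
  relief <- sm - thr_img
  relief[!fg] <- 0
  lab <- as.matrix(EBImage::watershed(EBImage::Image(relief), tolerance = hmax,
                                      ext = 1))
  lab <- drop_small_labels(lab, min_area)
  lab <- merge_regions(lab, sm, merge_fraction)
  new_seg_mask(lab)
}

# Merge adjacent labels while the saddle (highest intensity on the shared
# 4-neighbour interface) exceeds merge_fraction * the lower peak intensity.
merge_regions <- function(lab, img, merge_fraction) {
  repeat {
    labs <- sort(unique(lab[lab > 0]))
    if (length(labs) < 2L) return(lab)
    peaks <- vapply(labs, function(l) max(img[lab == l]), numeric(1))
    names(peaks) <- labs
    # interface saddles over horizontal and vertical neighbour pairs
    pairs <- rbind(
      interface_pairs(lab[-nrow(lab), ], lab[-1L, ],
                      img[-nrow(lab), ], img[-1L, ]),
      interface_pairs(lab[, -ncol(lab)], lab[, -1L],
                      img[, -ncol(lab)], img[, -1L]))
    if (is.null(pairs) || !nrow(pairs)) return(lab)
    key <- paste(pairs[, 1L], pairs[, 2L])
    saddle <- tapply(pairs[, 3L], key, max)
    ab <- do.call(rbind, strsplit(names(saddle), " "))
    a <- as.integer(ab[, 1L]); b <- as.integer(ab[, 2L])
    ratio <- as.numeric(saddle) /
      pmin(peaks[as.character(a)], peaks[as.character(b)])
    i <- which.max(ratio)
    if (ratio[i] <= merge_fraction) return(lab)
    lab[lab == b[i]] <- a[i]
  }
}

interface_pairs <- function(la, lb, va, vb) {
  sel <- la > 0 & lb > 0 & la != lb
  if (!any(sel)) return(NULL)
  a <- pmin(la[sel], lb[sel]); b <- pmax(la[sel], lb[sel])
  cbind(a, b, pmin(va[sel], vb[sel]))
}
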