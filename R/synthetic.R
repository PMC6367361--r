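# Seeded synthetic-data generators with ground truth for every input
# modality: AFM force maps, phase images, fibre images, colony plates,
# migration tracks and impedance series. Each generator draws from its own
# RNG substream derived from the master seed, so adding one generator to a
# workflow never perturbs the draws of another.

# Named substream: a distinct, reproducible seed per generator.
substream_seed <- function(seed, name) {
  idx <- match(name, c("force_map", "phase", "fiber", "colony", "tracks",
                       "impedance"))
  if (is.na(idx)) stop("unknown substream name")
  as.integer((as.numeric(seed) * 1009 + idx * 104729) %% 2147483587) + 1L
}

# ---- force maps -------------------------------------------------------------

#' Generate a synthetic AFM force map with known ground truth
#'
#' Builds a smooth height field of Gaussian-bump cells on a flat substrate,
#' assigns each cell its own Young's modulus, and simulates a
#' force-distance curve at every pixel with [simulate_force_curve()]
#' (per-cell E inside cells, substrate E elsewhere; contact point set by
#' the local surface height; Gaussian force noise). Cell centres are placed
#' at random; layouts whose cells overlap are rejected and redrawn with a
#' warning.
#'
#' @param seed Master integer seed.
#' @param E_cells Per-cell Young's moduli (Pa); the cell count is
#'   `length(E_cells)`. Default `c(700, 1200)`.
#' @param E_substrate Substrate modulus (Pa), default 10000.
#' @param shape Grid `(rows, cols)`, default `c(64, 64)`.
#' @param extent_um Physical edge length (um), default 80.
#' @param cell_radius_um,cell_height_um Cell bump radius and peak height.
#' @param noise_sd Force noise sd (nN), default 0.02.
#' @param tip A [tip_model()].
#' @param settings An [afm_settings()].
#' @return List with `map` (a [force_map()]) and `truth`: `height` (um
#'   matrix), `E_field` (Pa matrix), `masks` (integer label matrix, labels
#'   ordered as `E_cells`), `cells` (data frame `label`, `x`, `y`, `E`).
#' @export
gen_force_map <- function(seed, E_cells = c(700, 1200), E_substrate = 10000,
                          shape = c(64, 64), extent_um = 80,
                          cell_radius_um = 12, cell_height_um = 3,
                          noise_sd = 0.02, tip = tip_model(),
                          settings = afm_settings()) {
  n_cells <- length(E_cells)
  nr <- shape[1L]; nc <- shape[2L]
  px <- extent_um / nc
  xs <- (seq_len(nc) - 0.5) * px
  ys <- (seq_len(nr) - 0.5) * px
  X <- matrix(rep(xs, each = nr), nr, nc)
  Y <- matrix(rep(ys, nc), nr, nc)
  with_local_seed(substream_seed(seed, "force_map"), {
    centres <- NULL
    if (n_cells > 0) {
      for (attempt in seq_len(50)) {
        cx <- stats::runif(n_cells, cell_radius_um, extent_um - cell_radius_um)
        cy <- stats::runif(n_cells, cell_radius_um, extent_um - cell_radius_um)
        ok <- TRUE
        if (n_cells > 1)
          ok <- min(stats::dist(cbind(cx, cy))) > 2.2 * cell_radius_um
        if (ok) { centres <- cbind(cx, cy); break }
        warning("overlapping cell layout; regenerating")
      }
      if (is.null(centres)) stop("could not place non-overlapping cells")
    }
    h <- matrix(0, nr, nc)
    lab <- matrix(0L, nr, nc)
    best <- matrix(0, nr, nc)
    sig <- cell_radius_um / 2
    for (i in seq_len(n_cells)) {
      bump <- cell_height_um *
        exp(-((X - centres[i, 1L])^2 + (Y - centres[i, 2L])^2) / (2 * sig^2))
      h <- h + bump
      take <- bump > 0.5 & bump > best
      lab[take] <- i
      best[take] <- bump[take]
    }
    E_field <- matrix(E_substrate, nr, nc)
    for (i in seq_len(n_cells)) E_field[lab == i] <- E_cells[i]
    z_clear <- settings$z_max - 3   # leave room for indentation + bending
    curves <- vector("list", nr * nc)
    for (r in seq_len(nr)) for (c in seq_len(nc)) {
      curves[[(r - 1L) * nc + c]] <- simulate_force_curve(
        E_field[r, c], tip, z0 = z_clear - h[r, c], baseline = 0,
        noise_sd = noise_sd, settings = settings,
        position = c(X[r, c], Y[r, c]))
    }
    list(map = force_map(curves, shape = shape, extent_um = extent_um),
         truth = list(height = h, E_field = E_field, masks = lab,
                      cells = if (n_cells > 0)
                        data.frame(label = seq_len(n_cells),
                                   x = centres[, 1L], y = centres[, 2L],
                                   E = E_cells) else NULL))
  })
}

# ---- phase images -----------------------------------------------------------

# Compact cosine-taper bump with a flat core; integrates (discretely) to 1
# after normalisation, so a cell's deposited mass is exact.
mass_bump <- function(X, Y, cx, cy, r_core, r_out) {
  d <- sqrt((X - cx)^2 + (Y - cy)^2)
  w <- ifelse(d <= r_core, 1,
              ifelse(d >= r_out, 0,
                     0.5 * (1 + cos(pi * (d - r_core) / (r_out - r_core)))))
  w
}

#' Generate a synthetic quantitative phase image with known dry mass
#'
#' Deposits per-cell mass profiles (flat core with a cosine rim, discretely
#' normalised so each cell's total mass is exact), converts mass density to
#' phase by inverting `m = phi * lambda / (2 * pi * alpha)`, then adds a
#' constant background phase offset and Gaussian phase noise.
#'
#' @param seed Master integer seed.
#' @param total_mass_pg Per-cell dry masses (pg); cell count is its length.
#' @param shape Image `(rows, cols)`, default `c(160, 160)`.
#' @param pixel_size um per pixel, default 0.5.
#' @param wavelength,alpha Optical constants, defaults 0.65 um and
#'   0.18 um^3/pg.
#' @param cell_radius_um Outer cell radius (um), default 12.
#' @param bg_phase Background phase offset (rad), default 0.15.
#' @param noise_sd Phase noise sd (rad), default 0.01.
#' @return List with `image` (a [phase_image()]) and `truth`: `masks`
#'   (label matrix of cell supports), `mass` (noise-free pg/um^2 matrix),
#'   `cells` (data frame `label`, `x`, `y`, `total_mass`).
#' @export
gen_phase_image <- function(seed, total_mass_pg = c(250, 300, 350),
                            shape = c(160, 160), pixel_size = 0.5,
                            wavelength = 0.65, alpha = 0.18,
                            cell_radius_um = 12, bg_phase = 0.15,
                            noise_sd = 0.01) {
  n_cells <- length(total_mass_pg)
  nr <- shape[1L]; nc <- shape[2L]
  ext_x <- nc * pixel_size; ext_y <- nr * pixel_size
  X <- matrix(rep((seq_len(nc) - 0.5) * pixel_size, each = nr), nr, nc)
  Y <- matrix(rep((seq_len(nr) - 0.5) * pixel_size, nc), nr, nc)
  with_local_seed(substream_seed(seed, "phase"), {
    mass <- matrix(0, nr, nc)
    lab <- matrix(0L, nr, nc)
    centres <- matrix(NA_real_, n_cells, 2L)
    if (n_cells > 0) {
      for (attempt in seq_len(200)) {
        cx <- stats::runif(n_cells, cell_radius_um, ext_x - cell_radius_um)
        cy <- stats::runif(n_cells, cell_radius_um, ext_y - cell_radius_um)
        ok <- n_cells == 1 ||
          min(stats::dist(cbind(cx, cy))) > 2.1 * cell_radius_um
        if (ok) break
      }
      if (!ok) stop("could not place non-overlapping cells")
      centres <- cbind(cx, cy)
      for (i in seq_len(n_cells)) {
        w <- mass_bump(X, Y, cx[i], cy[i], 0.6 * cell_radius_um,
                       cell_radius_um)
        dens <- w / (sum(w) * pixel_size^2) * total_mass_pg[i]
        mass <- mass + dens
        lab[w > 0] <- i
      }
    }
    phase <- 2 * pi * alpha * mass / wavelength + bg_phase
    if (noise_sd > 0)
      phase <- phase + stats::rnorm(length(phase), 0, noise_sd)
    list(image = phase_image(matrix(phase, nr, nc), pixel_size, wavelength,
                             alpha),
         truth = list(masks = lab, mass = mass,
                      cells = if (n_cells > 0)
                        data.frame(label = seq_len(n_cells),
                                   x = centres[, 1L], y = centres[, 2L],
                                   total_mass = total_mass_pg) else NULL))
  })
}

# ---- fibre images -----------------------------------------------------------

# von Mises sampler (Best & Fisher 1979 rejection scheme), angles in
# radians around mu.
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(stats::runif(n, -pi, pi) + mu)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1L])
    f <- (1 + r * z) / (r + z)
    c_ <- kappa * (r - f)
    if (c_ * (2 - c_) - u[2L] > 0 || log(c_ / u[2L]) + 1 - c_ >= 0) {
      out[i] <- sign(u[3L] - 0.5) * acos(f) + mu
      i <- i + 1L
    }
  }
  out
}

#' Generate a synthetic stress-fibre image with known orientations
#'
#' Draws fibre orientations from a von Mises distribution with mean
#' `mu_deg` and concentration `kappa` (kappa -> Inf gives perfectly aligned
#' fibres), renders each fibre as a line segment with a Gaussian
#' cross-section into an intensity channel, and returns per-fibre masks.
#' The truth records the drawn angles and their circular dispersion (raw
#' and axial modes).
#'
#' @param seed Master integer seed.
#' @param n_fibers Number of fibres, default 30.
#' @param mu_deg Mean orientation (degrees), default 40.
#' @param kappa von Mises concentration, default 4.
#' @param shape Image `(rows, cols)`, default `c(200, 200)`.
#' @param pixel_size um per pixel, default 0.2.
#' @param length_um Fibre length range `(min, max)` in um.
#' @param thickness_px Gaussian cross-section sigma in pixels, default 1.
#' @param noise_sd Additive intensity noise sd, default 0.02.
#' @return List with `channel` (intensity matrix), `fibres` (list of
#'   logical masks) and `truth`: `angles_deg` (in `[0, 180)`),
#'   `dispersion_raw`, `dispersion_axial` (radians).
#' @export
gen_fiber_image <- function(seed, n_fibers = 30, mu_deg = 40, kappa = 4,
                            shape = c(200, 200), pixel_size = 0.2,
                            length_um = c(8, 20), thickness_px = 1,
                            noise_sd = 0.02) {
  nr <- shape[1L]; nc <- shape[2L]
  with_local_seed(substream_seed(seed, "fiber"), {
    ang <- rvonmises(n_fibers, mu_deg * pi / 180, kappa)
    ang_deg <- (ang * 180 / pi) %% 180
    lens <- stats::runif(n_fibers, length_um[1L], length_um[2L]) / pixel_size
    chan <- matrix(0, nr, nc)
    xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
    ys <- matrix(rep(seq_len(nr), nc), nr, nc)
    fibres <- vector("list", n_fibers)
    for (i in seq_len(n_fibers)) {
      th <- ang_deg[i] * pi / 180
      L <- lens[i]
      cx <- stats::runif(1, L / 2 + 3, nc - L / 2 - 3)
      cy <- stats::runif(1, L / 2 + 3, nr - L / 2 - 3)
      # distance of each pixel to the segment
      ux <- cos(th); uy <- sin(th)
      px <- xs - cx; py <- ys - cy
      t <- pmax(pmin(px * ux + py * uy, L / 2), -L / 2)
      d <- sqrt((px - t * ux)^2 + (py - t * uy)^2)
      fibres[[i]] <- d <= max(1.5 * thickness_px, 1)
      chan <- chan + exp(-d^2 / (2 * thickness_px^2))
    }
    if (noise_sd > 0)
      chan <- chan + stats::rnorm(length(chan), 0, noise_sd)
    list(channel = matrix(chan, nr, nc), fibres = fibres,
         truth = list(angles_deg = ang_deg,
                      dispersion_raw = angle_dispersion(ang_deg, "raw"),
                      dispersion_axial = angle_dispersion(ang_deg, "axial")))
  })
}

# ---- colony plates ----------------------------------------------------------

#' Generate a synthetic colony-plate photograph with known coverage
#'
#' White plate with blue anti-aliased disks (trypan-blue-stained colonies)
#' placed without overlap inside the region of interest until the target
#' covered fraction is reached. The truth is the exact rasterised covered
#' fraction (pixels with majority colony coverage / ROI pixels).
#'
#' @param seed Master integer seed.
#' @param target_fraction Target covered fraction of the ROI, in `[0, 1)`.
#' @param shape Image `(rows, cols)`, default `c(240, 240)`.
#' @param roi_margin ROI inset from the image border in pixels (the ROI is
#'   the centred rectangle), default 20.
#' @param radius_px Colony radius range `(min, max)` in pixels.
#' @return List with `image` (H x W x 3 array in `[0, 1]`), `roi` (logical
#'   matrix), `roi_polygon` (4 x 2 `(row, col)` vertices) and `truth`:
#'   `covered_fraction`, `colony_mask`.
#' @export
gen_colony_image <- function(seed, target_fraction = 0.3,
                             shape = c(240, 240), roi_margin = 20,
                             radius_px = c(5, 10)) {
  stopifnot(target_fraction >= 0, target_fraction < 0.55)
  nr <- shape[1L]; nc <- shape[2L]
  roi <- matrix(FALSE, nr, nc)
  roi[(roi_margin + 1):(nr - roi_margin), (roi_margin + 1):(nc - roi_margin)] <- TRUE
  poly <- cbind(c(roi_margin + 1, roi_margin + 1, nr - roi_margin, nr - roi_margin),
                c(roi_margin + 1, nc - roi_margin, nc - roi_margin, roi_margin + 1))
  xs <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  ys <- matrix(rep(seq_len(nr), nc), nr, nc)
  with_local_seed(substream_seed(seed, "colony"), {
    cover <- matrix(0, nr, nc)   # anti-aliased coverage in [0, 1]
    centres <- matrix(numeric(0), 0, 3)
    n_roi <- sum(roi)
    guard <- 0L
    while (mean((cover > 0.5)[roi]) < target_fraction && guard < 20000L) {
      guard <- guard + 1L
      r <- stats::runif(1, radius_px[1L], radius_px[2L])
      cx <- stats::runif(1, roi_margin + r + 1, nc - roi_margin - r - 1)
      cy <- stats::runif(1, roi_margin + r + 1, nr - roi_margin - r - 1)
      if (nrow(centres) > 0) {
        d <- sqrt((centres[, 1L] - cx)^2 + (centres[, 2L] - cy)^2)
        if (any(d < centres[, 3L] + r + 1)) next
      }
      d <- sqrt((xs - cx)^2 + (ys - cy)^2)
      cover <- pmax(cover, pmin(pmax(r + 0.5 - d, 0), 1))
      centres <- rbind(centres, c(cx, cy, r))
    }
    col_bg <- c(0.97, 0.97, 0.95)
    col_fg <- c(0.20, 0.25, 0.75)
    img <- array(0, c(nr, nc, 3L))
    for (ch in 1:3)
      img[, , ch] <- col_bg[ch] * (1 - cover) + col_fg[ch] * cover
    list(image = img, roi = roi, roi_polygon = poly,
         truth = list(covered_fraction = mean((cover > 0.5)[roi]),
                      colony_mask = cover > 0.5))
  })
}

# ---- migration tracks -------------------------------------------------------

#' Generate biased persistent random-walk tracks
#'
#' Each cell takes constant-length steps (`speed * dt`); the heading is a
#' persistent random walk (direction blended with the previous heading)
#' further blended toward a common drift direction with weight `bias`:
#' `bias = 0` gives an unbiased walk, `bias = 1` straight-line motion along
#' the drift direction. By construction the realised per-cell speed equals
#' path length / elapsed time exactly.
#'
#' @param seed Master integer seed.
#' @param n_cells Number of tracks, default 100.
#' @param n_steps Steps per track, default 60.
#' @param dt_h Sampling interval (h), default 0.25.
#' @param speed_um_h Step speed (um/h), default 10.
#' @param bias Drift weight in `[0, 1]`, default 0.
#' @param bias_dir_deg Drift direction (degrees), default 0.
#' @param persistence Heading persistence in `[0, 1)`, default 0.5.
#' @return List with `tracks` (list of [cell_track()]) and `truth`:
#'   data frame `id`, `speed` (um/h), `net_angle_deg`.
#' @export
gen_tracks <- function(seed, n_cells = 100, n_steps = 60, dt_h = 0.25,
                       speed_um_h = 10, bias = 0, bias_dir_deg = 0,
                       persistence = 0.5) {
  stopifnot(bias >= 0, bias <= 1)
  step <- speed_um_h * dt_h
  mu <- bias_dir_deg * pi / 180
  with_local_seed(substream_seed(seed, "tracks"), {
    tracks <- vector("list", n_cells)
    truth <- data.frame(id = character(n_cells), speed = numeric(n_cells),
                        net_angle_deg = numeric(n_cells))
    for (i in seq_len(n_cells)) {
      th <- stats::runif(1, -pi, pi)
      xs <- numeric(n_steps + 1L); ys <- numeric(n_steps + 1L)
      for (s in seq_len(n_steps)) {
        eta <- stats::runif(1, -pi, pi)
        vx <- persistence * cos(th) + (1 - persistence) * cos(eta)
        vy <- persistence * sin(th) + (1 - persistence) * sin(eta)
        th <- atan2(vy, vx)
        wx <- (1 - bias) * cos(th) + bias * cos(mu)
        wy <- (1 - bias) * sin(th) + bias * sin(mu)
        hd <- atan2(wy, wx)
        xs[s + 1L] <- xs[s] + step * cos(hd)
        ys[s + 1L] <- ys[s] + step * sin(hd)
      }
      tt <- seq(0, by = dt_h, length.out = n_steps + 1L)
      tracks[[i]] <- cell_track(sprintf("cell%03d", i), tt, xs, ys)
      truth$id[i] <- sprintf("cell%03d", i)
      truth$speed[i] <- speed_um_h
      truth$net_angle_deg[i] <-
        atan2(ys[n_steps + 1L], xs[n_steps + 1L]) * 180 / pi
    }
    list(tracks = tracks, truth = truth)
  })
}

# ---- impedance --------------------------------------------------------------

#' Generate a synthetic impedance (RTCA) series with known cell index
#'
#' Logistic growth of the cell index on a 15-minute grid over 150 h (601
#' samples by default), with the post-treatment growth rate multiplied by
#' `multiplier` (1 = no effect). Gaussian noise is added in CI space and
#' the noisy CI is inverted through the cell-index formula to impedance,
#' so `cell_index()` of the generated series recovers the stored true CI
#' exactly.
#'
#' @param seed Master integer seed.
#' @param duration_h,dt_h Sampling span and interval (h); defaults 150 and
#'   0.25.
#' @param t_treat Treatment time (h), default 24.
#' @param K Logistic carrying capacity in CI units, default 8.
#' @param rate Logistic growth rate (1/h), default 0.08.
#' @param ci0 Initial CI, default 0.05.
#' @param multiplier Post-treatment rate multiplier, default 1.
#' @param blank Cell-free impedance, default 10.
#' @param nominal Nominal impedance, default 15.
#' @param noise_sd CI noise sd, default 0.01.
#' @param matrigel Matrigel annotation, default `TRUE` (invasion assay).
#' @return List with `series` (an [impedance_series()]) and `truth`:
#'   `ci` (the noisy CI the series encodes), `ci_clean` (noise-free).
#' @export
gen_impedance <- function(seed, duration_h = 150, dt_h = 0.25, t_treat = 24,
                          K = 8, rate = 0.08, ci0 = 0.05, multiplier = 1,
                          blank = 10, nominal = 15, noise_sd = 0.01,
                          matrigel = TRUE) {
  times <- seq(0, duration_h, by = dt_h)
  ci <- numeric(length(times))
  ci[1L] <- ci0
  for (i in seq_along(times)[-1L]) {
    r <- if (times[i - 1L] >= t_treat) rate * multiplier else rate
    ci[i] <- ci[i - 1L] + dt_h * r * ci[i - 1L] * (1 - ci[i - 1L] / K)
  }
  with_local_seed(substream_seed(seed, "impedance"), {
    ci_noisy <- if (noise_sd > 0)
      ci + stats::rnorm(length(ci), 0, noise_sd) else ci
    series <- impedance_series(times, ci_noisy * nominal + blank,
                               blank = blank, nominal = nominal,
                               matrigel = matrigel, t_treat = t_treat)
    list(series = series, truth = list(ci = ci_noisy, ci_clean = ci))
  })
}
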