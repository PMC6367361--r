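# Periphery bands, region intensities, shape descriptors, fibre metrics
# and circular orientation statistics.

test_that("periphery band of a disk matches the closed-form annulus ratio", {
  # 10 um disk at 0.5 um/px, 4 um band: (10^2 - 6^2) / 10^2 = 0.64
  dk <- disk_mask(20)                       # radius 20 px = 10 um
  band <- periphery_band(dk, width = 4, pixel_size = 0.5)
  expect_lt(abs(sum(band) / sum(dk) - 0.64), 0.02)
  # width 0: empty band
  expect_identical(sum(periphery_band(dk, width = 0, pixel_size = 0.5)), 0L)
  # band wider than the cell: the whole cell is the band
  small <- disk_mask(6)                     # radius 3 um
  expect_identical(periphery_band(small, width = 4, pixel_size = 0.5), small)
})

test_that("periphery and interior partition the mask exactly", {
  dk <- disk_mask(18)
  band <- periphery_band(dk, width = 3, pixel_size = 0.5)
  interior <- dk & !band
  expect_true(all((band | interior) == dk))
  expect_false(any(band & interior))
})

test_that("region intensities equal brute-force pixel loops", {
  img <- matrix(5, 12, 12)
  reg <- matrix(FALSE, 12, 12); reg[2:11, 2:11] <- TRUE
  ri <- region_intensity(img, reg)
  expect_identical(ri$integrated_intensity, 500)
  expect_identical(ri$median_intensity, 5)
  # even-count median: mean of the central pair
  img2 <- img; img2[reg][1:50] <- 2; img2[reg][51:100] <- 10
  expect_identical(region_intensity(img2, reg)$median_intensity, 6)
  # seeded random image: exact agreement with an explicit loop
  set.seed(8)
  band <- periphery_band(disk_mask(4, pad = 1), width = 2, pixel_size = 1)
  img3 <- matrix(runif(length(band)), nrow(band), ncol(band))
  tot <- 0
  for (r in seq_len(nrow(band))) for (c in seq_len(ncol(band)))
    if (band[r, c]) tot <- tot + img3[r, c]
  expect_equal(region_intensity(img3, band)$integrated_intensity, tot)
  expect_error(region_intensity(img, reg & FALSE), "empty")
})

test_that("shape descriptors recover closed-form values for disks and ellipses", {
  dk <- disk_mask(40)
  s <- cell_shape(dk, pixel_size = 0.5)
  expect_lt(abs(s$max_feret - 40), 0.75)          # diameter 80 px = 40 um
  expect_lt(abs(s$roundness - 1), 0.03)
  expect_lt(abs(s$aspect_ratio - 1), 0.02)
  # 2:1 ellipse: AR = 2 and roundness = 4*(pi*a*b)/(pi*(2a)^2) = 0.5
  el <- ellipse_mask(60, 30)
  se <- cell_shape(el)
  expect_lt(abs(se$aspect_ratio - 2), 0.03)
  expect_lt(abs(se$roundness - 0.5), 0.02)
  # rotation by 90 degrees changes nothing beyond discretisation
  rot <- t(el)[ncol(el):1, ]
  sr <- cell_shape(rot)
  for (f in c("area", "max_feret", "roundness", "aspect_ratio", "circularity"))
    expect_lt(abs(sr[[f]] - se[[f]]) / se[[f]], 0.01)
  expect_error(cell_shape(matrix(FALSE, 5, 5)), "empty")
})

test_that("fibre metrics: length, orientation and count", {
  n <- 120
  seg_mask_at <- function(angle_deg, len_px, width_px = 1) {
    th <- angle_deg * pi / 180
    xs <- matrix(rep(1:n, each = n), n, n); ys <- matrix(rep(1:n, n), n, n)
    px <- xs - 60; py <- ys - 60
    t <- pmax(pmin(px * cos(th) + py * sin(th), len_px / 2), -len_px / 2)
    sqrt((px - t * cos(th))^2 + (py - t * sin(th))^2) <= width_px
  }
  chan <- matrix(1, n, n)
  fm <- fiber_metrics(list(seg_mask_at(0, 100, 0.6), seg_mask_at(45, 60, 0.6)),
                      chan, pixel_size = 0.2)
  expect_identical(nrow(fm), 2L)                 # count = number of masks
  expect_lt(abs(fm$length[1] - 20), 0.5)         # 100 px * 0.2 um
  expect_lt(min(fm$feret_angle[1], 180 - fm$feret_angle[1]), 1)
  expect_lt(abs(fm$feret_angle[2] - 45), 1)
  expect_equal(fm$integrated_intensity[1], sum(seg_mask_at(0, 100, 0.6)))
  expect_error(fiber_metrics(list(matrix(FALSE, 4, 4)), matrix(1, 4, 4)),
               "empty")
})

test_that("circular dispersion matches hand-computed values", {
  expect_equal(angle_dispersion(c(37, 37, 37)), 0)
  expect_equal(angle_dispersion(c(0, 90)), sqrt(-2 * log(sqrt(2) / 2)),
               tolerance = 1e-12)
  expect_equal(angle_dispersion(c(0, 90)), 0.8326, tolerance = 1e-4)
  expect_error(angle_dispersion(10), "at least 2")
})

test_that("axial mode treats near-parallel orientations as concentrated", {
  # {10, 170} as orientations is the same fibre pair as {10, -10}
  ax <- angle_dispersion(c(10, 170), mode = "axial")
  expect_equal(ax, angle_dispersion(c(10, -10), mode = "axial"),
               tolerance = 1e-12)
  expect_lt(ax, 0.3)
  expect_lt(ax, angle_dispersion(c(10, 170), mode = "raw"))
  # brute-force check of the axial formula: double, evaluate, halve
  th2 <- c(10, 170) * 2 * pi / 180
  R2 <- sqrt(mean(cos(th2))^2 + mean(sin(th2))^2)
  expect_equal(ax, sqrt(-2 * log(R2)) / 2, tolerance = 1e-12)
})

test_that("dispersion is shift invariant and monotone in von Mises concentration", {
  set.seed(4)
  a <- runif(30, 0, 360)
  expect_equal(angle_dispersion(a), angle_dispersion(a + 360))
  expect_equal(angle_dispersion(a), angle_dispersion(a + 123.4),
               tolerance = 1e-9)
  disp <- vapply(c(0.5, 2, 8), function(kap)
    gen_fiber_image(13, n_fibers = 150, kappa = kap,
                    shape = c(60, 60), length_um = c(2, 4))$truth$dispersion_axial,
    numeric(1))
  expect_true(all(diff(disp) < 0))
})
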