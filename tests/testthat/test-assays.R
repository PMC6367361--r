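# Colony registration and coverage, cell-index arithmetic, track motility
# and wound-closure aggregation.

test_that("registration recovers known shifts and rotations", {
  g <- gen_colony_image(7, target_fraction = 0.3)
  # identity
  r0 <- register_to_reference(g$image, g$image)
  expect_identical(r0$shift, c(0, 0))
  expect_lt(abs(r0$angle), 0.25)
  # pure translation
  shifted <- transform_image(g$image, 0, c(12, -7), fill = 0.97)
  r1 <- register_to_reference(shifted, g$image)
  expect_true(all(abs(r1$shift - c(12, -7)) <= 1))
  # rotation + translation
  moved <- transform_image(g$image, 5, c(6, 9), fill = 0.97)
  r2 <- register_to_reference(moved, g$image)
  expect_lt(abs(r2$angle - 5), 0.5)
  expect_true(all(abs(r2$shift - c(6, 9)) <= 1))
  # featureless images cannot register
  expect_error(register_to_reference(matrix(0.5, 64, 64) + 1e-3,
                                     matrix(0.5, 64, 64)),
               "registration failure")
})

test_that("colony coverage: blank, full and 30% synthetic plates", {
  white <- array(rep(c(0.97, 0.97, 0.95), each = 900), c(30, 30, 3))
  roi <- matrix(TRUE, 30, 30)
  expect_equal(colony_covered_fraction(white, roi)$covered_fraction, 0)
  blue <- array(rep(c(0.20, 0.25, 0.75), each = 900), c(30, 30, 3))
  expect_equal(colony_covered_fraction(blue, roi)$covered_fraction, 1)
  g <- gen_colony_image(7, target_fraction = 0.3)
  res <- colony_covered_fraction(g$image, g$roi)
  expect_lt(abs(res$covered_fraction - g$truth$covered_fraction), 0.005)
  expect_lt(abs(res$covered_fraction - 0.30), 0.01)
  expect_error(colony_covered_fraction(white, roi & FALSE), "empty ROI")
})

test_that("covered fraction is invariant under a joint rigid transform", {
  g <- gen_colony_image(19, target_fraction = 0.25)
  base <- colony_covered_fraction(g$image, g$roi)$covered_fraction
  moved <- transform_image(g$image, 4, c(-8, 5), fill = 0.97)
  roi_moved <- transform_image(g$roi * 1, 4, c(-8, 5), fill = 0) > 0.5
  after <- colony_covered_fraction(moved, roi_moved)$covered_fraction
  expect_lt(abs(after - base), 0.01)
})

test_that("cell index follows its defining formula", {
  s <- impedance_series(1:16, rep(20, 16), blank = 10, nominal = 15)
  expect_equal(cell_index(s), rep(2 / 3, 16))
  # CI == 0 when the well reads like the blank
  s0 <- impedance_series(1:16, rep(10, 16), blank = 10, nominal = 15)
  expect_true(all(cell_index(s0) == 0))
  # linear in Z at fixed blank/nominal
  z <- seq(10, 40, length.out = 16)
  s1 <- impedance_series(1:16, z, blank = 10, nominal = 15)
  s2 <- impedance_series(1:16, 2 * z - 10, blank = 10, nominal = 15)
  expect_equal(cell_index(s2), 2 * cell_index(s1))
  expect_error(impedance_series(1:16, z, 10, nominal = 0), "nominal")
})

test_that("CI normalisation anchors 1 at treatment and is scale invariant", {
  g <- gen_impedance(4, t_treat = 24)
  ci <- cell_index(g$series)
  nc <- normalize_ci(ci, g$series$times, 24)
  expect_equal(nc[g$series$times == 24], 1)
  expect_equal(normalize_ci(2 * ci, g$series$times, 24), nc)
  # joint rescaling of impedances and nominal leaves normalised CI alone
  s <- g$series
  s2 <- impedance_series(s$times, s$impedance * 3, s$blank * 3,
                         s$nominal * 3, s$matrigel, s$t_treat)
  expect_equal(normalize_ci(cell_index(s2), s2$times, 24), nc)
  # off-grid treatment time: linear interpolation of the anchor
  t_off <- 24.1                      # between 24.0 and 24.25 samples
  ref <- approx(s$times, ci, xout = t_off)$y
  expect_equal(normalize_ci(ci, s$times, t_off), ci / ref)
  expect_error(normalize_ci(ci, s$times, 1e4), "outside")
  expect_error(normalize_ci(ci * 0, s$times, 24), "zero")
  expect_equal(relative_invasiveness(s), nc)
})

test_that("track motility: straight, opposed and unbiased walks", {
  straight <- cell_track("a", 0:6, (0:6) * 10, rep(0, 7))
  m1 <- track_motility(list(straight))
  expect_equal(m1$speeds$speed, 10)
  expect_equal(m1$summary_vector, c(1, 0))
  opposed <- list(straight,
                  cell_track("b", 0:6, -(0:6) * 10, rep(0, 7)))
  m2 <- track_motility(opposed)
  expect_equal(m2$summary_vector, c(0, 0))
  g <- gen_tracks(3, n_cells = 100, bias = 0)
  m3 <- track_motility(g$tracks)
  expect_lt(m3$summary_magnitude, 0.1)
  expect_equal(m3$speeds$speed, g$truth$speed)   # realized speed by construction
  expect_error(track_motility(list(cell_track("c", c(0, 0.1), 0:1, 0:1),
                                   cell_track("d", c(0, -1), 0:1, 0:1))))
})

test_that("summary vector is bounded by 1 and the rose conserves weight", {
  set.seed(90)
  for (i in 1:20) {
    tracks <- lapply(seq_len(sample(1:6, 1)), function(j) {
      n <- sample(3:12, 1)
      cell_track(paste0("t", j), cumsum(runif(n, 0.1, 1)),
                 cumsum(rnorm(n, 0, 5)), cumsum(rnorm(n, 0, 5)))
    })
    m <- track_motility(tracks)
    expect_lte(m$summary_magnitude, 1 + 1e-12)
    # conservation: bin masses sum to the total speed-weighted step mass
    tot <- sum(vapply(tracks, function(tr) {
      sum(sqrt(diff(tr$x)^2 + diff(tr$y)^2) / diff(tr$times))
    }, numeric(1)))
    expect_equal(sum(m$rose$weight), tot)
  }
})

test_that("wound closure aggregates paired fractions and flags widening", {
  st <- wound_open_fraction_stats(c(100, 80, 50), c(40, 80, 60),
                                  group = c("a", "a", "b"))
  expect_equal(st$wells$closure, c(60, 0, -10))
  expect_identical(st$wells$widened, c(FALSE, FALSE, TRUE))
  expect_equal(st$summary$mean[st$summary$group == "a"], 30)
  expect_error(wound_open_fraction_stats(c(10, 20), 30), "unpaired")
})
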