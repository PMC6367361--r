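# Stiffness-map assembly, height segmentation and per-cell extraction.

test_that("substrate-only maps fit to a uniform modulus image", {
  st <- afm_settings()
  set.seed(21)
  curves <- lapply(seq_len(36), function(i)
    simulate_force_curve(10000, tip_model(), z0 = 9, noise_sd = 0.02,
                         settings = st))
  fmap <- force_map(curves, shape = c(6, 6), extent_um = 15)
  smap <- build_stiffness_map(fmap)
  expect_true(all(smap$quality_image))
  expect_lt(sd(smap$E_image) / mean(smap$E_image), 0.05)
  # setpoint height = z of the terminal extend sample
  expect_equal(smap$setpoint_height_image[1, 1],
               max(fmap$curves[[1]]$z_extend))
})

test_that("an empty curve grid is rejected", {
  expect_error(force_map(list(), shape = c(0, 0)), "at least one")
})

test_that("two synthetic cells are segmented and their moduli recovered within 5%", {
  g <- gen_force_map(5, E_cells = c(700, 1200), shape = c(24, 24),
                     extent_um = 60)
  smap <- build_stiffness_map(g$map)
  # E means inside the *true* masks
  for (i in 1:2) {
    sel <- g$truth$masks == i & smap$quality_image
    expect_lt(abs(mean(smap$E_image[sel]) - g$truth$cells$E[i]) /
                g$truth$cells$E[i], 0.05)
  }
  mask <- segment_height_map(map_topography(smap))
  expect_identical(max(mask), 2L)
  rec <- extract_cell_mechanics(smap, mask)
  hit <- match_labels(mask, g$truth$masks)
  for (l in rec$label) {
    E_true <- g$truth$cells$E[hit[l]]
    expect_lt(abs(rec$mean_E[rec$label == l] - E_true) / E_true, 0.05)
  }
})

test_that("height segmentation: separated bumps, flat images, touching bumps", {
  n <- 60
  xs <- matrix(rep(1:n, each = n), n, n); ys <- matrix(rep(1:n, n), n, n)
  bump <- function(cx, cy, h, s) h * exp(-((xs - cx)^2 + (ys - cy)^2) / (2 * s^2))
  # two well-separated bumps
  h2 <- bump(15, 15, 3, 5) + bump(45, 45, 3, 5)
  m <- segment_height_map(h2, sigma = 0)
  expect_identical(max(m), 2L)
  truth <- (bump(15, 15, 3, 5) > 0.5) + 2 * (bump(45, 45, 3, 5) > 0.5)
  hit <- match_labels(m, truth)
  for (l in 1:2) {
    tm <- truth == hit[l]
    expect_gt(sum(m == l & tm) / sum(tm), 0.9)
  }
  # flat image -> no cells, and that is not an error
  expect_identical(max(segment_height_map(matrix(1, 30, 30))), 0L)
  # touching bumps with distinct maxima split at the saddle
  h3 <- bump(24, 30, 3, 6) + bump(40, 30, 3, 6)
  m3 <- segment_height_map(h3, sigma = 0)
  expect_identical(max(m3), 2L)
  cen <- t(vapply(1:2, function(l) {
    ij <- which(unclass(m3) == l, arr.ind = TRUE); colMeans(ij)
  }, numeric(2)))
  expect_true(abs(diff(sort(cen[, 2])) ) > 8)  # split along the bump axis
})

test_that("manual corrections replay deterministically", {
  lab <- matrix(0L, 10, 10)
  lab[2:4, 2:4] <- 1L; lab[6:9, 6:9] <- 2L; lab[2:3, 7:9] <- 3L
  m <- apply_mask_edits(lab, list(
    list(op = "merge", labels = c(1, 3)),
    list(op = "split", label = 2, seeds = rbind(c(6, 6), c(9, 9))),
    list(op = "delete", label = 1)))
  expect_s3_class(m, "seg_mask")
  expect_identical(attr(m, "provenance"), "manually corrected")
  expect_identical(max(m), 2L)           # split halves, merged label deleted
  expect_true(all(m[2:4, 2:4] == 0L))
})

test_that("per-label means equal a brute-force pixel loop", {
  g <- gen_force_map(11, E_cells = 900, shape = c(10, 10), extent_um = 30,
                     cell_radius_um = 9)
  smap <- build_stiffness_map(g$map)
  lab <- g$truth$masks
  rec <- extract_cell_mechanics(smap, new_mask <- structure(
    lab, class = c("seg_mask", "matrix", "array"), provenance = "truth"))
  for (l in rec$label) {
    expect_equal(rec$mean_E[rec$label == l],
                 brute_label_mean(smap$E_image, lab, l, smap$quality_image))
    expect_equal(rec$mean_setpoint_height[rec$label == l],
                 brute_label_mean(smap$setpoint_height_image, lab, l,
                                  smap$quality_image))
  }
  # permuting label ids leaves the extracted statistics unchanged as a set
  lab2 <- lab; lab2[lab == 1] <- 2L
  lab2[lab == 2] <- 1L
  rec2 <- extract_cell_mechanics(smap, lab2)
  expect_setequal(round(rec2$mean_E, 9), round(rec$mean_E, 9))
})

test_that("constant and mixed fields extract exact means", {
  E <- matrix(997, 8, 8)
  E[5:8, ] <- 600; E[5:8, 5:8] <- 800
  smap <- structure(list(E_image = E, setpoint_height_image = E * 0 + 5,
                         quality_image = matrix(TRUE, 8, 8), pixel_size = 2),
                    class = "stiffness_map")
  lab <- matrix(0L, 8, 8); lab[1:4, ] <- 1L; lab[5:8, ] <- 2L
  rec <- extract_cell_mechanics(smap, lab)
  expect_identical(rec$mean_E, c(997, 700))
  expect_identical(rec$area, c(32 * 4, 32 * 4))
  # a label with no valid pixels is flagged and excluded
  q <- matrix(TRUE, 8, 8); q[5:8, ] <- FALSE
  smap$quality_image <- q
  rec2 <- extract_cell_mechanics(smap, lab)
  expect_false(rec2$valid[rec2$label == 2])
  expect_true(is.na(rec2$mean_E[rec2$label == 2]))
})

test_that("profile correlation matches its definition and rejects degenerate input", {
  h <- c(1, 2, 3, 5, 4, 2)
  expect_equal(profile_correlation(h, 2 * h + 5), 1)
  expect_equal(profile_correlation(h, -h), -1)
  set.seed(14)
  r <- profile_correlation(rnorm(64), rnorm(64))
  expect_lt(abs(r), 0.3)
  expect_error(profile_correlation(h, rep(1, 6)), "zero variance")
  expect_error(profile_correlation(h[1:2], h[1:2]))
})
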