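# circular hole mask on a pixel grid
circle_mask <- function(nr, nc, cx, cy, r_px) {
  xs <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  ys <- matrix(seq_len(nr), nr, nc)
  sqrt((xs - cx)^2 + (ys - cy)^2) <= r_px
}

test_that("ring labels follow distance geometry and the half-open convention", {
  mask <- circle_mask(901, 901, 451, 451, 200)   # 1 um/px, radius 200 um
  bins <- radial_bins(mask, um_per_pixel = 1, max_distance_um = 200)
  expect_identical(bins[451, 451 + 230], 0L)     # d = 30 um -> bin 0
  expect_identical(bins[451, 451 + 260], 1L)     # d = 60 um -> bin 1
  expect_identical(bins[451, 451], -1L)          # hole
  expect_identical(bins[451, 451 + 200 + 201], -2L)  # beyond max distance

  # single-pixel hole: a pixel exactly 50 um away falls in bin 1
  m1 <- matrix(FALSE, 120, 120)
  m1[60, 60] <- TRUE
  b1 <- radial_bins(m1, um_per_pixel = 1, max_distance_um = 100)
  expect_identical(b1[60, 110], 1L)
  expect_identical(b1[60, 109], 0L)

  expect_error(radial_bins(matrix(FALSE, 5, 5), 1), "empty")
  two <- matrix(FALSE, 20, 20); two[3, 3] <- TRUE; two[15, 15] <- TRUE
  expect_error(radial_bins(two, 1), "connected")
})

test_that("ring pixel counts match analytic annulus areas within 2%", {
  # 0.5 um/px keeps discretization error well below the tolerance
  mask <- circle_mask(1301, 1301, 651, 651, 200)  # radius 100 um at 0.5 um/px
  bins <- radial_bins(mask, um_per_pixel = 0.5, max_distance_um = 200)
  prof <- bin_intensity(matrix(1, 1301, 1301), bins)
  r0 <- 100
  for (k in prof$bin) {
    analytic <- pi * ((r0 + prof$outer_um[k + 1])^2 -
                        (r0 + prof$inner_um[k + 1])^2)
    measured <- prof$n_pixels[k + 1] * 0.5^2
    expect_lt(abs(measured / analytic - 1), 0.02)
  }
})

test_that("bin means are exact on uniform fields and ignore masked artifacts", {
  mask <- circle_mask(301, 301, 151, 151, 50)
  bins <- radial_bins(mask, um_per_pixel = 1, max_distance_um = 100)
  img <- matrix(1234, 301, 301)
  prof <- bin_intensity(img, bins)
  expect_true(all(prof$mean_intensity == 1234))

  art <- matrix(FALSE, 301, 301)
  art[140:160, 210:230] <- TRUE
  img_art <- img
  img_art[art] <- 65535
  prof_art <- bin_intensity(img_art, bins, artifact_mask = art)
  expect_equal(prof_art$mean_intensity, prof$mean_intensity)

  # pixel bookkeeping: bins + hole + beyond + nothing else = image
  expect_identical(sum(bins == -1L) + sum(bins == -2L) + sum(bins >= 0L),
                   length(bins))
})

test_that("ring means of a linear gradient match the annulus-averaged profile", {
  mask <- circle_mask(1301, 1301, 651, 651, 200)
  upp <- 0.5
  bins <- radial_bins(mask, um_per_pixel = upp, max_distance_um = 200)
  d <- attr(bins, "distance_um")
  img <- 100 + 3 * d                      # linear in distance from hole edge
  prof <- bin_intensity(img, bins)
  r0 <- 100
  for (k in prof$bin) {
    a <- r0 + prof$inner_um[k + 1]; b <- r0 + prof$outer_um[k + 1]
    # area-weighted mean of 100 + 3*(r - r0) over the annulus [a, b)
    mean_r <- 2 * (b^3 - a^3) / (3 * (b^2 - a^2))
    analytic <- 100 + 3 * (mean_r - r0)
    expect_lt(abs(prof$mean_intensity[k + 1] / analytic - 1), 0.01)
  }
})

test_that("normalization maps the background ring to the marker factor", {
  prof <- data.frame(bin = 0:12, inner_um = seq(0, 600, 50),
                     outer_um = seq(50, 650, 50),
                     mean_intensity = c(rep(2000, 12), 1000))
  gfap <- normalize_profile(prof, f = 1)
  expect_identical(gfap$normalized[13], 1)
  expect_equal(gfap$normalized[1], 2)
  cd68 <- normalize_profile(prof, f = 0)
  expect_identical(cd68$normalized[13], 0)
  expect_equal(cd68$normalized[1], 1)

  expect_identical(marker_factor("GFAP"), 1)
  expect_identical(marker_factor("NeuN"), 1)
  expect_identical(marker_factor("CD68"), 0)
  expect_identical(marker_factor("IgG"), 0)
  expect_error(marker_factor("DAPI"), "unknown")

  bad <- prof; bad$mean_intensity[13] <- 0
  expect_error(normalize_profile(bad, 1), "> 0")
})

test_that("neuron densities are per-area, normalized, and scale-covariant", {
  cfg <- histo_sim_config(shape = c(900, 900), um_per_pixel = 2,
                          hole = list(center_px = c(450, 450),
                                      radius_um = 150),
                          neuron_density_profile = function(d)
                            rep(800, length(d)),
                          seed = 9)
  out <- simulate_histology(cfg)
  bins <- radial_bins(out$hole_mask, 2)
  prof <- neuron_density(out$centroids, bins, 2)
  se <- sqrt(1 / prof$n_neurons + 1 / prof$n_neurons[13])
  expect_true(all(abs(prof$normalized - 1) <= 4 * se))

  expect_warning(
    empty <- neuron_density(data.frame(x_px = numeric(0), y_px = numeric(0)),
                            bins, 2), "zero")
  expect_true(all(empty$density_per_mm2 == 0))

  # with fixed pixel content, doubling the pixel pitch quadruples every
  # ring's physical area, so densities quarter and normalized values are
  # unchanged (halving the pitch quadruples densities symmetrically)
  p1 <- neuron_density(out$centroids, bins, 2)
  p2 <- neuron_density(out$centroids, bins, 4)
  expect_equal(p2$density_per_mm2, p1$density_per_mm2 / 4)
  expect_equal(p2$normalized, p1$normalized)
  p_half <- neuron_density(out$centroids, bins, 1)
  expect_equal(p_half$density_per_mm2, 4 * p1$density_per_mm2)
})

test_that("recovered profiles track the generator and are rotation-invariant", {
  profile_fn <- function(d) 800 + 1200 * exp(-d / 150)
  cfg <- histo_sim_config(shape = c(901, 901), um_per_pixel = 2,
                          hole = list(center_px = c(451, 451),
                                      radius_um = 150),
                          marker_profile = profile_fn, noise_sd = 0, seed = 2)
  out <- simulate_histology(cfg)
  bins <- radial_bins(out$hole_mask, 2)
  prof <- bin_intensity(out$image, bins)
  centers <- (prof$inner_um + prof$outer_um) / 2
  expect_gt(cor(prof$mean_intensity, profile_fn(centers)), 0.99)

  rot <- t(out$image)[ncol(out$image):1, ]           # 90-degree rotation
  rot_mask <- t(out$hole_mask)[ncol(out$hole_mask):1, ]
  prof_rot <- bin_intensity(rot, radial_bins(rot_mask, 2))
  expect_true(all(abs(prof_rot$mean_intensity / prof$mean_intensity - 1)
                  <= 0.01))
})
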