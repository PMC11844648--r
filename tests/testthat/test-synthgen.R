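test_that("degenerate config yields an all-zero recording and empty truth", {
  cfg <- ephys_sim_config(n_channels = 4, duration = 1, fs = 10000,
                          noise_sd = 0, band = NULL, seed = 1)
  sim <- simulate_recording(cfg)
  expect_true(all(sim$recording$voltages == 0))
  expect_length(sim$truth$units, 0)
  expect_length(sim$truth$artifacts, 0)
})

test_that("planted spike counts follow the Poisson law and are reproducible", {
  tpl <- spike_template(100, 10000)
  cfg <- ephys_sim_config(n_channels = 1, duration = 600, fs = 10000,
                          noise_sd = 0, band = NULL,
                          units = list(list(channel = 1, template = tpl,
                                            rate_hz = 5)), seed = 7)
  sim1 <- simulate_recording(cfg)
  sim2 <- simulate_recording(cfg)
  n <- length(sim1$truth$units[[1]]$spike_times)
  expect_lt(abs(n - 3000), 3 * sqrt(3000))          # Poisson count oracle
  expect_identical(sim1$truth$units[[1]]$spike_times,
                   sim2$truth$units[[1]]$spike_times)
  expect_identical(sim1$recording$voltages, sim2$recording$voltages)
  tt <- sim1$truth$units[[1]]$spike_times
  expect_true(all(diff(tt) > 0))
  expect_true(all(tt >= 0 & tt <= 600))
  expect_true(all(diff(tt) >= 1e-3 - 1e-9))         # refractory thinning
})

test_that("ground truth echoes the configured motion artifact channel set", {
  cfg <- ephys_sim_config(n_channels = 16, duration = 2, fs = 10000,
                          noise_sd = 0, band = NULL,
                          motion_artifacts = list(
                            list(time_s = 1, amplitude_uv = 300,
                                 n_channels = 15)), seed = 2)
  sim <- simulate_recording(cfg)
  expect_length(sim$truth$artifacts, 1)
  expect_length(sim$truth$artifacts[[1]]$channels, 15)
})

test_that("a template longer than the recording is rejected", {
  tpl <- spike_template(100, 10000, duration_ms = 300)
  cfg <- ephys_sim_config(n_channels = 1, duration = 0.2, fs = 10000,
                          noise_sd = 0, band = NULL,
                          units = list(list(channel = 1, template = tpl,
                                            rate_hz = 1)))
  expect_error(simulate_recording(cfg), "longer")
})

test_that("identical seeds give bit-identical noisy recordings", {
  cfg <- small_scene(seed = 11, n_channels = 2, duration = 2)
  expect_identical(simulate_recording(cfg)$recording$voltages,
                   simulate_recording(cfg)$recording$voltages)
  cfg2 <- small_scene(seed = 12, n_channels = 2, duration = 2)
  expect_false(identical(simulate_recording(cfg)$recording$voltages,
                         simulate_recording(cfg2)$recording$voltages))
})

test_that("flat-profile histology is constant outside the hole", {
  cfg <- histo_sim_config(shape = c(200, 200), um_per_pixel = 2,
                          hole = list(center_px = c(100, 100),
                                      radius_um = 50),
                          marker_profile = function(d) rep(1000, length(d)),
                          hole_fill = 7, noise_sd = 0, seed = 1)
  out <- simulate_histology(cfg)
  expect_true(all(out$image[!out$hole_mask] == 1000))
  expect_true(all(out$image[out$hole_mask] == 7))
})

test_that("neuron point process matches its configured density", {
  cfg <- histo_sim_config(shape = c(1000, 1000), um_per_pixel = 2,
                          hole = list(center_px = c(500, 500),
                                      radius_um = 20),
                          neuron_density_profile = function(d)
                            rep(500, length(d)),
                          seed = 5)
  out <- simulate_histology(cfg)
  # 2 mm x 2 mm field at 500 / mm^2 => ~2000 centroids (hole area ~ 0.001 mm^2)
  expect_lt(abs(nrow(out$centroids) - 2000), 4 * sqrt(2000))
  cfg0 <- histo_sim_config(shape = c(200, 200), um_per_pixel = 2,
                           hole = list(center_px = c(100, 100),
                                       radius_um = 20),
                           neuron_density_profile = function(d)
                             rep(0, length(d)))
  expect_identical(nrow(simulate_histology(cfg0)$centroids), 0L)
})

test_that("a hole touching the border is rejected", {
  expect_error(histo_sim_config(shape = c(100, 100), um_per_pixel = 1,
                                hole = list(center_px = c(10, 50),
                                            radius_um = 20)),
               "inside")
})

test_that("release simulation respects trivial and arithmetic cases", {
  cfg0 <- release_sim_config(release_fn = function(t) rep(0, length(t)),
                             sample_times = c(1, 2, 3))
  expect_true(all(simulate_release(cfg0)$conc_mg_per_ml == 0))

  cfg1 <- release_sim_config(release_fn = function(t) 0.5 * (t > 0),
                             loaded_mass = 4, sample_times = 1,
                             measurement_cv = 0)
  expect_equal(simulate_release(cfg1)$conc_mg_per_ml, 2 / 14)

  expect_error(release_sim_config(sample_times = c(-1, 2)), ">= 0")
  expect_error(release_sim_config(sample_times = c(2, 1)), "increasing")
  expect_error(release_sim_config(v_aliquot = 20), "exceed")
})

test_that("release simulation conserves mass at every step", {
  cfg <- release_sim_config(measurement_cv = 0, seed = 3)
  ser <- simulate_release(cfg)
  f <- attr(ser, "released_fraction")
  conc <- attr(ser, "true_conc")
  removed <- cumsum(conc * attr(ser, "v_aliquot"))
  reservoir <- conc * attr(ser, "v_reservoir")
  unreleased <- attr(ser, "loaded_mass") * (1 - f)
  total <- reservoir + c(0, removed[-length(removed)]) + unreleased +
    conc * 0  # aliquot at t_i removed after measuring C_i
  expect_equal(total, rep(attr(ser, "loaded_mass"), length(f)),
               tolerance = 1e-12)
})

test_that("default biexponential release hits its burst and plateau anchors", {
  f <- biexp_release()
  expect_equal(f(0), 0, tolerance = 1e-12)
  expect_equal(f(24), 0.65, tolerance = 0.005)
  expect_equal(f(576), 0.98, tolerance = 0.005)
  tt <- seq(0, 600, by = 1)
  expect_true(all(diff(f(tt)) >= 0))
})
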