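test_that("common median reference removes shared signals and keeps deviants", {
  fs <- 1000
  s <- sin(2 * pi * 7 * (1:500) / fs) * 50
  rec <- recording(matrix(rep(s, each = 16), nrow = 16), fs)
  out <- common_median_reference(rec)
  expect_true(all(abs(out$voltages) < 1e-12))

  v <- matrix(0, 16, 100)
  v[3, 40] <- 10
  out <- common_median_reference(recording(v, fs))
  expect_equal(out$voltages[3, 40], 10)
  expect_true(all(out$voltages[-3, ] == 0))

  expect_error(common_median_reference(recording(matrix(1, 1, 10), fs)),
               ">= 2 channels")
})

test_that("referencing matches a brute-force per-column median and is idempotent", {
  set.seed(1)
  v <- matrix(rnorm(16 * 1000), 16, 1000)
  rec <- recording(v, 1000)
  out <- common_median_reference(rec)
  oracle <- sweep(v, 2, apply(v, 2, median), `-`)   # brute-force recount
  expect_equal(out$voltages, oracle, tolerance = 1e-12)
  expect_true(max(abs(apply(out$voltages, 2, median))) < 1e-12)
  twice <- common_median_reference(out)
  expect_equal(twice$voltages, out$voltages, tolerance = 1e-12)
})

test_that("band-pass rejects DC and 60 Hz, passes 1 kHz, and is linear", {
  fs <- 24414
  n <- fs * 2
  t <- (1:n) / fs
  dc <- recording(matrix(100, 1, n), fs)
  out <- bandpass_filter(dc)$voltages[1, ]
  expect_lt(max(abs(out[(n / 4):(3 * n / 4)])), 1e-6 * 100)

  mid <- (n / 4):(3 * n / 4)
  s1k <- sin(2 * pi * 1000 * t)
  r1k <- bandpass_filter(recording(matrix(s1k * 50, 1, n), fs))$voltages[1, ]
  ratio <- max(abs(r1k[mid])) / 50
  expect_gt(ratio, 0.89)
  expect_lt(ratio, 1.12)

  s60 <- sin(2 * pi * 60 * t)
  r60 <- bandpass_filter(recording(matrix(s60 * 50, 1, n), fs))$voltages[1, ]
  expect_lt(max(abs(r60[mid])) / 50, 10^(-20 / 20))

  set.seed(2)
  a <- matrix(rnorm(n), 1, n); b <- matrix(rnorm(n), 1, n)
  fa <- bandpass_filter(recording(a, fs))$voltages
  fb <- bandpass_filter(recording(b, fs))$voltages
  fab <- bandpass_filter(recording(a + b, fs))$voltages
  expect_lt(max(abs(fab - fa - fb)) / max(abs(fab)), 1e-9)

  expect_error(bandpass_filter(recording(matrix(0, 1, 100), 1000),
                               c(300, 3000)), "Nyquist")
})

test_that("detection finds planted spikes and rejects an all-zero signal", {
  z <- recording(matrix(0, 2, 24414), 24414)
  expect_identical(nrow(detect_spikes(z)), 0L)

  # planted -80 uV biphasic peaks in sigma ~10 uV band-limited noise
  vpp80 <- 80 / 0.7                      # template negative peak = -80
  sc <- small_scene(seed = 21, n_channels = 2, duration = 30, vpp = vpp80,
                    rates = 5)
  sim <- simulate_recording(sc)
  ev <- detect_spikes(sim$recording)
  for (u in sim$truth$units) {
    dt <- ev$time_s[ev$channel == u$channel]
    near <- vapply(u$spike_times, function(t) min(abs(t - dt)), numeric(1))
    expect_gt(mean(near <= 2e-4), 0.97)  # matched within +/-0.2 ms
  }
  n_true <- sum(lengths(lapply(sim$truth$units, `[[`, "spike_times")))
  fp_rate <- (nrow(ev) - n_true) / 30 / 2
  expect_lt(fp_rate, 1)                  # false positives < 1/s/channel
})

test_that("sub-threshold spikes are mostly missed, matching window geometry", {
  vpp30 <- 30 / 0.7                      # negative peak -30 vs threshold ~-40
  sc <- small_scene(seed = 22, n_channels = 2, duration = 30, vpp = vpp30,
                    rates = 5)
  sim <- simulate_recording(sc)
  cfg <- detection_config()
  ev <- detect_spikes(sim$recording, cfg)
  lock <- round(1e-3 * 24414)
  frac_oracle <- frac_det <- numeric(0)
  for (u in sim$truth$units) {
    x <- sim$recording$voltages[u$channel, ]
    thr <- -cfg$k_sigma * robust_sigma(x)
    # oracle: a planted peak is detectable iff its local window dips below
    # the threshold (independent of crossing/lockout bookkeeping)
    pk <- round(u$spike_times * 24414) + 1
    dips <- vapply(pk, function(p)
      min(x[max(1, p - lock):min(length(x), p + lock)]) < thr, logical(1))
    frac_oracle <- c(frac_oracle, mean(dips))
    dt <- ev$time_s[ev$channel == u$channel]
    near <- vapply(u$spike_times, function(t)
      if (length(dt)) min(abs(t - dt)) else Inf, numeric(1))
    frac_det <- c(frac_det, mean(near <= 5e-4))
  }
  expect_lt(abs(mean(frac_det) - mean(frac_oracle)), 0.05)
  expect_lt(mean(frac_det), 2 * mean(frac_oracle) + 0.05)
})

test_that("detection count is non-increasing in the threshold multiplier", {
  sc <- small_scene(seed = 23, n_channels = 2, duration = 10, vpp = 120,
                    rates = 8)
  rec <- simulate_recording(sc)$recording
  counts <- vapply(c(3, 4, 5), function(k)
    nrow(detect_spikes(rec, detection_config(k_sigma = k))), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("amplitude and motion rules partition events as stated", {
  # one event at +600 uV -> abnormal amplitude
  ev <- make_events(channel = 1, time_s = 0.5, amplitude_uv = 600)
  out <- reject_artifacts(ev)
  expect_identical(nrow(out$removed_amplitude), 1L)
  expect_identical(nrow(out$kept), 0L)

  # synchronous events on 15 of 16 channels -> motion artifact
  ev15 <- make_events(channel = 1:15, time_s = rep(0.5, 15),
                      amplitude_uv = rep(-100, 15))
  out15 <- reject_artifacts(ev15)
  expect_identical(nrow(out15$removed_motion), 15L)
  expect_identical(nrow(out15$kept), 0L)

  # exactly 14 channels -> kept (strict inequality)
  ev14 <- make_events(channel = 1:14, time_s = rep(0.5, 14),
                      amplitude_uv = rep(-100, 14))
  out14 <- reject_artifacts(ev14)
  expect_identical(nrow(out14$kept), 14L)
  expect_identical(nrow(out14$removed_motion), 0L)

  # empty input -> three empty sets
  e0 <- make_events(integer(0), numeric(0), numeric(0),
                    waveforms = matrix(0, 0, 3))
  out0 <- reject_artifacts(e0)
  expect_identical(nrow(out0$kept) + nrow(out0$removed_amplitude) +
                     nrow(out0$removed_motion), 0L)
})

test_that("the artifact partition is exhaustive and disjoint", {
  set.seed(9)
  n <- 200L
  ev <- make_events(channel = sample(16, n, TRUE),
                    time_s = sort(runif(n, 0, 10)),
                    amplitude_uv = rnorm(n, -100, 150))
  out <- reject_artifacts(ev)
  expect_identical(nrow(out$kept) + nrow(out$removed_amplitude) +
                     nrow(out$removed_motion), n)
  keys <- function(e) paste(e$channel, e$peak_sample)
  all_keys <- c(keys(out$kept), keys(out$removed_amplitude),
                keys(out$removed_motion))
  expect_identical(sort(all_keys), sort(keys(ev)))
})

test_that("the amplitude rule inspects the whole snippet, not only the peak", {
  wf <- matrix(c(-100, -400, 550), 1, 3)   # peak below limit, tail above
  ev <- make_events(channel = 1, time_s = 0.5, amplitude_uv = -400,
                    waveforms = wf)
  expect_identical(nrow(reject_artifacts(ev)$removed_amplitude), 1L)
})

test_that("impedance QC applies inclusive 100 kOhm - 1 MOhm bounds", {
  expect_true(impedance_qc(rep(5e5, 16))$pass)
  expect_false(impedance_qc(c(5e4, rep(5e5, 15)))$pass)
  expect_true(impedance_qc(c(1e5, rep(5e5, 15)))$pass)   # inclusive boundary
  expect_true(impedance_qc(c(1e6, rep(5e5, 15)))$pass)
  expect_error(impedance_qc(c(-1, rep(5e5, 15))), "positive")
})
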