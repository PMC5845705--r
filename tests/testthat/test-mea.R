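# MEA module: referencing, filtering, spike detection, rasters, global rate.

test_that("median referencing zeroes the across-electrode median", {
  v <- matrix(c(1, 2, 4), nrow = 3, ncol = 5)
  rec <- voltage_recording(v, 10000, reference_index = 3)
  out <- median_reference(rec)
  expect_equal(out$voltages[, 1], c(-1, 0, 2))
  # identical signal on all electrodes -> all zero
  rec2 <- voltage_recording(matrix(rnorm(100), nrow = 4, ncol = 25,
                                   byrow = TRUE)[c(1, 1, 1, 1), ], 10000)
  expect_true(all(abs(median_reference(rec2)$voltages) < 1e-12))
  expect_error(median_reference(voltage_recording(matrix(0, 1, 10), 1000)),
               "at least 3")
})

test_that("median referencing is exactly shift-equivariant", {
  set.seed(1)
  v <- matrix(rnorm(5 * 200), nrow = 5)
  cm <- 100 * sin(2 * pi * 7 * seq_len(200) / 1000)
  a <- median_reference(voltage_recording(v, 1000))
  b <- median_reference(voltage_recording(sweep(v, 2, cm, "+"), 1000))
  expect_equal(a$voltages, b$voltages, tolerance = 1e-12)
})

test_that("band-pass rejects DC and stop-band, passes the spike band", {
  fs <- 10000
  t <- seq_len(2 * fs) / fs
  p <- mea_params()
  flt <- function(x) {
    rec <- bandpass_voltage(voltage_recording(rbind(x), fs), p)
    rec$voltages[1, ]
  }
  mid <- (fs / 2):(3 * fs / 2)  # avoid edges when measuring amplitude
  expect_lt(max(abs(flt(rep(50, length(t)))[mid])), 0.5)
  amp1k <- max(abs(flt(sin(2 * pi * 1000 * t))[mid]))
  expect_gte(amp1k, 0.9); expect_lte(amp1k, 1.0 + 1e-6)
  expect_lt(max(abs(flt(sin(2 * pi * 50 * t))[mid])), 0.1)
  expect_error(bandpass_voltage(voltage_recording(rbind(t), 5000), p),
               "Nyquist")
})

test_that("spike detector honours trivial cases and the dead time", {
  fs <- 10000
  p <- mea_params()
  zero <- voltage_recording(matrix(0, 3, fs), fs)
  st <- detect_spikes(zero, p)
  expect_true(all(lengths(st$times) == 0))
  expect_error(detect_spikes(voltage_recording(matrix(0, 3, 0), fs), p),
               "empty")
  # two crossings 1.0 ms apart on a noisy electrode: one spike kept
  set.seed(2)
  x <- rnorm(fs)  # 1 s, single window
  x[5000] <- 40; x[5010] <- 35
  st2 <- detect_spikes(voltage_recording(rbind(x, rnorm(fs), rnorm(fs)), fs), p)
  near <- st2$times[[1]][abs(st2$times[[1]] - 0.5) < 0.005]
  expect_length(near, 1)
  # cutout length matches the 1 + 2.2 ms span
  expect_equal(ncol(st2$cutouts[[1]]), round(0.001 * fs) + round(0.0022 * fs) + 1)
})

test_that("detected spike count is non-increasing in the threshold multiplier", {
  set.seed(3)
  fs <- 5000
  sch <- generate_event_schedule("synchronous", 20, 0.1, n_cells = 1, seed = 4)
  r <- render_mea_recording(sch, n_electrodes = 4, sampling_rate_hz = fs,
                            background_rate_hz = 1, seed = 5)
  rec <- bandpass_voltage(median_reference(r$recording),
                          mea_params(band_high_hz = 2000))
  counts <- vapply(3:8, function(m) {
    st <- detect_spikes(rec, mea_params(band_high_hz = 2000,
                                        threshold_multiplier = m))
    sum(lengths(st$times))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the robust noise-scale estimate recovers sigma on Gaussian noise", {
  set.seed(6)
  for (sigma in c(1, 3)) {
    x <- abs(rnorm(300000, sd = sigma))
    est <- calmea:::noise_scale(x, "quiroga")
    expect_lt(abs(est - sigma) / sigma, 0.05)
  }
})

test_that("rate raster conserves counts and maps grayscale as specified", {
  st <- structure(list(
    times = list(c(1.1, 1.2, 1.3, 1.4), numeric(0), c(0.5, 9.5)),
    cutouts = list(NULL, NULL, NULL),
    duration_s = 10, sampling_rate_hz = 10000, reference_index = 3,
    params = mea_params()), class = "spike_train")
  r <- spike_rate_raster(st, mea_params())
  expect_equal(r[1, 1], 2.0)             # 4 spikes in one 2-s bin
  expect_equal(sum(r[1, ]) * 2, 4)       # conservation
  expect_true(all(r[2, ] == 0))
  g <- raster_grayscale(r)
  expect_equal(g[1, 1], 0)               # 2 Hz clips to black
  expect_equal(g[2, 1], 1)               # 0 Hz is white
  expect_equal(raster_grayscale(matrix(0.25))[1, 1], 128 / 255)  # mid-gray (8-bit)
})

test_that("global rate pools electrodes minus the reference and normalizes", {
  times <- c(lapply(1:59, function(e) 5.0 + e * 0.01), list(numeric(0)))
  st <- structure(list(times = times, cutouts = NULL, duration_s = 60,
                       sampling_rate_hz = 10000, reference_index = 60,
                       params = mea_params()), class = "spike_train")
  g <- global_spike_rate(st, mea_params(normalize_global = FALSE))
  expect_equal(max(g$rate_hz), 5.9)      # 59 spikes in a 10-s window
  # empty train: zero trace
  st0 <- st; st0$times <- rep(list(numeric(0)), 60)
  g0 <- global_spike_rate(st0, mea_params())
  expect_true(all(g0$rate_hz == 0))
  # dense burst: normalized maximum of 1 at the burst window
  st2 <- st
  st2$times <- c(lapply(1:59, function(e) seq(30, 32, by = 0.2)), list(numeric(0)))
  g2 <- global_spike_rate(st2, mea_params())
  expect_equal(max(g2$value), 1)
  expect_equal(g2$time_s[which.max(g2$value)], 31, tolerance = 5)
})

test_that("voltage delimited IO round-trips", {
  set.seed(8)
  rec <- voltage_recording(matrix(rnorm(4 * 50), 4), 2500, reference_index = 2)
  f <- tempfile(fileext = ".tsv")
  write_voltage_delim(rec, f)
  back <- read_voltage_delim(f)
  expect_equal(back$voltages, rec$voltages, tolerance = 1e-6)
  expect_equal(back$sampling_rate_hz, 2500)
  expect_equal(back$reference_index, 2)
  unlink(f)
})
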