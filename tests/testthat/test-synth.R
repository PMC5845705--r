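# Synthetic-data generator: schedules, response classes, renderers.

test_that("protocol validation enforces ordering, agents and concentrations", {
  expect_s3_class(protocol_full_series(), "pharmacology_protocol")
  expect_error(pharmacology_protocol("TTX", 1, "uM", 0, 10), "unknown agent")
  expect_error(pharmacology_protocol(c("GABA", "Bic"), c(100, 10), c("uM", "uM"),
                                     c(0, 50), c(100, 150)), "non-overlapping")
  expect_error(pharmacology_protocol("GABA", -1, "uM", 0, 10))
})

test_that("zero-rate schedules are empty and unknown modes are rejected", {
  s <- generate_event_schedule("synchronous", duration_s = 600,
                               network_rate_hz = 0, per_cell_rate_hz = 0,
                               n_cells = 5, seed = 1)
  expect_length(s$network_events, 0)
  expect_true(all(lengths(s$cell_events) == 0))
  expect_error(generate_event_schedule("rhythmic", duration_s = 10), "arg")
})

test_that("network event count at 0.03 Hz over 600 s matches the expectation", {
  counts <- vapply(1:200, function(s)
    length(generate_event_schedule("synchronous", 600, 0.03,
                                   n_cells = 1, seed = s)$network_events),
    numeric(1))
  expect_gt(mean(counts), qpois(0.005, 18))
  expect_lt(mean(counts), qpois(0.995, 18))
  # and intervals live in the observed biological range
  iv <- diff(generate_event_schedule("synchronous", 6000, 0.03,
                                     n_cells = 1, seed = 3)$network_events)
  expect_gte(min(iv), 17.9)
  expect_lte(max(iv), 49.1)
})

test_that("asynchronous schedules show no lag-0 cross-correlation beyond chance", {
  s <- generate_event_schedule("asynchronous", 600, n_cells = 40,
                               per_cell_rate_hz = 0.02, seed = 11)
  bins <- seq(0, 600, by = 2)
  trains <- t(vapply(s$cell_events, function(ev)
    tabulate(findInterval(ev, bins), nbins = length(bins) - 1),
    numeric(length(bins) - 1)))
  mean_pair_cor <- function(tr) {
    cm <- suppressWarnings(cor(t(tr)))
    mean(cm[upper.tri(cm)], na.rm = TRUE)
  }
  obs <- mean_pair_cor(trains)
  set.seed(12)
  null <- vapply(1:200, function(k) {
    sh <- t(apply(trains, 1, function(r)
      r[(seq_along(r) + sample.int(length(r), 1)) %% length(r) + 1]))
    mean_pair_cor(sh)
  }, numeric(1))
  expect_gte(obs, quantile(null, 0.005))
  expect_lte(obs, quantile(null, 0.995))
})

test_that("synchronous per-cell events are jittered, thinned network events", {
  s <- generate_event_schedule("synchronous", 600, 0.03,
                               participation_prob = 0.7, jitter_s = 0.5,
                               n_cells = 30, seed = 21)
  for (i in seq_len(30)) {
    ev <- s$cell_events[[i]]
    src <- s$participation[[i]]
    expect_length(ev, length(src))
    if (length(ev)) expect_lte(max(abs(sort(ev) - sort(src))), 0.5)
  }
  # participation converges to the nominal probability across cells
  frac <- mean(lengths(s$cell_events)) / length(s$network_events)
  expect_lt(abs(frac - 0.7), 0.1)
})

test_that("response class assignment is multinomial, seeded and validated", {
  expect_error(assign_response_classes(10, c(0.5, 0.5, 0.2, -0.2)))
  expect_error(assign_response_classes(10, c(0.5, 0.5)), "one proportion")
  all_strong <- assign_response_classes(50, c(1, 0, 0, 0), seed = 1)
  expect_true(all(all_strong$class == "strongly_depolarized"))
  a <- assign_response_classes(1000, seed = 5)
  b <- assign_response_classes(1000, seed = 5)
  expect_identical(a, b)
  big <- assign_response_classes(10000, c(0.1, 0.2, 0.4, 0.3), seed = 9)
  emp <- as.numeric(table(factor(big$class,
                                 levels = response_class_defaults()$class)) / 10000)
  expect_true(all(abs(emp - c(0.1, 0.2, 0.4, 0.3)) < 0.02))
})

test_that("movie renderer obeys its degenerate contracts", {
  # zero cells: pure noise around the baseline
  gt0 <- synthetic_ground_truth(1, 48, 48, 60, seed = 1)
  gt0$n_cells <- 0
  gt0$centroids <- gt0$centroids[0, , drop = FALSE]
  gt0$brightness <- numeric(0)
  gt0$is_neuron <- logical(0)
  gt0$classes <- gt0$classes[0, ]
  gt0$schedule$cell_events <- list()
  m0 <- render_calcium_movie(gt0, noise_sd = 2, baseline_intensity = 100,
                             seed = 2)
  expect_lt(abs(mean(m0$data) - 100), 0.1)
  expect_lt(abs(sd(m0$data) - 2), 0.1)
  # one cell, no events, no noise: constant pixel trace
  gt1 <- synthetic_ground_truth(1, 48, 48, 60, seed = 3)
  gt1$schedule$cell_events[[1]] <- numeric(0)
  m1 <- render_calcium_movie(gt1, noise_sd = 0, seed = 4)
  px <- m1$data[round(gt1$centroids[1, 1]) + 1, round(gt1$centroids[1, 2]) + 1, ]
  expect_lt(diff(range(px)), 1e-9)
  # cells outside the frame are rejected
  gt_bad <- synthetic_ground_truth(1, 48, 48, 60, seed = 5)
  gt_bad$centroids[1, ] <- c(1, 1)
  expect_error(render_calcium_movie(gt_bad), "inside the frame")
})

test_that("a single transient peaks within one rise time of its event", {
  gt <- synthetic_ground_truth(1, 48, 48, 200, seed = 6)
  gt$schedule$cell_events[[1]] <- 100
  m <- render_calcium_movie(gt, noise_sd = 0, seed = 7)
  px <- m$data[round(gt$centroids[1, 1]) + 1, round(gt$centroids[1, 2]) + 1, ]
  t_max <- (which.max(px) - 1) * 0.5
  expect_gte(t_max, 100)
  expect_lte(t_max, 100 + gt$rise_s + 0.5)
})

test_that("rendered transients map one-to-one to ground-truth events", {
  gt <- synthetic_ground_truth(20, 96, 96, 300, seed = 8)
  tr <- render_cell_traces(gt, NULL, 0.5, seed = 9)
  rendered <- attr(tr, "events")
  for (i in seq_len(20))
    expect_identical(length(rendered[[i]]),
                     length(gt$schedule$cell_events[[i]]))
})

test_that("fixed seed gives bit-identical movie and voltage output", {
  a <- simulate_network_recording(seed = 42, n_cells = 6, baseline_s = 60,
                                  kplus_s = 15, washout_s = 15,
                                  width_px = 64, height_px = 64)
  b <- simulate_network_recording(seed = 42, n_cells = 6, baseline_s = 60,
                                  kplus_s = 15, washout_s = 15,
                                  width_px = 64, height_px = 64)
  expect_identical(a$movie$data, b$movie$data)
  sch <- generate_event_schedule("synchronous", 20, 0.05, n_cells = 1, seed = 1)
  r1 <- render_mea_recording(sch, n_electrodes = 4, sampling_rate_hz = 5000,
                             seed = 3)
  r2 <- render_mea_recording(sch, n_electrodes = 4, sampling_rate_hz = 5000,
                             seed = 3)
  expect_identical(r1$recording$voltages, r2$recording$voltages)
  expect_identical(r1$spike_times, r2$spike_times)
})

test_that("MEA renderer rejects an over-long template and carries true spikes", {
  sch <- generate_event_schedule("synchronous", 2, 0.5, n_cells = 1, seed = 2)
  expect_error(render_mea_recording(sch, n_electrodes = 4,
                                    sampling_rate_hz = 1000,
                                    spike_template = numeric(5000)),
               "longer than the recording")
  r <- render_mea_recording(sch, n_electrodes = 4, sampling_rate_hz = 5000,
                            background_rate_hz = 2, seed = 5)
  expect_length(r$spike_times, 4)
  expect_length(r$spike_times[[4]], 0)  # reference electrode is silent
})
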