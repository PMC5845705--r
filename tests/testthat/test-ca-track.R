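# Tracking: gated costs, optimal assignment, track filtering, traces.

test_that("cost matrix applies the distance rule and the gate", {
  prev <- cbind(row = c(0, 10), col = c(0, 0))
  new <- cbind(row = c(0, 10, 25), col = c(0, 0, 0))
  cm <- build_cost_matrix(prev, new, track_params())
  expect_equal(cm[1, 1], 0)
  expect_equal(cm[2, 2], 0)
  expect_equal(cm[1, 2], 10)     # distance 10 within gate
  expect_equal(cm[1, 3], 5000)   # distance 25 > 20 -> gating cost
  expect_equal(dim(build_cost_matrix(prev[0, , drop = FALSE], new)), c(0, 3))
})

test_that("assignment matches the documented 1x1 behaviour", {
  a1 <- assign_tracks(matrix(10, 1, 1))
  expect_equal(nrow(a1$matches), 1)
  a2 <- assign_tracks(matrix(5000, 1, 1))
  expect_equal(nrow(a2$matches), 0)
  expect_equal(a2$total_cost, 1000)
})

test_that("assignment equals the exhaustive optimum up to 6x6", {
  set.seed(4)
  p <- track_params()
  for (k in 1:40) {
    n <- sample(1:6, 1); m <- sample(1:6, 1)
    cm <- matrix(runif(n * m, 0, 1500), n, m)
    got <- assign_tracks(cm, p)$total_cost
    want <- brute_force_assignment_cost(cm, p$cost_non_assignment)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("track filtering applies the age and visibility rules", {
  mk_track <- function(first, visible_steps, n_steps) {
    tr <- list(id = 1L, first_step = first,
               centroids = matrix(NA_real_, n_steps, 2),
               regions = vector("list", n_steps),
               visible = logical(n_steps))
    tr$visible[visible_steps] <- TRUE
    tr
  }
  tl <- structure(list(tracks = list(
    mk_track(1, seq(1, 40, by = 4), 40),   # 10 of 40 visible -> removed
    mk_track(22, 22:40, 40),               # age 19 -> removed
    mk_track(1, 1:40, 40)),                # full visibility -> kept
    n_steps = 40), class = "cell_tracks")
  kept <- filter_tracks(tl, track_params())
  expect_length(kept$tracks, 1)
  expect_true(all(kept$tracks[[1]]$visible))
})

test_that("traces obey the normalization contract and count conservation", {
  set.seed(5)
  sim <- simulate_network_recording(seed = 9, n_cells = 8, baseline_s = 250,
                                    kplus_s = 15, washout_s = 35,
                                    width_px = 72, height_px = 72)
  segs <- segment_movie(sim$movie)
  tracks <- filter_tracks(track_cells(segs, track_params()),
                          track_params(min_track_age = 5))
  traces <- extract_traces(sim$movie, tracks, attr(segs, "blocks"))
  expect_equal(ncol(traces), length(tracks$tracks))   # conservation
  expect_true(all(apply(traces, 2, max) == 1))
  expect_true(all(traces >= 0))
  expect_equal(nrow(traces), dim(sim$movie$data)[3])
})

test_that("a constant-intensity cell yields an all-zero trace", {
  seg <- structure(list(
    labels = matrix(1L, 4, 4),
    centroids = data.frame(id = 1L, row = 1.5, col = 1.5, area_px = 16L),
    pixels = list(1:16)), class = "segmentation")
  tracks <- track_cells(list(seg, seg), track_params())
  arr <- array(7, dim = c(4, 4, 10))
  tr <- extract_traces(arr, tracks, data.frame(start = c(1, 6), end = c(5, 10)))
  expect_true(all(tr == 0))
})

test_that("drifting cells keep their identity across 40 steps", {
  sim <- simulate_network_recording(seed = 31, n_cells = 20,
                                    baseline_s = 960, kplus_s = 20,
                                    washout_s = 20,
                                    width_px = 128, height_px = 128,
                                    drift_max_px = 3)
  segs <- segment_movie(sim$movie)
  tracks <- filter_tracks(track_cells(segs, track_params()), track_params())
  # final-block truth positions vs final visible track centroids
  n_blocks <- dim(sim$movie$positions)[3]
  truth_end <- sim$movie$positions[, , n_blocks]
  ends <- t(vapply(tracks$tracks, function(tr) {
    s <- max(which(tr$visible)); tr$centroids[s, ]
  }, numeric(2)))
  d <- sqrt(outer(truth_end[, 1], ends[, 1], "-")^2 +
              outer(truth_end[, 2], ends[, 2], "-")^2)
  matched <- sum(apply(d, 1, min) <= 3)
  expect_gte(matched / 20, 0.95)
  expect_lte(length(tracks$tracks), 22)   # no runaway track fragmentation
})

test_that("synthetic transient trains survive extraction with high fidelity", {
  sim <- simulate_network_recording(seed = 13, n_cells = 10, baseline_s = 250,
                                    kplus_s = 15, washout_s = 35,
                                    width_px = 80, height_px = 80)
  segs <- segment_movie(sim$movie)
  tracks <- filter_tracks(track_cells(segs, track_params()),
                          track_params(min_track_age = 5))
  traces <- extract_traces(sim$movie, tracks, attr(segs, "blocks"))
  m <- match_tracks_to_cells(tracks, sim$ground_truth$centroids)
  expect_gte(nrow(m), 9)
  cors <- vapply(seq_len(nrow(m)), function(i)
    cor(traces[, m$track[i]], sim$movie$traces[, m$cell[i]]), numeric(1))
  expect_gte(median(cors), 0.9)
})
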