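# Trace analytics: QC, peak prominence, network trace, epoch metrics,
# GABA score, histograms.

mk_traces <- function(m, fi = 0.5) {
  attr(m, "frame_interval_s") <- fi
  m
}

test_that("QC removes noisy and inactive traces and keeps responders", {
  prot <- protocol_baseline_kplus(600, 30)
  nf <- (600 + 30 + 60) * 2
  t <- (seq_len(nf) - 1) * 0.5
  kfr <- epoch_frames(prot, "K+", 0.5, nf)
  flat <- rep(0, nf)
  noisy <- 0.5 + 0.2 * sin(2 * pi * 0.01 * t)
  quiet <- rep(0.1, nf); quiet[kfr] <- 0.4   # 0.3 step during K+
  tr <- mk_traces(cbind(flat, noisy, quiet))
  qc <- qc_filter(tr, prot)
  expect_equal(sort(qc$removed$trace), c(1, 2))
  expect_setequal(qc$removed$reason[qc$removed$trace == 2], "noisy")
  expect_setequal(qc$removed$reason[qc$removed$trace == 1], "inactive")
  expect_equal(ncol(qc$traces), 1)
  # the in-band sd of the 0.01 Hz sinusoid really is near amplitude/sqrt(2)
  bp <- butter_filter(noisy, c(0.0013, 0.02), 2, "pass", 2)
  expect_gt(sd(bp), 0.1)
  # missing K+ epoch: viability filter skipped with a warning
  prot0 <- pharmacology_protocol("baseline", 0, "", 0, 690)
  expect_warning(qc0 <- qc_filter(tr, prot0), "K\\+")
  expect_false(1 %in% qc0$removed$trace)
})

test_that("find_peaks matches trivial prominence geometry", {
  expect_equal(nrow(find_peaks(seq(0, 1, length.out = 50), 0.01)), 0)
  bump <- c(rep(0, 10), seq(0, 0.3, length.out = 6),
            seq(0.3, 0, length.out = 6)[-1], rep(0, 10))
  pk <- find_peaks(bump, 0.025)
  expect_equal(nrow(pk), 1)
  expect_equal(pk$prominence, 0.3)
  expect_equal(pk$height, 0.3)
  # two bumps of 0.3 and 0.04: threshold selects
  two <- c(bump, 0.04 * bump / 0.3)
  expect_equal(nrow(find_peaks(two, 0.025)), 2)
  expect_equal(nrow(find_peaks(two, 0.05)), 1)
})

test_that("find_peaks agrees with the quadratic prominence oracle", {
  set.seed(6)
  for (k in 1:100) {
    x <- cumsum(rnorm(sample(50:500, 1)))
    pk <- find_peaks(x, 0.4)
    or <- oracle_peak_prominences(x)
    or <- or[or$prominence >= 0.4, , drop = FALSE]
    if (is.null(or)) or <- data.frame(index = integer(0),
                                      prominence = numeric(0))
    expect_equal(pk$index, or$index)
    expect_equal(pk$prominence, or$prominence, tolerance = 1e-12)
  }
})

test_that("peak count is non-increasing in the prominence threshold", {
  set.seed(7)
  x <- cumsum(rnorm(400))
  counts <- vapply(seq(0.1, 2, by = 0.1),
                   function(mp) nrow(find_peaks(x, mp)), numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("peak widths are measured at half prominence", {
  # symmetric triangle, height 1 on zero baseline: width = half the base
  tri <- c(rep(0, 5), seq(0, 1, length.out = 11),
           seq(1, 0, length.out = 11)[-1], rep(0, 5))
  pk <- find_peaks(tri, 0.5, frame_interval_s = 1)
  expect_equal(pk$width_s, 10, tolerance = 0.1)
})

test_that("network trace normalizes, absorbs duplication, separates modes", {
  set.seed(8)
  prot <- NULL
  gt_s <- synthetic_ground_truth(50, 192, 192, 600, mode = "synchronous",
                                 seed = 9)
  gt_a <- synthetic_ground_truth(50, 192, 192, 600, mode = "asynchronous",
                                 seed = 9, per_cell_rate_hz = 0.024)
  tr_s <- apply(render_cell_traces(gt_s, NULL, 0.5, seed = 10), 2, minmax_scale)
  tr_a <- apply(render_cell_traces(gt_a, NULL, 0.5, seed = 10), 2, minmax_scale)
  nt_s <- network_trace(mk_traces(tr_s))
  nt_a <- network_trace(mk_traces(tr_a))
  expect_equal(max(nt_s), 1)
  # N identical traces give the same network trace as one
  one <- tr_s[, 1, drop = FALSE]
  many <- tr_s[, c(1, 1, 1, 1), drop = FALSE]
  expect_equal(as.numeric(network_trace(mk_traces(many))),
               as.numeric(network_trace(mk_traces(one))), tolerance = 1e-9)
  # synchrony reinforces in the (un-normalized) sum: asynchrony averages out
  raw_s <- network_trace(mk_traces(tr_s), normalize = FALSE)
  raw_a <- network_trace(mk_traces(tr_a), normalize = FALSE)
  p_s <- find_peaks(as.numeric(raw_s), 0.01, 0.5)
  p_a <- find_peaks(as.numeric(raw_a), 0.01, 0.5)
  expect_gt(max(p_s$prominence) / max(p_a$prominence), 2)
  expect_error(network_trace(matrix(numeric(0), 10, 0)), "at least one")
})

test_that("epoch metrics compute changes and flag empty epochs", {
  prot <- pharmacology_protocol(c("baseline", "GABA"), c(0, 100), c("", "uM"),
                                c(0, 300), c(300, 480))
  peaks <- data.frame(index = 1:5, time_s = c(0, 30, 60, 330, 400),
                      height = 1, prominence = c(0.2, 0.2, 0.2, 0.1, 0.1),
                      width_s = 5)
  em <- epoch_metrics(peaks, prot, "GABA")
  expect_equal(em$baseline$intervals, c(30, 30))
  expect_equal(em$baseline$median_interval_s, 30)
  expect_equal(em$prominence_change, -0.1)
  expect_equal(em$prominence_relative_change, -0.5)
  # epoch without peaks: flagged, changes undefined
  em0 <- epoch_metrics(peaks[1:3, ], prot, "GABA")
  expect_true(em0$flags[["no_epoch_peaks"]])
  expect_true(is.na(em0$prominence_change))
})

test_that("CBX analysis is restricted to the application tail", {
  prot <- pharmacology_protocol(c("baseline", "CBX"), c(0, 25), c("", "uM"),
                                c(0, 300), c(300, 540))
  peaks <- data.frame(index = 1:4, time_s = c(10, 100, 310, 500),
                      height = 1, prominence = c(0.2, 0.2, 0.9, 0.1),
                      width_s = 5)
  em <- epoch_metrics(peaks, prot, "CBX", params = trace_params(cbx_tail_s = 180))
  # the early-CBX peak (t=310, before the final 180 s) is excluded
  expect_equal(em$treatment$n_peaks, 1)
  expect_equal(em$treatment$median_prominence, 0.1)
})

test_that("the excitatory GABA score integrates the low-passed difference", {
  prot <- pharmacology_protocol(c("baseline", "GABA"), c(0, 100), c("", "uM"),
                                c(0, 180), c(180, 360))
  nf <- 720
  gfr <- epoch_frames(prot, "GABA", 0.5, nf)
  same <- rep(0.5, nf)
  expect_equal(gaba_excitatory_response(mk_traces(same), prot), 0,
               tolerance = 1e-9)
  step <- rep(0, nf); step[gfr] <- 0.2
  resp <- gaba_excitatory_response(mk_traces(step), prot)
  # ideal step integral = 0.2 * 360 samples = 72; the zero-phase low-pass
  # symmetrically smears ~2 of those units across the epoch boundary
  expect_gt(resp, 68)
  expect_lt(resp, 72.5)
  suppressed <- rep(0.1, nf); suppressed[gfr] <- 0
  expect_lt(gaba_excitatory_response(mk_traces(suppressed), prot), 0)
  expect_error(gaba_excitatory_response(mk_traces(same),
                                        protocol_baseline_kplus(60, 30)),
               "baseline and GABA")
})

test_that("response histograms total 100% with monotone cumulative sums", {
  h1 <- response_histograms(0.37, 0.05)
  expect_equal(sum(h1$pct), 100)
  expect_equal(max(h1$cum_pct), 100)
  set.seed(11)
  v <- runif(10000)
  h <- response_histograms(v, 0.05)
  expect_true(all(abs(h$pct[1:20] - 5) < 1))
  expect_true(all(diff(h$cum_pct) >= 0))
  expect_equal(h$cum_pct[length(h$cum_pct)], 100)
  hr <- response_histograms(v, 0.05, direction = "reverse")
  expect_equal(hr$cum_pct[1], 100)   # everything is >= the minimum bin edge
  expect_true(all(diff(hr$cum_pct) <= 0))
  expect_equal(nrow(response_histograms(numeric(0), 0.1)), 0)
})
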