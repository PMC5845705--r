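# Network statistics: classification, paired tests, correlation, report.

synthetic_cohort_traces <- function(mode, seed, n_cells = 40,
                                    duration_s = 600, ...) {
  gt <- synthetic_ground_truth(n_cells, 160, 160, duration_s, mode = mode,
                               seed = seed, ...)
  tr <- apply(render_cell_traces(gt, NULL, 0.5, seed = seed + 1000), 2,
              minmax_scale)
  attr(tr, "frame_interval_s") <- 0.5
  tr
}

classify_one <- function(mode, seed, ...) {
  tr <- synthetic_cohort_traces(mode, seed, ...)
  nt <- network_trace(tr)
  pk <- find_peaks(as.numeric(nt), 0.025, 0.5)
  classify_network(tr, pk)
}

test_that("generator modes are classified as generated (sampled seeds)", {
  for (s in c(101, 202, 303)) {
    expect_equal(classify_one("synchronous", s)$label, "synchronous")
    expect_equal(classify_one("asynchronous", s)$label, "asynchronous")
    expect_equal(classify_one("loosely_synchronous", s,
                              participation_prob = 0.4,
                              per_cell_rate_hz = 0.015)$label,
                 "loosely_synchronous")
  }
})

test_that("too few traces yield an undetermined label with diagnostics", {
  tr <- synthetic_cohort_traces("synchronous", 7)[, 1:5]
  attr(tr, "frame_interval_s") <- 0.5
  nt <- network_trace(tr)
  pk <- find_peaks(as.numeric(nt), 0.025, 0.5)
  cl <- classify_network(tr, pk)
  expect_equal(cl$label, "undetermined")
  expect_equal(cl$n_traces, 5)
})

test_that("Wilcoxon handles the documented example, zeros and symmetry", {
  before <- c(1, 2, 3, 4, 5, 6)
  after <- c(2, 4, 6, 8, 10, 12)
  w <- wilcoxon_signed_rank(before, after)
  expect_equal(w$p_value, 2 / 64)
  # swapping the vectors leaves the two-tailed p unchanged
  expect_equal(wilcoxon_signed_rank(after, before)$p_value, 2 / 64)
  z <- wilcoxon_signed_rank(1:5, 1:5)
  expect_true(z$all_zero)
  expect_true(is.na(z$p_value))
})

test_that("Wilcoxon p equals exhaustive sign-flip enumeration for n <= 10", {
  set.seed(12)
  for (k in 1:20) {
    n <- sample(4:10, 1)
    before <- rnorm(n)
    after <- before + rnorm(n, 0.3)
    got <- wilcoxon_signed_rank(before, after)$p_value
    want <- oracle_signed_rank_p(before, after)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("Pearson correlation covers the worked examples and degeneracy", {
  x <- c(1, 2, 3, 4)
  expect_equal(pearson_correlation(x, x)$r, 1)
  expect_equal(pearson_correlation(x, -2 * x + 3)$r, -1)
  p <- pearson_correlation(x, c(1, 3, 2, 4))
  expect_equal(p$r, 0.8)
  expect_false(p$degenerate)
  expect_true(pearson_correlation(x, rep(1, 4))$degenerate)
})

test_that("classification proportions round as printed summaries do", {
  labels <- c(rep("asynchronous", 7), rep("loosely_synchronous", 2))
  cc <- classification_counts(labels)
  expect_equal(cc$proportion_pct[cc$label == "asynchronous"], 78)
  expect_equal(cc$proportion_pct[cc$label == "loosely_synchronous"], 22)
  # 7 async of 9 networks, mirrored as a cohort report
  nets <- lapply(labels, function(l) list(label = l))
  rep_ <- build_report(nets)
  expect_equal(sum(rep_$classification$count), 9)
  # two networks, one of each: 50/50
  cc2 <- classification_counts(c("synchronous", "asynchronous"))
  expect_true(all(cc2$proportion_pct == 50))
})

test_that("ROI bookkeeping totals match the printed per-week counts", {
  counts <- read.table(system.file("extdata", "roi_counts.tsv",
                                   package = "calmea"),
                       header = TRUE, sep = "\t")
  tot <- roi_count_totals(counts)
  expect_equal(unname(tot["analyzed_rois"]), 9782)
  expect_equal(unname(tot["synchronous_rois"]), 2574)
  expect_equal(unname(tot["analyzed_networks"]), 17)
})

test_that("report assembles GABA curves and epoch metric tables", {
  prot <- pharmacology_protocol(c("baseline", "GABA"), c(0, 100), c("", "uM"),
                                c(0, 300), c(300, 480))
  peaks <- data.frame(index = 1:4, time_s = c(10, 50, 320, 420), height = 1,
                      prominence = c(0.2, 0.3, 0.1, 0.1), width_s = 4)
  nets <- list(
    list(label = "synchronous", timepoint = 3,
         gaba_responses = rnorm(50),
         epoch_metrics = list(epoch_metrics(peaks, prot, "GABA")),
         response_map = data.frame(row = 1:3, col = 1:3, response = 1:3)),
    list(label = "asynchronous", timepoint = 3, gaba_responses = rnorm(30)))
  rp <- build_report(nets)
  expect_equal(sum(rp$classification$count), 2)
  expect_equal(max(rp$gaba_reverse_cumulative$cum_pct), 100)
  expect_equal(nrow(rp$epoch_metrics), 1)
  expect_equal(rp$epoch_metrics$prominence_change, -0.15)
  expect_equal(nrow(rp$response_maps), 3)
})

test_that("classification agrees with the generating mode over 20 seeds", {
  agree <- function(mode, ...) {
    mean(vapply(1:20, function(s) {
      gt <- synthetic_ground_truth(30, 160, 160, 500, mode = mode,
                                   seed = 7000 + s, ...)
      tr <- apply(render_cell_traces(gt, NULL, 0.5, seed = 8000 + s), 2,
                  minmax_scale)
      attr(tr, "frame_interval_s") <- 0.5
      nt <- network_trace(tr)
      pk <- find_peaks(as.numeric(nt), 0.025, 0.5)
      classify_network(tr, pk)$label == mode
    }, logical(1)))
  }
  expect_gte(agree("synchronous"), 0.9)
  expect_gte(agree("asynchronous"), 0.9)
})
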