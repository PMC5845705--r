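# Trace-level analysis: quality control, activity-peak detection by
# topographic prominence, the summed network trace, pharmacological epoch
# metrics, the excitatory-GABA score and response histograms.

#' Trace analysis parameters
#'
#' @param qc_band quality-control band, Hz: traces whose band-passed
#'   version has sd above `qc_sd_max` are removed as noisy.
#' @param qc_sd_max sd threshold for the noise filter.
#' @param qc_scope where the in-band sd is evaluated: `"baseline"`
#'   (default) restricts it to the drug-free baseline epoch so that
#'   pharmacological responses — which quality control must not remove —
#'   do not masquerade as noise; `"full"` uses the whole trace.
#' @param kplus_min_rise minimum normalized fluorescence rise during the
#'   high-potassium epoch for a trace to count as a live neuron.
#' @param network_band band for single-trace filtering before the network
#'   sum, Hz.
#' @param peak_prominence_network,peak_prominence_single prominence
#'   criteria for network and single-cell activity peaks.
#' @param gaba_lowpass_hz low-pass cutoff for the excitatory-GABA score.
#' @param hist_bin_prominence,hist_bin_interval_s,hist_bin_change
#'   histogram bin widths for prominences, inter-peak intervals and
#'   relative changes.
#' @param cbx_tail_s length of the analysis window at the end of the CBX
#'   epoch (the blocker acts slowly; only the tail is analyzed).
#' @param gaba_reference_s common reference duration when epoch sums are
#'   duration-normalized.
#' @param filter_order Butterworth order per pass for all trace filters.
#' @return a `trace_params` list.
#' @export
trace_params <- function(qc_band = c(0.0013, 0.02), qc_sd_max = 0.05,
                         qc_scope = c("baseline", "full"),
                         kplus_min_rise = 0.10,
                         network_band = c(0.005, 0.2),
                         peak_prominence_network = 0.025,
                         peak_prominence_single = 0.025,
                         gaba_lowpass_hz = 0.024,
                         hist_bin_prominence = 0.005,
                         hist_bin_interval_s = 1,
                         hist_bin_change = 0.05,
                         cbx_tail_s = 180,
                         gaba_reference_s = 180,
                         filter_order = 2) {
  qc_scope <- match.arg(qc_scope)
  stopifnot(qc_band[1] < qc_band[2], network_band[1] < network_band[2],
            peak_prominence_network > 0, peak_prominence_single > 0)
  as.list(environment())
}

trace_frame_interval <- function(traces, frame_interval_s) {
  if (!is.null(frame_interval_s)) return(frame_interval_s)
  fi <- attr(traces, "frame_interval_s")
  if (is.null(fi)) stop("frame_interval_s not given and not attached to traces")
  fi
}

#' Quality-control filtering of traces
#'
#' Two removal rules on normalized traces: (1) traces whose
#' `qc_band`-band-passed version has sd above `qc_sd_max` are removed as
#' noisy; (2) traces whose normalized fluorescence rises less than
#' `kplus_min_rise` during the high-potassium epoch (mean during the
#' epoch minus the pre-epoch median) are removed as inactive or
#' non-neuronal. If the protocol has no K+ epoch the second filter is
#' skipped with a warning.
#'
#' @param traces matrix frames x cells, each column normalized to \[0, 1\].
#' @param protocol a [pharmacology_protocol()].
#' @param params a [trace_params()].
#' @param frame_interval_s frame interval, s (taken from the traces
#'   attribute when `NULL`).
#' @return list: `traces` (kept columns), `removed` (data frame `trace`,
#'   `reason`), `retention` (fraction kept).
#' @export
qc_filter <- function(traces, protocol, params = trace_params(),
                      frame_interval_s = NULL) {
  fi <- trace_frame_interval(traces, frame_interval_s)
  fs <- 1 / fi
  nf <- nrow(traces)
  nc <- ncol(traces)
  sd_frames <- seq_len(nf)
  if (identical(params$qc_scope, "baseline")) {
    bl <- epoch_frames(protocol, "baseline", fi, nf)
    if (length(bl) > 16) sd_frames <- bl
  }
  noisy <- logical(nc)
  for (j in seq_len(nc)) {
    bp <- butter_filter(traces[, j], params$qc_band, fs, type = "pass",
                        order = params$filter_order)
    noisy[j] <- sd(bp[sd_frames]) > params$qc_sd_max
  }
  inactive <- logical(nc)
  kfr <- epoch_frames(protocol, "K+", fi, nf)
  if (length(kfr) == 0) {
    warning("protocol has no K+ epoch: the viability filter was skipped")
  } else {
    pre <- seq_len(min(kfr) - 1)
    for (j in seq_len(nc)) {
      rise <- mean(traces[kfr, j]) - median(traces[pre, j])
      inactive[j] <- rise < params$kplus_min_rise
    }
  }
  reason <- ifelse(noisy, "noisy", ifelse(inactive, "inactive", NA))
  removed <- data.frame(trace = which(!is.na(reason)),
                        reason = reason[!is.na(reason)])
  kept <- traces[, is.na(reason), drop = FALSE]
  for (a in c("frame_interval_s", "protocol"))
    attr(kept, a) <- attr(traces, a)
  list(traces = kept, removed = removed,
       retention = ncol(kept) / max(1, nc))
}

#' Detect activity peaks by topographic prominence
#'
#' Local maxima (plateau centres) whose topographic prominence — height
#' above the higher of the two flanking minima separating the peak from
#' higher terrain (signal edges act as terrain ends) — reaches
#' `min_prominence`. Width is the full width at half prominence,
#' linearly interpolated.
#'
#' @param x numeric trace.
#' @param min_prominence minimum prominence.
#' @param frame_interval_s sampling interval, s (1 if `NULL`: sample units).
#' @return data frame: `index`, `time_s`, `height`, `prominence`,
#'   `width_s`.
#' @export
find_peaks <- function(x, min_prominence, frame_interval_s = NULL) {
  fi <- if (is.null(frame_interval_s)) 1 else frame_interval_s
  n <- length(x)
  stopifnot(all(is.finite(x)))
  empty <- data.frame(index = integer(0), time_s = numeric(0),
                      height = numeric(0), prominence = numeric(0),
                      width_s = numeric(0))
  if (n < 3) return(empty)
  # plateau-aware local maxima
  d <- diff(x)
  nz <- which(d != 0)
  if (length(nz) < 2) return(empty)
  peaks <- integer(0)
  for (k in seq_len(length(nz) - 1)) {
    if (d[nz[k]] > 0 && d[nz[k + 1]] < 0) {
      i0 <- nz[k] + 1          # first sample of plateau
      i1 <- nz[k + 1]          # last sample of plateau
      peaks <- c(peaks, (i0 + i1) %/% 2)
    }
  }
  if (!length(peaks)) return(empty)
  height <- x[peaks]
  prom <- numeric(length(peaks))
  lbase <- integer(length(peaks)); rbase <- integer(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]; h <- x[p]
    i <- p; lmin <- h; lpos <- p
    while (i > 1) {
      i <- i - 1
      if (x[i] > h) break
      if (x[i] < lmin) { lmin <- x[i]; lpos <- i }
    }
    i <- p; rmin <- h; rpos <- p
    while (i < n) {
      i <- i + 1
      if (x[i] > h) break
      if (x[i] < rmin) { rmin <- x[i]; rpos <- i }
    }
    prom[k] <- h - max(lmin, rmin)
    lbase[k] <- lpos; rbase[k] <- rpos
  }
  keep <- prom >= min_prominence
  peaks <- peaks[keep]; height <- height[keep]; prom <- prom[keep]
  lbase <- lbase[keep]; rbase <- rbase[keep]
  width <- numeric(length(peaks))
  for (k in seq_along(peaks)) {
    p <- peaks[k]
    ref <- height[k] - prom[k] / 2
    i <- p
    while (i > lbase[k] && x[i - 1] > ref) i <- i - 1
    left <- if (i == 1 || x[i] <= ref) i else
      i - (x[i] - ref) / (x[i] - x[i - 1])
    i <- p
    while (i < rbase[k] && x[i + 1] > ref) i <- i + 1
    right <- if (i == n || x[i] <= ref) i else
      i + (x[i] - ref) / (x[i] - x[i + 1])
    width[k] <- (right - left) * fi
  }
  data.frame(index = peaks, time_s = (peaks - 1) * fi,
             height = height, prominence = prom, width_s = width)
}

#' Summed network activity trace
#'
#' Each trace is band-pass filtered (`network_band`), min-max normalized,
#' summed across cells, and the sum is min-max normalized again, yielding
#' a network trace in \[0, 1\]. Synchronous transients reinforce in the
#' sum; asynchronous ones average out.
#'
#' @param traces matrix frames x cells.
#' @param params a [trace_params()].
#' @param frame_interval_s frame interval, s.
#' @param normalize min-max normalize the summed trace (default); with
#'   `FALSE` the raw sum of the filtered, per-trace-normalized traces is
#'   returned (useful when comparing absolute summed amplitudes between
#'   recordings).
#' @return numeric vector (length = frames) with attribute
#'   `frame_interval_s`.
#' @export
network_trace <- function(traces, params = trace_params(),
                          frame_interval_s = NULL, normalize = TRUE) {
  if (is.null(dim(traces))) traces <- matrix(traces, ncol = 1)
  if (ncol(traces) < 1) stop("need at least one trace")
  fi <- trace_frame_interval(traces, frame_interval_s)
  fs <- 1 / fi
  acc <- numeric(nrow(traces))
  for (j in seq_len(ncol(traces))) {
    bp <- butter_filter(traces[, j], params$network_band, fs, type = "pass",
                        order = params$filter_order)
    acc <- acc + minmax_scale(bp)
  }
  out <- if (normalize) minmax_scale(acc) else acc
  attr(out, "frame_interval_s") <- fi
  out
}

epoch_window <- function(protocol, label, params) {
  ep <- protocol_epoch(protocol, label)
  if (is.null(ep)) stop("epoch '", label, "' not present in the protocol")
  w <- c(ep$start_s, ep$end_s)
  if (label == "CBX" && !is.null(params$cbx_tail_s))
    w[1] <- max(w[1], w[2] - params$cbx_tail_s)
  w
}

#' Per-epoch peak metrics and change vs baseline
#'
#' Restricts detected peaks to the baseline and treatment epochs (for CBX
#' only the final `cbx_tail_s` of the application, where the slow-acting
#' blocker has taken effect), and summarizes median peak prominence and
#' median inter-peak interval, their change (epoch minus baseline) and
#' relative change (change / baseline). Epochs without peaks yield `NA`
#' metrics and are flagged.
#'
#' @param peaks a [find_peaks()] data frame (times in s).
#' @param protocol a [pharmacology_protocol()].
#' @param epoch_label treatment epoch agent name.
#' @param baseline_label baseline epoch agent name.
#' @param params a [trace_params()].
#' @return an `epoch_metrics` list.
#' @export
epoch_metrics <- function(peaks, protocol, epoch_label,
                          baseline_label = "baseline",
                          params = trace_params()) {
  win_b <- epoch_window(protocol, baseline_label, params)
  win_e <- epoch_window(protocol, epoch_label, params)
  pick <- function(w) peaks[peaks$time_s >= w[1] & peaks$time_s < w[2], ,
                            drop = FALSE]
  pb <- pick(win_b); pe <- pick(win_e)
  summarize <- function(p) {
    iv <- if (nrow(p) >= 2) diff(p$time_s) else numeric(0)
    list(n_peaks = nrow(p),
         median_prominence = if (nrow(p)) median(p$prominence) else NA_real_,
         intervals = iv,
         median_interval_s = if (length(iv)) median(iv) else NA_real_)
  }
  sb <- summarize(pb); se <- summarize(pe)
  chg <- function(b, e) {
    if (is.na(b) || is.na(e)) return(list(change = NA_real_, relative = NA_real_))
    list(change = e - b,
         relative = if (b != 0) (e - b) / b else NA_real_)
  }
  cp <- chg(sb$median_prominence, se$median_prominence)
  ci <- chg(sb$median_interval_s, se$median_interval_s)
  structure(list(epoch = epoch_label, baseline = sb, treatment = se,
                 prominence_change = cp$change,
                 prominence_relative_change = cp$relative,
                 interval_change_s = ci$change,
                 interval_relative_change = ci$relative,
                 flags = c(no_baseline_peaks = sb$n_peaks == 0,
                           no_epoch_peaks = se$n_peaks == 0)),
            class = "epoch_metrics")
}

#' Excitatory GABA response of one trace
#'
#' The trace is low-pass filtered at `gaba_lowpass_hz` and summed over the
#' baseline and GABA epochs; the difference (GABA minus baseline) is the
#' excitatory GABA response (positive = depolarizing, negative =
#' inhibitory). Because the two epochs can differ in length, each sum is
#' by default computed as the per-sample mean times a common reference
#' duration (`gaba_reference_s`); `duration_normalize = FALSE` gives raw
#' sums.
#'
#' @param trace numeric vector (one normalized trace).
#' @param protocol a [pharmacology_protocol()] containing baseline and
#'   GABA epochs.
#' @param params a [trace_params()].
#' @param frame_interval_s frame interval, s.
#' @param duration_normalize equalize epoch durations (default `TRUE`).
#' @return scalar response.
#' @export
gaba_excitatory_response <- function(trace, protocol, params = trace_params(),
                                     frame_interval_s = NULL,
                                     duration_normalize = TRUE) {
  fi <- trace_frame_interval(trace, frame_interval_s)
  fs <- 1 / fi
  nf <- length(trace)
  bfr <- epoch_frames(protocol, "baseline", fi, nf)
  gfr <- epoch_frames(protocol, "GABA", fi, nf)
  if (!length(bfr) || !length(gfr))
    stop("protocol must contain both baseline and GABA epochs")
  lp <- butter_filter(as.numeric(trace), params$gaba_lowpass_hz, fs,
                      type = "low", order = params$filter_order)
  if (duration_normalize) {
    ref_n <- params$gaba_reference_s * fs
    mean(lp[gfr]) * ref_n - mean(lp[bfr]) * ref_n
  } else {
    sum(lp[gfr]) - sum(lp[bfr])
  }
}

#' Histogram and (reverse-)cumulative sum of responses
#'
#' Counts are expressed as % of neurons; the cumulative sum rises to 100%
#' (or, for `direction = "reverse"`, starts at 100% — the fraction of
#' neurons with a value at or above each bin's left edge).
#'
#' @param values numeric vector.
#' @param bin_width bin width.
#' @param direction `"cumulative"` or `"reverse"`.
#' @return data frame: `bin_left`, `bin_mid`, `pct`, `cum_pct`.
#' @export
response_histograms <- function(values, bin_width,
                                direction = c("cumulative", "reverse")) {
  direction <- match.arg(direction)
  stopifnot(bin_width > 0)
  if (!length(values))
    return(data.frame(bin_left = numeric(0), bin_mid = numeric(0),
                      pct = numeric(0), cum_pct = numeric(0)))
  lo <- floor(min(values) / bin_width) * bin_width
  hi <- max(values) + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  cnt <- tabulate(findInterval(values, breaks), nbins = length(breaks) - 1)
  pct <- 100 * cnt / length(values)
  cum <- if (direction == "cumulative") cumsum(pct) else rev(cumsum(rev(pct)))
  data.frame(bin_left = breaks[-length(breaks)],
             bin_mid = breaks[-length(breaks)] + bin_width / 2,
             pct = pct, cum_pct = cum)
}
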