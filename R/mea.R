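# MEA processing: raw voltage -> referenced, filtered signal -> spike
# trains -> rate rasters and a global network rate ready for peak
# detection.

#' Standard 60-electrode layout
#'
#' 8x8 grid with the four corners absent (60 electrodes), 200 um pitch.
#'
#' @param pitch_um electrode pitch, micrometers.
#' @return data frame: `electrode`, `grid_row`, `grid_col`, `x_um`, `y_um`.
#' @export
mea_layout_8x8 <- function(pitch_um = 200) {
  g <- expand.grid(grid_row = 1:8, grid_col = 1:8)
  corner <- (g$grid_row %in% c(1, 8)) & (g$grid_col %in% c(1, 8))
  g <- g[!corner, ]
  g <- g[order(g$grid_col, g$grid_row), ]
  data.frame(electrode = seq_len(nrow(g)), grid_row = g$grid_row,
             grid_col = g$grid_col,
             x_um = (g$grid_col - 1) * pitch_um,
             y_um = (g$grid_row - 1) * pitch_um)
}

#' Multi-electrode voltage recording
#'
#' @param voltages matrix, electrodes x samples, microvolts.
#' @param sampling_rate_hz sampling rate, Hz.
#' @param layout electrode layout table (see [mea_layout_8x8()]).
#' @param reference_index electrode excluded from network summaries.
#' @return a `voltage_recording` object.
#' @export
voltage_recording <- function(voltages, sampling_rate_hz,
                              layout = NULL,
                              reference_index = nrow(voltages)) {
  stopifnot(is.matrix(voltages), sampling_rate_hz > 0)
  n <- nrow(voltages)
  if (is.null(layout) && n == 60) layout <- mea_layout_8x8()
  if (reference_index < 1 || reference_index > n)
    stop("reference_index out of range")
  structure(list(voltages = voltages, sampling_rate_hz = sampling_rate_hz,
                 layout = layout, reference_index = reference_index),
            class = "voltage_recording")
}

#' @export
print.voltage_recording <- function(x, ...) {
  cat(sprintf("voltage_recording: %d electrodes x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$voltages), ncol(x$voltages), x$sampling_rate_hz,
              ncol(x$voltages) / x$sampling_rate_hz))
  invisible(x)
}

#' MEA analysis parameters
#'
#' Defaults follow the published analysis settings: 200-3000 Hz band,
#' 30-s windows with 80% overlap, threshold at five times the robust
#' median-based noise estimate, 1.5 ms dead time, cutouts of 1 ms before
#' and 2.2 ms after the spike extremum, 2-s raster bins displayed on a
#' \[0, 0.5 Hz\] grayscale, a combined rate in 10-s bins with 80% overlap,
#' and network peak detection at prominence 0.05 on the normalized rate.
#'
#' @param band_low_hz,band_high_hz band-pass edges, Hz.
#' @param window_s detection window length, s.
#' @param window_overlap detection window overlap fraction.
#' @param threshold_multiplier threshold in units of the noise scale.
#' @param threshold_rule `"quiroga"` (sigma = median(|x|)/0.6745) or
#'   `"median"` (plain median(|x|)).
#' @param dead_time_s detector dead time, s.
#' @param cutout_pre_s,cutout_post_s cutout span around the extremum, s.
#' @param raster_bin_s raster bin width, s.
#' @param raster_scale_hz grayscale saturation range, Hz.
#' @param global_bin_s combined-rate window, s.
#' @param global_overlap combined-rate window overlap fraction.
#' @param network_peak_prominence prominence criterion on the (normalized)
#'   combined rate.
#' @param normalize_global min-max normalize the combined rate before peak
#'   detection (the prominence criterion is unitless).
#' @param filter_order Butterworth order per pass (zero-phase filtering).
#' @return a `mea_params` list.
#' @export
mea_params <- function(band_low_hz = 200, band_high_hz = 3000,
                       window_s = 30, window_overlap = 0.8,
                       threshold_multiplier = 5,
                       threshold_rule = c("quiroga", "median"),
                       dead_time_s = 1.5e-3,
                       cutout_pre_s = 1e-3, cutout_post_s = 2.2e-3,
                       raster_bin_s = 2, raster_scale_hz = c(0, 0.5),
                       global_bin_s = 10, global_overlap = 0.8,
                       network_peak_prominence = 0.05,
                       normalize_global = TRUE,
                       filter_order = 3) {
  threshold_rule <- match.arg(threshold_rule)
  stopifnot(band_low_hz < band_high_hz,
            window_overlap >= 0, window_overlap < 1,
            global_overlap >= 0, global_overlap < 1,
            window_s > 0, dead_time_s > 0)
  as.list(environment())
}

#' Median-reference a recording
#'
#' Subtracts, at every sample, the across-electrode median from each
#' electrode. Removes any common-mode waveform exactly (the median is
#' shift-equivariant); after referencing the across-electrode median is
#' zero everywhere.
#'
#' @param recording a [voltage_recording()].
#' @return the referenced recording.
#' @export
median_reference <- function(recording) {
  v <- recording$voltages
  if (nrow(v) < 3) stop("median referencing needs at least 3 electrodes")
  med <- cpp_col_median(v)
  recording$voltages <- cpp_subtract_col(v, med)
  recording
}

#' Band-pass filter a recording
#'
#' Zero-phase (forward-backward) Butterworth band-pass per electrode, so
#' spike times are not shifted.
#'
#' @param recording a [voltage_recording()].
#' @param params a [mea_params()].
#' @return the filtered recording.
#' @export
bandpass_voltage <- function(recording, params = mea_params()) {
  fs <- recording$sampling_rate_hz
  if (params$band_high_hz >= fs / 2)
    stop("band edge at or above Nyquist frequency")
  v <- recording$voltages
  for (e in seq_len(nrow(v)))
    v[e, ] <- butter_filter(v[e, ], c(params$band_low_hz, params$band_high_hz),
                            fs, type = "pass", order = params$filter_order)
  recording$voltages <- v
  recording
}

# robust per-window noise scale
noise_scale <- function(absx, rule) {
  m <- median(absx)
  if (rule == "quiroga") m / 0.6745 else m
}

#' Detect spikes with a windowed median-based threshold
#'
#' Per electrode, the recording is analyzed in overlapping windows
#' (default 30 s, 80% overlap). In each window the noise scale is
#' estimated from the median absolute voltage and crossings of
#' `threshold_multiplier` times that scale (both polarities) yield one
#' spike at the local extremum of each supra-threshold excursion.
#' Duplicates from overlapping windows are merged and a per-electrode
#' dead time is enforced (first detection kept). Each spike carries a
#' cutout spanning `cutout_pre_s` before to `cutout_post_s` after the
#' extremum.
#'
#' The recording is expected to be referenced and filtered already.
#'
#' @param recording a [voltage_recording()].
#' @param params a [mea_params()].
#' @return a `spike_train`: list with `times` (per-electrode spike time
#'   vectors, s), `cutouts` (per-electrode matrices, one row per spike),
#'   `duration_s`, `sampling_rate_hz`, `reference_index`, `params`.
#' @export
detect_spikes <- function(recording, params = mea_params()) {
  v <- recording$voltages
  fs <- recording$sampling_rate_hz
  n <- ncol(v)
  if (n == 0) stop("empty recording")
  win <- round(params$window_s * fs)
  step <- max(1L, round(win * (1 - params$window_overlap)))
  starts <- if (n <= win) 1L else unique(c(seq(1L, n - win + 1L, by = step),
                                           n - win + 1L))
  dead <- params$dead_time_s
  pre <- round(params$cutout_pre_s * fs)
  post <- round(params$cutout_post_s * fs)
  ne <- nrow(v)
  times <- vector("list", ne)
  cutouts <- vector("list", ne)
  for (e in seq_len(ne)) {
    x <- v[e, ]
    ax <- abs(x)
    cand <- integer(0)
    for (s0 in starts) {
      s1 <- min(n, s0 + win - 1L)
      seg <- ax[s0:s1]
      thr <- params$threshold_multiplier *
        noise_scale(seg, params$threshold_rule)
      above <- seg > thr
      if (!any(above)) next
      r <- rle(above)
      ends <- cumsum(r$lengths)
      begs <- ends - r$lengths + 1L
      runs <- which(r$values)
      ext <- vapply(runs, function(k) {
        i <- begs[k]:ends[k]
        i[which.max(seg[i])]
      }, integer(1))
      cand <- c(cand, s0 - 1L + ext)
    }
    cand <- sort(unique(cand))
    keep <- integer(0)
    last <- -Inf
    for (i in cand) {
      t_i <- (i - 1) / fs
      if (t_i - last >= dead) {
        keep <- c(keep, i)
        last <- t_i
      }
    }
    times[[e]] <- (keep - 1) / fs
    if (length(keep)) {
      co <- t(vapply(keep, function(i) {
        idx <- (i - pre):(i + post)
        out <- rep(NA_real_, length(idx))
        ok <- idx >= 1 & idx <= n
        out[ok] <- x[idx[ok]]
        out
      }, numeric(pre + post + 1)))
    } else {
      co <- matrix(numeric(0), nrow = 0, ncol = pre + post + 1)
    }
    cutouts[[e]] <- co
  }
  structure(list(times = times, cutouts = cutouts,
                 duration_s = n / fs, sampling_rate_hz = fs,
                 reference_index = recording$reference_index,
                 params = params),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("spike_train: %d electrodes, %d spikes over %.1f s\n",
              length(x$times), sum(lengths(x$times)), x$duration_s))
  invisible(x)
}

#' Per-electrode spike-rate raster
#'
#' Spike rate per electrode in fixed bins (default 2 s), as displayed on a
#' white-to-black grayscale saturating at the upper end of `raster_scale`.
#'
#' @param spiketrain a [detect_spikes()] result.
#' @param params a [mea_params()].
#' @return matrix electrodes x bins (Hz), with attributes `bin_s` and
#'   `time_s` (bin left edges).
#' @export
spike_rate_raster <- function(spiketrain, params = mea_params()) {
  bw <- params$raster_bin_s
  edges <- seq(0, spiketrain$duration_s + bw - 1e-9, by = bw)
  nb <- length(edges) - 1
  out <- matrix(0, nrow = length(spiketrain$times), ncol = nb)
  for (e in seq_along(spiketrain$times)) {
    t <- spiketrain$times[[e]]
    if (length(t)) {
      b <- findInterval(t, edges, rightmost.closed = FALSE)
      b <- b[b >= 1 & b <= nb]
      out[e, ] <- tabulate(b, nbins = nb) / bw
    }
  }
  attr(out, "bin_s") <- bw
  attr(out, "time_s") <- edges[-length(edges)]
  out
}

#' Grayscale mapping of a rate raster
#'
#' `value = round(255 * (1 - min(rate, hi) / hi)) / 255`, white at 0 Hz
#' and black at/above the saturation rate.
#'
#' @param raster a [spike_rate_raster()] matrix.
#' @param scale_hz saturation range, Hz.
#' @return matrix in \[0, 1\], same shape (1 = white).
#' @export
raster_grayscale <- function(raster, scale_hz = c(0, 0.5)) {
  hi <- scale_hz[2]
  round(255 * (1 - pmin(raster, hi) / hi)) / 255
}

#' Combined network spike rate
#'
#' Total spike rate over all electrodes except the reference, in sliding
#' windows (default 10 s stepping 2 s, i.e. 80% overlap). The trace is
#' min-max normalized to \[0, 1\] before peak detection by default, because
#' the prominence criterion is unitless.
#'
#' @param spiketrain a [detect_spikes()] result.
#' @param params a [mea_params()].
#' @return data frame: `time_s` (window centre), `rate_hz` (raw combined
#'   rate) and `value` (normalized if `params$normalize_global`).
#' @export
global_spike_rate <- function(spiketrain, params = mea_params()) {
  keep <- setdiff(seq_along(spiketrain$times), spiketrain$reference_index)
  allt <- sort(unlist(spiketrain$times[keep]))
  win <- params$global_bin_s
  step <- win * (1 - params$global_overlap)
  starts <- seq(0, max(0, spiketrain$duration_s - win), by = step)
  rate <- vapply(starts, function(s0)
    sum(allt >= s0 & allt < s0 + win) / win, numeric(1))
  value <- if (params$normalize_global) minmax_scale(rate) else rate
  data.frame(time_s = starts + win / 2, rate_hz = rate, value = value)
}

#' Export a rate raster as a grayscale PNG
#'
#' @param raster a [spike_rate_raster()] matrix.
#' @param path output file.
#' @param scale_hz grayscale saturation range, Hz.
#' @return `path`, invisibly.
#' @export
write_raster_png <- function(raster, path, scale_hz = c(0, 0.5)) {
  png::writePNG(raster_grayscale(raster, scale_hz), path)
  invisible(path)
}
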