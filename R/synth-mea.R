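# Synthetic extracellular voltage: template spikes in Gaussian noise,
# dense around scheduled network events, sparse Poisson background
# elsewhere, with an optional common-mode artifact added identically to
# all electrodes (perfusion/imaging interference).

#' Biphasic extracellular spike template
#'
#' A smooth negative-first biphasic waveform of the given duration, peak
#' (negative) amplitude normalized to 1.
#'
#' @param sampling_rate_hz sampling rate, Hz.
#' @param duration_ms template duration, ms.
#' @return numeric vector, `min == -1`.
#' @export
spike_template_biphasic <- function(sampling_rate_hz, duration_ms = 1) {
  n <- max(4L, round(sampling_rate_hz * duration_ms / 1000))
  tau <- seq(0, 1, length.out = n)
  w <- -sin(2 * pi * tau) * sin(pi * tau)
  w / abs(min(w))
}

#' Render a synthetic MEA voltage recording
#'
#' Inserts scaled spike templates at known times per electrode: around each
#' network event, `spikes_per_event_per_electrode` spikes (Poisson count)
#' spread with sd `event_spread_s`; plus a homogeneous Poisson background
#' at `background_rate_hz`. The reference electrode carries no spikes.
#' `common_mode` (a waveform of one sample per recording sample, or `NULL`)
#' is added identically to every electrode and is therefore removed exactly
#' by median referencing.
#'
#' @param schedule an [generate_event_schedule()] result (its
#'   `network_events` drive the event-locked spikes).
#' @param n_electrodes number of electrodes (default 60, 8x8 grid minus
#'   corners, one reference).
#' @param sampling_rate_hz sampling rate, Hz; must be at least 4x the
#'   template bandwidth (~ 1 / template duration).
#' @param spike_template waveform inserted per spike (peak normalized);
#'   default [spike_template_biphasic()] of 1 ms.
#' @param spike_amplitude_uv template scale in microvolts.
#' @param amplitude_jitter multiplicative amplitude range per spike.
#' @param spikes_per_event_per_electrode mean event-locked spikes.
#' @param event_spread_s temporal spread of event-locked spikes, s.
#' @param background_rate_hz background spike rate per electrode, Hz.
#' @param noise_sd noise standard deviation, microvolts.
#' @param common_mode numeric vector (length = samples) or `NULL`.
#' @param reference_index electrode excluded from spiking (ground).
#' @param seed integer seed.
#' @return list with `recording` (a [voltage_recording()]) and
#'   `spike_times` (list of true spike times per electrode, s).
#' @export
render_mea_recording <- function(schedule, n_electrodes = 60,
                                 sampling_rate_hz = 10000,
                                 spike_template = NULL,
                                 spike_amplitude_uv = 30,
                                 amplitude_jitter = c(0.9, 1.1),
                                 spikes_per_event_per_electrode = 10,
                                 event_spread_s = 0.3,
                                 background_rate_hz = 0.1,
                                 noise_sd = 3,
                                 common_mode = NULL,
                                 reference_index = n_electrodes,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  duration_s <- schedule$duration_s
  n_samples <- round(duration_s * sampling_rate_hz)
  if (is.null(spike_template))
    spike_template <- spike_template_biphasic(sampling_rate_hz)
  nk <- length(spike_template)
  if (nk > n_samples) stop("spike template longer than the recording")
  template_bandwidth_hz <- sampling_rate_hz / nk
  if (sampling_rate_hz < 4 * template_bandwidth_hz)
    stop("sampling rate must be >= 4x the template bandwidth")

  # fill noise row-by-row: avoids a second full-matrix allocation
  v <- matrix(0, nrow = n_electrodes, ncol = n_samples)
  for (e in seq_len(n_electrodes)) v[e, ] <- rnorm(n_samples, sd = noise_sd)
  spike_times <- vector("list", n_electrodes)
  events <- schedule$network_events
  for (e in seq_len(n_electrodes)) {
    if (e == reference_index) {
      spike_times[[e]] <- numeric(0)
      next
    }
    t_ev <- if (length(events)) {
      counts <- rpois(length(events), spikes_per_event_per_electrode)
      unlist(lapply(seq_along(events), function(j)
        rnorm(counts[j], mean = events[j], sd = event_spread_s)))
    } else numeric(0)
    n_bg <- rpois(1, background_rate_hz * duration_s)
    t_all <- sort(c(t_ev, runif(n_bg, 0, duration_s)))
    t_all <- t_all[t_all >= 0 & t_all <= duration_s - nk / sampling_rate_hz]
    if (length(t_all)) {
      amp <- spike_amplitude_uv *
        runif(length(t_all), amplitude_jitter[1], amplitude_jitter[2])
      i0 <- round(t_all * sampling_rate_hz) + 1
      for (j in seq_along(i0)) {
        idx <- i0[j]:(i0[j] + nk - 1)
        v[e, idx] <- v[e, idx] + amp[j] * spike_template
      }
      # ground truth time = template extremum, matching detector convention
      t_all <- (i0 - 1 + which.min(spike_template) - 1) / sampling_rate_hz
    }
    spike_times[[e]] <- t_all
  }
  if (!is.null(common_mode)) {
    if (length(common_mode) != n_samples)
      stop("common_mode must have one value per sample")
    v <- sweep(v, 2, common_mode, "+")
  }
  rec <- voltage_recording(v, sampling_rate_hz,
                           reference_index = reference_index)
  list(recording = rec, spike_times = spike_times)
}
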