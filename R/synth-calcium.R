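# Rendering of synthetic fluorescence recordings. Per-cell signal traces
# are built first (transient kernel + epoch responses); the movie painter
# then places them as Gaussian somata in a noisy field. Keeping the two
# stages separate lets tests check trace-level logic without paying for
# full movies.

#' Calcium transient kernel
#'
#' Linear rise to 1 over `rise_s`, then exponential decay with constant
#' `decay_s`. Kinetics are generator defaults (indicator kinetics are not
#' identifiable from network-level data); the defaults put network-trace
#' peak widths on the several-second scale seen in population calcium
#' signals.
#'
#' @param rise_s rise time, s.
#' @param decay_s decay constant, s.
#' @param frame_interval_s sampling interval, s.
#' @return numeric vector sampled at the frame interval, peak value 1.
#' @export
transient_kernel <- function(rise_s = 1, decay_s = 4, frame_interval_s = 0.5) {
  t <- seq(0, rise_s + 6 * decay_s, by = frame_interval_s)
  k <- ifelse(t < rise_s, t / rise_s, exp(-(t - rise_s) / decay_s))
  if (rise_s < frame_interval_s) k[1] <- 1  # instantaneous rise still peaks
  k
}

# first-order smoothed epoch indicator (perfusion wash-in/out, tau seconds)
smoothed_epoch <- function(n_frames, frames, frame_interval_s, tau_s = 5) {
  ind <- numeric(n_frames)
  ind[frames] <- 1
  a <- frame_interval_s / (tau_s + frame_interval_s)
  y <- numeric(n_frames)
  acc <- 0
  for (i in seq_len(n_frames)) {
    acc <- acc + a * (ind[i] - acc)
    y[i] <- acc
  }
  y
}

#' Render noise-free per-cell fluorescence traces
#'
#' Converts a ground truth into the clean per-cell signal (fraction of the
#' fluorescence saturation level) that the movie renderer paints:
#' resting level, one transient per scheduled event (amplitude drawn per
#' event), the class-specific baseline shift and participation thinning
#' during the GABA epoch, and the sustained high-potassium rise for
#' neurons. Cells flagged as non-neurons render flat (no events, no K+
#' response).
#'
#' @param ground_truth a [synthetic_ground_truth()].
#' @param protocol a [pharmacology_protocol()] or `NULL`.
#' @param frame_interval_s frame interval, s.
#' @param seed integer seed for event amplitudes and thinning.
#' @return matrix `n_frames x n_cells`; attribute `events` holds the
#'   per-cell event times actually rendered (after GABA thinning).
#' @export
render_cell_traces <- function(ground_truth, protocol = NULL,
                               frame_interval_s = 0.5, seed = NULL) {
  gt <- ground_truth
  if (!is.null(seed)) set.seed(seed)
  nf <- round(gt$duration_s / frame_interval_s)
  kern <- transient_kernel(gt$rise_s, gt$decay_s, frame_interval_s)
  nk <- length(kern)
  gaba_fr <- if (!is.null(protocol))
    epoch_frames(protocol, "GABA", frame_interval_s, nf) else integer(0)
  kplus_fr <- if (!is.null(protocol))
    epoch_frames(protocol, "K+", frame_interval_s, nf) else integer(0)
  gaba_env <- if (length(gaba_fr))
    smoothed_epoch(nf, gaba_fr, frame_interval_s) else NULL
  kplus_env <- if (length(kplus_fr))
    smoothed_epoch(nf, kplus_fr, frame_interval_s) else NULL
  gaba_t <- if (!is.null(protocol)) protocol_epoch(protocol, "GABA") else NULL

  traces <- matrix(gt$rest_level, nrow = nf, ncol = gt$n_cells)
  rendered_events <- vector("list", gt$n_cells)
  for (i in seq_len(gt$n_cells)) {
    ev <- gt$schedule$cell_events[[i]]
    if (!gt$is_neuron[i]) ev <- numeric(0)
    if (!is.null(gaba_t) && length(ev)) {
      mult <- gt$classes$participation_multiplier[i]
      in_gaba <- ev >= gaba_t$start_s & ev < gaba_t$end_s
      drop <- in_gaba & (runif(length(ev)) >= mult)
      ev <- ev[!drop]
    }
    ev <- ev[ev < gt$duration_s]
    rendered_events[[i]] <- ev
    if (length(ev)) {
      skew <- gt$event_amp_skew %||% 1
      amps <- gt$event_amp_range[1] +
        diff(gt$event_amp_range) * runif(length(ev))^skew
      for (j in seq_along(ev)) {
        i0 <- floor(ev[j] / frame_interval_s) + 1
        idx <- i0:min(nf, i0 + nk - 1)
        traces[idx, i] <- traces[idx, i] + amps[j] * kern[seq_along(idx)]
      }
    }
    if (gt$is_neuron[i]) {
      if (!is.null(gaba_env))
        traces[, i] <- traces[, i] + gt$classes$amplitude[i] * gaba_env
      if (!is.null(kplus_env))
        traces[, i] <- traces[, i] + gt$kplus_amplitude * kplus_env
    }
  }
  traces[traces < 0] <- 0
  attr(traces, "events") <- rendered_events
  attr(traces, "frame_interval_s") <- frame_interval_s
  traces
}

#' Render a synthetic fluorescence movie
#'
#' Paints each cell as a 2-D Gaussian soma (sigma = radius / 2) whose
#' brightness follows its clean signal trace, on a constant background with
#' i.i.d. Gaussian pixel noise. Optional slow drift moves cells in
#' piecewise-constant steps of `drift_max_px` per `block_frames`-frame
#' block, emulating stage/tissue drift at the segmentation cadence.
#'
#' @param ground_truth a [synthetic_ground_truth()].
#' @param protocol a [pharmacology_protocol()] or `NULL`.
#' @param frame_interval_s frame interval, s (default 0.5 s, i.e. 2 Hz).
#' @param noise_sd pixel noise standard deviation (counts).
#' @param baseline_intensity background level (counts).
#' @param drift_max_px maximum per-block centroid displacement, px.
#' @param block_frames frames per drift block.
#' @param seed integer seed (traces, noise and drift).
#' @return a `fluorescence_movie`: list with `data` (height x width x
#'   frames array, counts clipped to \[0, 65535\]), `frame_interval_s`,
#'   `protocol`, `positions` (per-block centroid paths) and `traces`
#'   (the clean per-cell signals used).
#' @export
render_calcium_movie <- function(ground_truth, protocol = NULL,
                                 frame_interval_s = 0.5, noise_sd = 2,
                                 baseline_intensity = 100,
                                 drift_max_px = 0, block_frames = 50,
                                 seed = NULL) {
  gt <- ground_truth
  if (!is.null(seed)) set.seed(seed)
  h <- gt$height_px; w <- gt$width_px
  nf <- round(gt$duration_s / frame_interval_s)
  sigma <- gt$radius_px / 2
  half <- ceiling(3 * sigma)
  if (any(gt$centroids[, "row"] < half | gt$centroids[, "row"] > h - 1 - half |
          gt$centroids[, "col"] < half | gt$centroids[, "col"] > w - 1 - half))
    stop("cells (incl. their 3-sigma support) must lie inside the frame")

  traces <- render_cell_traces(gt, protocol, frame_interval_s, seed = NULL)

  n_blocks <- ceiling(nf / block_frames)
  # per-block positions: random-walk drift, clamped to the valid area
  pos <- array(NA_real_, dim = c(gt$n_cells, 2, n_blocks))
  pos[, , 1] <- gt$centroids
  if (n_blocks > 1) {
    for (b in 2:n_blocks) {
      if (drift_max_px > 0) {
        ang <- runif(gt$n_cells, 0, 2 * pi)
        mag <- runif(gt$n_cells, 0, drift_max_px)
        pos[, 1, b] <- pmin(pmax(pos[, 1, b - 1] + mag * sin(ang), half), h - 1 - half)
        pos[, 2, b] <- pmin(pmax(pos[, 2, b - 1] + mag * cos(ang), half), w - 1 - half)
      } else {
        pos[, , b] <- pos[, , b - 1]
      }
    }
  }

  npix <- h * w
  movie <- matrix(rnorm(npix * nf, mean = baseline_intensity, sd = noise_sd),
                  nrow = npix, ncol = nf)
  off <- seq(-half, half)
  paint <- function(i, b, fr) {
    r0 <- round(pos[i, 1, b]); c0 <- round(pos[i, 2, b])
    rows <- r0 + off; cols <- c0 + off
    dr <- rows - pos[i, 1, b]; dc <- cols - pos[i, 2, b]
    wgt <- exp(-outer(dr^2, dc^2, "+") / (2 * sigma^2))
    pix <- rep(rows + 1, times = length(cols)) +
      rep(cols * h, each = length(rows))
    movie[pix, fr] <<- movie[pix, fr] +
      gt$brightness[i] * (as.vector(wgt) %o% traces[fr, i])
  }
  if (drift_max_px == 0) {
    for (i in seq_len(gt$n_cells)) paint(i, 1L, seq_len(nf))
  } else {
    for (b in seq_len(n_blocks)) {
      fr <- ((b - 1) * block_frames + 1):min(nf, b * block_frames)
      for (i in seq_len(gt$n_cells)) paint(i, b, fr)
    }
  }
  # clip to the 16-bit range only when it can actually be hit
  if (baseline_intensity - 8 * noise_sd < 0) movie[movie < 0] <- 0
  if (baseline_intensity + 8 * noise_sd +
      3 * max(c(0, gt$brightness)) > 65535)
    movie[movie > 65535] <- 65535
  dim(movie) <- c(h, w, nf)
  structure(list(data = movie, frame_interval_s = frame_interval_s,
                 protocol = protocol, positions = pos,
                 block_frames = block_frames,
                 traces = traces, ground_truth = gt),
            class = "fluorescence_movie")
}

#' @export
print.fluorescence_movie <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("fluorescence_movie: %d x %d px, %d frames @ %.2f s (%.1f s)\n",
              d[1], d[2], d[3], x$frame_interval_s, d[3] * x$frame_interval_s))
  invisible(x)
}
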