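# End-to-end drivers: movie -> traces -> QC, and the standard synthetic
# study conditions used throughout the analysis scripts and tests.

#' Analyze a fluorescence movie into QC-passed traces
#'
#' Runs the imaging half of the pipeline: block-averaged reference
#' images, marker-controlled watershed segmentation, gated Hungarian
#' tracking, trace extraction and quality control.
#'
#' @param movie a `fluorescence_movie`.
#' @param seg_pars a [seg_params()].
#' @param track_pars a [track_params()].
#' @param trace_pars a [trace_params()].
#' @return list: `traces` (QC-passed), `qc` (full [qc_filter()] result),
#'   `all_traces`, `tracks` (filtered), `segmentations`.
#' @export
analyze_movie <- function(movie, seg_pars = seg_params(),
                          track_pars = track_params(),
                          trace_pars = trace_params()) {
  segs <- segment_movie(movie, seg_pars)
  blocks <- attr(segs, "blocks")
  tracks <- track_cells(segs, track_pars)
  tracks <- filter_tracks(tracks, track_pars)
  traces <- extract_traces(movie, tracks, blocks)
  qc <- qc_filter(traces, movie$protocol, trace_pars)
  list(traces = qc$traces, qc = qc, all_traces = traces,
       tracks = tracks, segmentations = segs)
}

#' Default study-condition synthetic recording
#'
#' The standard synthetic movie used for pipeline verification: cells on
#' a jittered grid in a 192 x 192 px field at 2 Hz, a 20-min drug-free
#' baseline followed by a 30-s high-potassium epoch and a recorded
#' washout, default pixel noise, and a synchronous event schedule at
#' 0.03 Hz.
#'
#' @param seed integer seed.
#' @param n_cells number of cells.
#' @param mode activity mode.
#' @param baseline_s pre-K+ duration, s.
#' @param kplus_s K+ epoch duration, s.
#' @param washout_s recorded washout after the K+ application, s; the
#'   recording does not end on the elevated K+ plateau (sessions keep
#'   acquiring while the response decays), which also keeps the K+ step
#'   from dominating the low-frequency QC band at the trace edge.
#' @param width_px,height_px field size.
#' @param noise_sd pixel noise sd (counts).
#' @param non_neuron_fraction fraction of K+-unresponsive blobs.
#' @param drift_max_px per-block drift, px.
#' @param ... passed to [synthetic_ground_truth()].
#' @return list: `movie`, `ground_truth`, `protocol`.
#' @export
simulate_network_recording <- function(seed, n_cells = 200,
                                       mode = "synchronous",
                                       baseline_s = 1200, kplus_s = 30,
                                       washout_s = 120,
                                       width_px = 192, height_px = 192,
                                       noise_sd = 2,
                                       non_neuron_fraction = 0,
                                       drift_max_px = 0, ...) {
  protocol <- protocol_baseline_kplus(baseline_s, kplus_s)
  gt <- synthetic_ground_truth(
    n_cells = n_cells, width_px = width_px, height_px = height_px,
    duration_s = protocol_duration(protocol) + washout_s,
    mode = mode, seed = seed,
    non_neuron_fraction = non_neuron_fraction, ...)
  movie <- render_calcium_movie(gt, protocol, noise_sd = noise_sd,
                                drift_max_px = drift_max_px, seed = seed + 1L)
  list(movie = movie, ground_truth = gt, protocol = protocol)
}

#' QC retention on one default synthetic recording
#'
#' Generates a default recording ([simulate_network_recording()]),
#' extracts traces through the full imaging pipeline and applies both
#' quality-control filters; reports the retention.
#'
#' @param seed integer seed.
#' @param n_cells number of cells.
#' @param ... passed to [simulate_network_recording()].
#' @return list: `retention_pct`, `n_extracted`, `n_kept`, `removed`.
#' @export
synthetic_qc_retention <- function(seed, n_cells = 200, ...) {
  sim <- simulate_network_recording(seed, n_cells = n_cells, ...)
  res <- analyze_movie(sim$movie)
  list(retention_pct = 100 * res$qc$retention,
       n_extracted = ncol(res$all_traces),
       n_kept = ncol(res$traces),
       removed = res$qc$removed)
}

#' Match tracks to ground-truth cells
#'
#' Greedy nearest-centroid matching (each truth cell to the closest track
#' mean centroid within `max_dist_px`, one-to-one).
#'
#' @param tracks a `cell_tracks` object.
#' @param centroids matrix of true (row, col) centroids.
#' @param max_dist_px matching radius, px.
#' @return data frame: `cell`, `track`, `dist_px` (matched rows only).
#' @export
match_tracks_to_cells <- function(tracks, centroids, max_dist_px = 2) {
  tc <- t(vapply(tracks$tracks, function(tr)
    colMeans(tr$centroids[tr$visible, , drop = FALSE]), numeric(2)))
  if (!nrow(tc))
    return(data.frame(cell = integer(0), track = integer(0),
                      dist_px = numeric(0)))
  d <- sqrt(outer(centroids[, 1], tc[, 1], "-")^2 +
              outer(centroids[, 2], tc[, 2], "-")^2)
  out <- data.frame(cell = integer(0), track = integer(0), dist_px = numeric(0))
  used <- logical(nrow(tc))
  for (i in order(apply(d, 1, min))) {
    j <- which.min(ifelse(used, Inf, d[i, ]))
    if (length(j) && is.finite(d[i, j]) && d[i, j] <= max_dist_px) {
      out <- rbind(out, data.frame(cell = i, track = j, dist_px = d[i, j]))
      used[j] <- TRUE
    }
  }
  out
}
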