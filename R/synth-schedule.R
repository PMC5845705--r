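# Ground-truth generation: event schedules, pharmacological response
# classes and cell geometry. Everything downstream of these objects is
# deterministic given the seed, so rendered recordings can be checked
# against the schedule event-for-event.

#' Generate a network event schedule
#'
#' Builds the ground-truth event times that drive a synthetic recording.
#' Three activity modes mirror the patterns seen in developing cultures:
#'
#' * `synchronous`: network-wide events; each cell joins an event with
#'   probability `participation_prob`, jittered by at most `jitter_s`.
#' * `loosely_synchronous`: as above, plus independent per-cell events at
#'   `per_cell_rate_hz` (staggered, partial participation).
#' * `asynchronous`: independent per-cell events only, no common schedule.
#'
#' Network inter-event intervals are drawn, by default, uniformly on
#' `interval_spread / network_rate_hz`, so that at the default rate of
#' 0.03 Hz intervals span roughly 18-49 s while keeping the mean interval
#' at `1 / network_rate_hz`; `interval_model = "poisson"` switches to
#' exponential intervals.
#'
#' @param mode `"synchronous"`, `"loosely_synchronous"` or `"asynchronous"`.
#' @param duration_s recording duration, seconds (> 0).
#' @param network_rate_hz mean network event rate, Hz.
#' @param participation_prob probability a cell joins a network event.
#' @param jitter_s maximum per-cell jitter applied to joined events, s.
#' @param per_cell_rate_hz rate of independent per-cell events, Hz.
#' @param n_cells number of cells.
#' @param seed integer seed; fixed seed gives an identical schedule.
#' @param interval_model `"jittered"` (uniform renewal) or `"poisson"`.
#' @param interval_spread length-2 multiplier range for the uniform renewal
#'   intervals (relative to the mean interval).
#' @return an `event_schedule`: list with `mode`, `duration_s`,
#'   `network_events` (s), `cell_events` (list of per-cell event times, s)
#'   and the generating parameters.
#' @export
generate_event_schedule <- function(mode = c("synchronous", "loosely_synchronous",
                                             "asynchronous"),
                                    duration_s, network_rate_hz = 0.03,
                                    participation_prob = 0.8, jitter_s = 0.5,
                                    per_cell_rate_hz = 0.01, n_cells = 1,
                                    seed = NULL,
                                    interval_model = c("jittered", "poisson"),
                                    interval_spread = c(0.54, 1.46)) {
  mode <- match.arg(mode)
  interval_model <- match.arg(interval_model)
  if (duration_s <= 0) stop("duration_s must be positive")
  if (network_rate_hz < 0 || per_cell_rate_hz < 0) stop("rates must be >= 0")
  if (participation_prob < 0 || participation_prob > 1)
    stop("participation_prob must be in [0, 1]")
  if (!is.null(seed)) set.seed(seed)

  draw_renewal <- function(rate) {
    if (rate <= 0) return(numeric(0))
    mean_iv <- 1 / rate
    # draw enough intervals to cover the recording, then truncate
    n_draw <- ceiling(duration_s * rate * 2) + 10
    iv <- if (interval_model == "jittered")
      runif(n_draw, interval_spread[1] * mean_iv, interval_spread[2] * mean_iv)
    else stats::rexp(n_draw, rate)
    t <- cumsum(iv)
    t[t <= duration_s]
  }
  draw_poisson <- function(rate) {
    if (rate <= 0) return(numeric(0))
    n <- rpois(1, rate * duration_s)
    sort(runif(n, 0, duration_s))
  }

  network_events <- if (mode == "asynchronous") numeric(0) else
    draw_renewal(network_rate_hz)

  cell_events <- vector("list", n_cells)
  participation <- vector("list", n_cells)
  for (i in seq_len(n_cells)) {
    joined <- numeric(0)
    if (mode != "asynchronous" && length(network_events) > 0) {
      keep <- runif(length(network_events)) < participation_prob
      joined <- network_events[keep] +
        runif(sum(keep), -jitter_s, jitter_s)
      joined <- pmin(pmax(joined, 0), duration_s)
      participation[[i]] <- network_events[keep]
    } else {
      participation[[i]] <- numeric(0)
    }
    indep <- if (mode != "synchronous") draw_poisson(per_cell_rate_hz) else numeric(0)
    cell_events[[i]] <- sort(c(joined, indep))
  }

  structure(list(mode = mode, duration_s = duration_s,
                 network_events = network_events,
                 cell_events = cell_events,
                 participation = participation,
                 params = list(network_rate_hz = network_rate_hz,
                               participation_prob = participation_prob,
                               jitter_s = jitter_s,
                               per_cell_rate_hz = per_cell_rate_hz,
                               interval_model = interval_model,
                               interval_spread = interval_spread)),
            class = "event_schedule")
}

#' Response-class definitions
#'
#' Phenomenological per-cell responses to the GABA application epoch:
#' a signed baseline-fluorescence shift (fraction of the saturation level)
#' and a multiplier on event participation during the epoch. Amplitudes are
#' ordered strongly > weakly > 0 > inhibited.
#'
#' @return data frame with columns `class`, `amplitude`,
#'   `participation_multiplier`.
#' @export
response_class_defaults <- function() {
  data.frame(
    class = c("strongly_depolarized", "weakly_depolarized",
              "no_response", "inhibited"),
    amplitude = c(0.4, 0.15, 0, -0.1),
    participation_multiplier = c(0.5, 1, 1, 0),
    stringsAsFactors = FALSE)
}

#' Assign GABA response classes to cells
#'
#' Multinomial draw of per-cell response classes. Empirical proportions
#' converge to the nominal ones as `n_cells` grows; the same seed always
#' yields the same assignment.
#'
#' @param n_cells number of cells.
#' @param class_proportions numeric vector of length 4 summing to 1, in the
#'   order of [response_class_defaults()] (strongly depolarized, weakly
#'   depolarized, no response, inhibited).
#' @param seed integer seed.
#' @param classes class definition table (see [response_class_defaults()]).
#' @return data frame with one row per cell: `cell`, `class`, `amplitude`,
#'   `participation_multiplier`.
#' @export
assign_response_classes <- function(n_cells,
                                    class_proportions = c(0.05, 0.25, 0.40, 0.30),
                                    seed = NULL,
                                    classes = response_class_defaults()) {
  if (any(class_proportions < 0)) stop("class proportions must be non-negative")
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop("class proportions must sum to 1")
  if (length(class_proportions) != nrow(classes))
    stop("need one proportion per class")
  stopifnot(classes$amplitude[1] > classes$amplitude[2],
            classes$amplitude[2] > 0,
            classes$amplitude[classes$class == "inhibited"] < 0)
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(classes), n_cells, replace = TRUE,
                    prob = class_proportions)
  out <- classes[idx, , drop = FALSE]
  out <- cbind(cell = seq_len(n_cells), out)
  rownames(out) <- NULL
  out
}

#' Place cell centroids on a jittered grid
#'
#' Non-overlapping soma positions: a regular grid with spacing derived from
#' the field size, jittered by a fraction of the pitch. Guarantees at least
#' `2 * radius + 2` px between neighbouring centroids.
#'
#' @param n_cells number of cells.
#' @param width_px,height_px field size in pixels.
#' @param radius_px soma radius in pixels.
#' @param margin_px border kept free of centroids.
#' @param seed integer seed.
#' @return matrix `n_cells x 2` of (row, col) centroids, 0-based pixel
#'   centre coordinates.
#' @export
place_cells <- function(n_cells, width_px, height_px, radius_px = 4,
                        margin_px = radius_px + 4, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  usable_w <- width_px - 2 * margin_px
  usable_h <- height_px - 2 * margin_px
  k <- ceiling(sqrt(n_cells * usable_w / usable_h))
  krow <- ceiling(n_cells / k)
  pitch <- min(usable_w / k, usable_h / krow)
  min_sep <- 2 * radius_px + 2
  if (pitch < min_sep)
    stop("field too small to place ", n_cells, " non-overlapping cells")
  jit <- (pitch - min_sep) / 2
  grid <- expand.grid(r = seq_len(krow), c = seq_len(k))
  grid <- grid[seq_len(n_cells), , drop = FALSE]
  rows <- margin_px + (grid$r - 0.5) * (usable_h / krow) +
    runif(n_cells, -jit, jit)
  cols <- margin_px + (grid$c - 0.5) * (usable_w / k) +
    runif(n_cells, -jit, jit)
  cbind(row = rows, col = cols)
}

#' Build a complete synthetic ground truth
#'
#' Combines cell geometry, calcium kinetics, the event schedule and the
#' per-cell response classes into one object that both renderers consume
#' and that tests compare analysis output against.
#'
#' @param n_cells number of cells.
#' @param width_px,height_px field size, pixels.
#' @param duration_s recording duration, seconds.
#' @param mode activity mode, see [generate_event_schedule()].
#' @param seed integer seed controlling placement, schedule and classes.
#' @param radius_px soma radius, px.
#' @param rise_s,decay_s calcium transient kinetics: linear rise time and
#'   exponential decay constant, seconds.
#' @param rest_level resting fluorescence signal level (fraction of the
#'   saturation level).
#' @param event_amp_range per-event transient amplitude range (fraction of
#'   saturation).
#' @param event_amp_skew skew exponent of the per-event amplitude draw
#'   (`amp = min + (max - min) * U^skew`, U uniform): most transients are
#'   small relative to the largest one, which sets each trace's
#'   normalization maximum — the amplitude statistics real recordings show
#'   and the reason quality control retains nearly all traces.
#' @param kplus_amplitude sustained fluorescence rise during the K+ epoch
#'   (fraction of saturation) for responsive cells.
#' @param non_neuron_fraction fraction of blobs rendered without events or
#'   K+ response (exercises the viability filter).
#' @param class_proportions passed to [assign_response_classes()].
#' @param ... further arguments to [generate_event_schedule()].
#' @return a `synthetic_ground_truth` list.
#' @export
synthetic_ground_truth <- function(n_cells, width_px, height_px, duration_s,
                                   mode = "synchronous", seed = NULL,
                                   radius_px = 4, rise_s = 1, decay_s = 4,
                                   rest_level = 0.12,
                                   event_amp_range = c(0.05, 0.9),
                                   event_amp_skew = 6,
                                   kplus_amplitude = 0.3,
                                   non_neuron_fraction = 0,
                                   class_proportions = c(0.05, 0.25, 0.40, 0.30),
                                   ...) {
  if (!is.null(seed)) set.seed(seed)
  centroids <- place_cells(n_cells, width_px, height_px, radius_px)
  schedule <- generate_event_schedule(mode, duration_s = duration_s,
                                      n_cells = n_cells, seed = NULL, ...)
  classes <- assign_response_classes(n_cells, class_proportions, seed = NULL)
  is_neuron <- rep(TRUE, n_cells)
  if (non_neuron_fraction > 0) {
    n_nn <- round(non_neuron_fraction * n_cells)
    if (n_nn > 0) is_neuron[sample.int(n_cells, n_nn)] <- FALSE
  }
  brightness <- runif(n_cells, 35, 65)
  structure(list(n_cells = n_cells, width_px = width_px,
                 height_px = height_px, duration_s = duration_s,
                 centroids = centroids, radius_px = radius_px,
                 schedule = schedule, classes = classes,
                 is_neuron = is_neuron, brightness = brightness,
                 rise_s = rise_s, decay_s = decay_s,
                 rest_level = rest_level,
                 event_amp_range = event_amp_range,
                 event_amp_skew = event_amp_skew,
                 kplus_amplitude = kplus_amplitude),
            class = "synthetic_ground_truth")
}
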