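#' Pharmacology protocol
#'
#' An ordered, non-overlapping set of agent-application epochs attached to a
#' recording. Agents follow the application order used in perfusion
#' experiments on developing networks: GABA, the GABA-A antagonist
#' bicuculline (Bic), the gap-junction blocker carbenoxolone (CBX),
#' glutamate (glut) and high potassium (K+), separated by washout perfusion.
#'
#' @param agent character vector of agent names; each must be one of
#'   `"baseline"`, `"GABA"`, `"Bic"`, `"CBX"`, `"glut"`, `"K+"`.
#' @param concentration numeric vector of concentrations (positive).
#' @param unit character vector of concentration units (e.g. `"uM"`, `"mM"`).
#' @param start_s,end_s numeric vectors of epoch start/end times in seconds.
#' @return An object of class `pharmacology_protocol`: a data frame with
#'   columns `agent`, `concentration`, `unit`, `start_s`, `end_s`.
#' @export
#' @examples
#' pharmacology_protocol(
#'   agent = c("baseline", "K+"),
#'   concentration = c(0, 5), unit = c("", "mM"),
#'   start_s = c(0, 300), end_s = c(300, 360))
pharmacology_protocol <- function(agent, concentration, unit, start_s, end_s) {
  agents_allowed <- c("baseline", "GABA", "Bic", "CBX", "glut", "K+")
  if (!all(agent %in% agents_allowed)) {
    stop("unknown agent(s): ", paste(setdiff(agent, agents_allowed), collapse = ", "),
         "; allowed: ", paste(agents_allowed, collapse = ", "))
  }
  n <- length(agent)
  stopifnot(length(concentration) == n, length(unit) == n,
            length(start_s) == n, length(end_s) == n)
  if (any(concentration < 0)) stop("concentrations must be non-negative")
  if (any(concentration[agent != "baseline"] <= 0))
    stop("non-baseline concentrations must be positive")
  if (any(end_s <= start_s)) stop("epoch end must be after start")
  o <- order(start_s)
  if (n > 1 && any(start_s[o][-1] < end_s[o][-n]))
    stop("epochs must be non-overlapping")
  out <- data.frame(agent = agent[o], concentration = concentration[o],
                    unit = unit[o], start_s = start_s[o], end_s = end_s[o],
                    stringsAsFactors = FALSE)
  class(out) <- c("pharmacology_protocol", "data.frame")
  out
}

#' Default baseline + high-potassium protocol
#'
#' The minimal protocol for viability-oriented analyses: a drug-free
#' baseline of at least 10 minutes (the minimum perfusion-settled baseline
#' used in end-point sessions) followed by a brief high-potassium (5 mM
#' KCl) challenge. Recordings built on this protocol should keep acquiring
#' for a short washout after the K+ application (see
#' [simulate_network_recording()]) so traces do not end on the elevated
#' plateau.
#'
#' @param baseline_s duration of the pre-K+ baseline, seconds.
#' @param kplus_s duration of the K+ application, seconds.
#' @return a [pharmacology_protocol()].
#' @export
protocol_baseline_kplus <- function(baseline_s = 1200, kplus_s = 30) {
  pharmacology_protocol(
    agent = c("baseline", "K+"),
    concentration = c(0, 5), unit = c("", "mM"),
    start_s = c(0, baseline_s), end_s = c(baseline_s, baseline_s + kplus_s))
}

#' Full pharmacological series protocol
#'
#' The complete application order used in the end-point experiments:
#' baseline, GABA (100 uM), bicuculline (10 uM), carbenoxolone (25 uM),
#' glutamate (30 uM) and KCl (5 mM), each separated by a washout perfusion
#' gap. Durations are scaled-down defaults; washouts default to 3 min
#' (within the 3-5 min range used experimentally).
#'
#' @param baseline_s baseline duration (s).
#' @param application_s duration of each agent application (s).
#' @param cbx_s duration of the CBX application (s); longer by default
#'   because the gap-junction blocker acts slowly and only its tail is
#'   analyzed.
#' @param washout_s perfusion gap between applications (s).
#' @param kplus_s duration of the final K+ application (s).
#' @return a [pharmacology_protocol()].
#' @export
protocol_full_series <- function(baseline_s = 600, application_s = 180,
                                 cbx_s = 240, washout_s = 180, kplus_s = 60) {
  agents <- c("GABA", "Bic", "CBX", "glut", "K+")
  conc <- c(100, 10, 25, 30, 5)
  unit <- c("uM", "uM", "uM", "uM", "mM")
  dur <- c(application_s, application_s, cbx_s, application_s, kplus_s)
  start <- numeric(5)
  t0 <- baseline_s
  for (i in seq_along(agents)) {
    start[i] <- t0
    t0 <- t0 + dur[i] + washout_s
  }
  pharmacology_protocol(
    agent = c("baseline", agents),
    concentration = c(0, conc), unit = c("", unit),
    start_s = c(0, start), end_s = c(baseline_s, start + dur))
}

#' Look up an epoch in a protocol
#'
#' @param protocol a [pharmacology_protocol()].
#' @param agent agent name to find.
#' @return one-row data frame, or `NULL` if the agent is absent.
#' @export
protocol_epoch <- function(protocol, agent) {
  stopifnot(inherits(protocol, "pharmacology_protocol"))
  hit <- which(protocol$agent == agent)
  if (length(hit) == 0) return(NULL)
  protocol[hit[1], , drop = FALSE]
}

#' Frame indices covered by an epoch
#'
#' @param protocol a [pharmacology_protocol()].
#' @param agent agent name.
#' @param frame_interval_s frame interval in seconds.
#' @param n_frames total number of frames.
#' @return integer vector of frame indices (1-based), possibly empty.
#' @export
epoch_frames <- function(protocol, agent, frame_interval_s, n_frames) {
  ep <- protocol_epoch(protocol, agent)
  if (is.null(ep)) return(integer(0))
  t <- (seq_len(n_frames) - 1) * frame_interval_s
  which(t >= ep$start_s & t < ep$end_s)
}

#' Total duration implied by a protocol
#' @param protocol a [pharmacology_protocol()].
#' @return last epoch end time, seconds.
#' @export
protocol_duration <- function(protocol) max(protocol$end_s)
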