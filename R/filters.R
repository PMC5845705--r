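# Zero-phase Butterworth filtering helpers shared by the trace and MEA
# modules. Forward-backward filtering keeps event timing unbiased; mirror
# padding suppresses the edge transients that plain filtfilt leaves at very
# low normalized cutoffs.

#' Zero-phase Butterworth filter
#'
#' Applies a Butterworth filter forward and backward (zero phase). The
#' signal is extended on both sides by an odd (point-mirrored) reflection
#' before filtering and trimmed afterwards, which suppresses edge
#' transients; pad length defaults to the signal length minus one.
#'
#' @param x numeric vector.
#' @param cutoff_hz scalar (low/high-pass) or length-2 vector (band-pass)
#'   of cutoff frequencies in Hz.
#' @param fs sampling rate, Hz.
#' @param type `"pass"`, `"low"` or `"high"`.
#' @param order filter order per pass.
#' @param pad_samples mirror-pad length on each side; `NULL` chooses
#'   six cycles of the lowest cutoff (capped at the signal length).
#' @return filtered vector, same length as `x`.
#' @export
butter_filter <- function(x, cutoff_hz, fs, type = c("pass", "low", "high"),
                          order = 2, pad_samples = NULL) {
  type <- match.arg(type)
  ny <- fs / 2
  w <- cutoff_hz / ny
  if (any(w <= 0) || any(w >= 1))
    stop("cutoff frequencies must lie strictly inside (0, Nyquist)")
  if (type == "pass" && (length(w) != 2 || w[1] >= w[2]))
    stop("band-pass needs cutoff_hz = c(low, high) with low < high")
  bf <- signal::butter(order, w, type = type)
  n <- length(x)
  if (n < 4)
    return(as.numeric(cpp_filtfilt(bf$b, bf$a, as.numeric(x))))
  if (is.null(pad_samples))
    pad_samples <- ceiling(6 * fs / min(cutoff_hz))
  p <- min(n - 1, pad_samples)
  xp <- c(2 * x[1] - rev(x[2:(p + 1)]), as.numeric(x),
          2 * x[n] - rev(x[(n - p):(n - 1)]))
  y <- cpp_filtfilt(bf$b, bf$a, xp)
  y[(p + 1):(p + n)]
}

#' Min-max normalization to \[0, 1\]
#'
#' The degenerate rule mirrors the segmentation preprocessing contract: a
#' constant input maps to all zeros rather than NaN.
#'
#' @param x numeric vector or matrix.
#' @return rescaled object with min 0 and max 1 (all zeros if constant).
#' @export
minmax_scale <- function(x) {
  rng <- range(x, finite = TRUE)
  if (!is.finite(rng[1]) || rng[2] - rng[1] <= 0) {
    x[] <- 0
    return(x)
  }
  (x - rng[1]) / (rng[2] - rng[1])
}
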