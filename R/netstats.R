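# Network-level statistics: an operational activity-pattern classifier
# (the three diagnostic quantities are always reported next to the
# label), paired nonparametric comparisons, correlations and the report
# tables.

#' Classification parameters
#'
#' Thresholds of the operational activity-pattern rule; all configurable.
#'
#' @param min_peaks_per_5min fewer network peaks than this per 5 minutes
#'   marks the recording asynchronous.
#' @param min_participation_async mean event participation below this also
#'   marks it asynchronous.
#' @param min_participation_sync participation at or above this (and a
#'   sufficient activity ratio) marks it synchronous.
#' @param min_activity_ratio_sync minimum in-event / out-of-event activity
#'   ratio for the synchronous label.
#' @param event_halfwidth_s half-width of the window around a network peak
#'   within which a single-cell peak counts as participating, s.
#' @param min_traces fewer traces than this yields "undetermined".
#' @return a `classify_params` list.
#' @export
classify_params <- function(min_peaks_per_5min = 2,
                            min_participation_async = 0.2,
                            min_participation_sync = 0.5,
                            min_activity_ratio_sync = 3,
                            event_halfwidth_s = 5,
                            min_traces = 10) {
  as.list(environment())
}

#' Classify a recording's activity pattern
#'
#' Operational rule distinguishing the three developmental activity
#' patterns (the published classification was visual; this rule is the
#' package's own, and its three diagnostics are always reported with the
#' label):
#'
#' * asynchronous — fewer than `min_peaks_per_5min` network peaks per
#'   5 min, or mean event participation below `min_participation_async`;
#' * synchronous — participation at or above `min_participation_sync`
#'   and in-event / out-of-event single-cell activity ratio at or above
#'   `min_activity_ratio_sync`;
#' * loosely synchronous — otherwise.
#'
#' Participation at a network peak is the fraction of cells with a
#' single-cell activity peak within `event_halfwidth_s` of it; the
#' activity ratio compares mean absolute band-passed single-cell signal
#' inside event windows to outside.
#'
#' @param traces QC-passed matrix frames x cells.
#' @param network_peaks [find_peaks()] result for the network trace.
#' @param params a [classify_params()].
#' @param trace_pars a [trace_params()] (single-cell peak criterion and
#'   band).
#' @param frame_interval_s frame interval, s.
#' @return a `network_classification`: list with `label`,
#'   `peaks_per_5min`, `mean_participation`, `activity_ratio`,
#'   `n_traces`, `participation_per_event`.
#' @export
classify_network <- function(traces, network_peaks,
                             params = classify_params(),
                             trace_pars = trace_params(),
                             frame_interval_s = NULL) {
  fi <- trace_frame_interval(traces, frame_interval_s)
  nf <- nrow(traces); nc <- ncol(traces)
  duration_s <- nf * fi
  out <- function(label, part, ratio) {
    structure(list(label = label,
                   peaks_per_5min = nrow(network_peaks) / duration_s * 300,
                   mean_participation = part,
                   activity_ratio = ratio,
                   n_traces = nc,
                   participation_per_event = attr(part, "per_event")),
              class = "network_classification")
  }
  if (nc < params$min_traces) return(out("undetermined", NA_real_, NA_real_))
  fs <- 1 / fi
  filt <- matrix(0, nf, nc)
  for (j in seq_len(nc))
    filt[, j] <- butter_filter(traces[, j], trace_pars$network_band, fs,
                               type = "pass", order = trace_pars$filter_order)
  cell_peaks <- lapply(seq_len(nc), function(j)
    find_peaks(filt[, j], trace_pars$peak_prominence_single, fi)$time_s)
  hw <- params$event_halfwidth_s
  ev_t <- network_peaks$time_s
  if (length(ev_t)) {
    per_event <- vapply(ev_t, function(te)
      mean(vapply(cell_peaks, function(tp) any(abs(tp - te) <= hw),
                  logical(1))), numeric(1))
    part <- mean(per_event)
    attr(part, "per_event") <- per_event
    t_fr <- (seq_len(nf) - 1) * fi
    in_event <- rep(FALSE, nf)
    guard <- rep(FALSE, nf)   # transient tails just outside the event window
    for (te in ev_t) {
      in_event <- in_event | (abs(t_fr - te) <= hw)
      guard <- guard | (abs(t_fr - te) <= 2 * hw)
    }
    out_event <- !guard
    if (!any(in_event) || !any(out_event)) {
      ratio <- NA_real_
    } else {
      # activity = fluorescence above the cell's resting (median) level;
      # the raw normalized trace avoids band-pass rebound artifacts
      act <- sweep(traces, 2, apply(traces, 2, median), "-")
      act[act < 0] <- 0
      a_in <- colMeans(act[in_event, , drop = FALSE])
      a_out <- colMeans(act[out_event, , drop = FALSE])
      ratio <- median(a_in) / median(pmax(a_out, 1e-12))
    }
  } else {
    part <- 0
    attr(part, "per_event") <- numeric(0)
    ratio <- NA_real_
  }
  peaks5 <- nrow(network_peaks) / duration_s * 300
  label <- if (peaks5 < params$min_peaks_per_5min ||
               (!is.na(part) && part < params$min_participation_async)) {
    "asynchronous"
  } else if (!is.na(part) && part >= params$min_participation_sync &&
             !is.na(ratio) && ratio >= params$min_activity_ratio_sync) {
    "synchronous"
  } else {
    "loosely_synchronous"
  }
  out(label, part, ratio)
}

#' @export
print.network_classification <- function(x, ...) {
  cat(sprintf(paste0("network_classification: %s\n",
                     "  network peaks / 5 min: %.2f\n",
                     "  mean event participation: %.2f\n",
                     "  in/out-of-event activity ratio: %.2f\n",
                     "  traces: %d\n"),
              x$label, x$peaks_per_5min, x$mean_participation,
              x$activity_ratio, x$n_traces))
  invisible(x)
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-tailed paired signed-rank comparison. Zero differences are dropped
#' (the original signed-rank procedure); the exact distribution is used
#' for up to 25 nonzero differences, the normal approximation above that.
#' All-zero differences yield an undefined p, flagged.
#'
#' @param paired_before,paired_after equal-length numeric vectors.
#' @return list: `statistic` (V), `p_value`, `n` (nonzero pairs),
#'   `all_zero` flag, `method`.
#' @export
wilcoxon_signed_rank <- function(paired_before, paired_after) {
  stopifnot(length(paired_before) == length(paired_after))
  d <- paired_after - paired_before
  nz <- d != 0
  n <- sum(nz)
  if (n == 0)
    return(list(statistic = NA_real_, p_value = NA_real_, n = 0L,
                all_zero = TRUE, method = "wilcoxon_signed_rank"))
  exact <- n <= 25
  ht <- suppressWarnings(
    wilcox.test(paired_after[nz], paired_before[nz], paired = TRUE,
                alternative = "two.sided", exact = exact, correct = !exact))
  list(statistic = unname(ht$statistic), p_value = ht$p.value, n = n,
       all_zero = FALSE,
       method = if (exact) "exact" else "normal_approximation")
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y equal-length numeric vectors (length >= 3, non-constant).
#' @return list: `r`, `p_value`, `n`, `degenerate` flag.
#' @export
pearson_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0)
    return(list(r = NA_real_, p_value = NA_real_, n = length(x),
                degenerate = TRUE))
  ht <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ht$estimate), p_value = ht$p.value, n = length(x),
       degenerate = FALSE)
}

#' Classification count table
#'
#' Counts and rounded percentage proportions of activity-pattern labels,
#' optionally per time point.
#'
#' @param labels character vector of labels.
#' @param timepoint optional grouping vector (e.g. culture week).
#' @return data frame: `timepoint` (if given), `label`, `count`,
#'   `proportion_pct` (rounded to integer percent; proportions within a
#'   time point sum to 100 before rounding).
#' @export
classification_counts <- function(labels, timepoint = NULL) {
  if (is.null(timepoint)) timepoint <- rep("all", length(labels))
  df <- data.frame(timepoint = timepoint, label = labels)
  agg <- aggregate(list(count = rep(1L, nrow(df))),
                   by = list(timepoint = df$timepoint, label = df$label),
                   FUN = sum)
  tot <- tapply(agg$count, agg$timepoint, sum)
  agg$proportion_pct <- round(100 * agg$count / as.numeric(tot[as.character(agg$timepoint)]))
  agg[order(agg$timepoint, -agg$count), ]
}

#' Column totals of a per-week ROI bookkeeping table
#'
#' Sums per-week analyzed-ROI counts (and any other numeric columns) into
#' a totals row, for checking against printed totals.
#'
#' @param counts data frame with a `week` column and numeric count
#'   columns (`NA` allowed for weeks without a category).
#' @return named numeric vector of column totals.
#' @export
roi_count_totals <- function(counts) {
  num <- vapply(counts, is.numeric, logical(1))
  num["week"] <- FALSE
  colSums(counts[, num, drop = FALSE], na.rm = TRUE)
}

#' Assemble report tables for a cohort of analyzed networks
#'
#' One machine-readable table per standard figure analogue:
#' classification counts per time point, reverse-cumulative GABA response
#' curves, per-epoch metric rows, and a per-cell response map (centroid +
#' response value) per network where available.
#'
#' @param networks list of per-network results; each element may carry
#'   `label`, `timepoint`, `gaba_responses` (numeric per cell),
#'   `epoch_metrics` (list of [epoch_metrics()]), `response_map`
#'   (data frame `row`, `col`, `response`).
#' @param hist_bin bin width for the reverse-cumulative GABA curves.
#' @return list of data frames: `classification`, `gaba_reverse_cumulative`,
#'   `epoch_metrics`, `response_maps`.
#' @export
build_report <- function(networks, hist_bin = 0.05) {
  stopifnot(length(networks) >= 1)
  labels <- vapply(networks, function(x) x$label %||% NA_character_, "")
  tps <- vapply(networks, function(x) as.character(x$timepoint %||% "all"), "")
  cls <- classification_counts(labels[!is.na(labels)],
                               tps[!is.na(labels)])
  gr <- do.call(rbind, lapply(seq_along(networks), function(i) {
    v <- networks[[i]]$gaba_responses
    if (is.null(v) || !length(v)) return(NULL)
    h <- response_histograms(v, hist_bin, direction = "reverse")
    cbind(network = i, h)
  }))
  em <- do.call(rbind, lapply(seq_along(networks), function(i) {
    ems <- networks[[i]]$epoch_metrics
    if (is.null(ems)) return(NULL)
    do.call(rbind, lapply(ems, function(m) data.frame(
      network = i, epoch = m$epoch,
      baseline_median_prominence = m$baseline$median_prominence,
      epoch_median_prominence = m$treatment$median_prominence,
      prominence_change = m$prominence_change,
      prominence_relative_change = m$prominence_relative_change,
      baseline_median_interval_s = m$baseline$median_interval_s,
      epoch_median_interval_s = m$treatment$median_interval_s,
      interval_change_s = m$interval_change_s,
      interval_relative_change = m$interval_relative_change)))
  }))
  rm_ <- do.call(rbind, lapply(seq_along(networks), function(i) {
    mp <- networks[[i]]$response_map
    if (is.null(mp)) return(NULL)
    cbind(network = i, mp)
  }))
  list(classification = cls, gaba_reverse_cumulative = gr,
       epoch_metrics = em, response_maps = rm_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
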