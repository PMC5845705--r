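#!/usr/bin/env Rscript
# Step 4 — pharmacological quantification across the cohort.
#
# For every network in the manifest: re-render its traces, build the
# network activity trace, detect peaks, classify the activity pattern,
# and quantify the GABA, Bic and CBX epochs (peak prominence and
# inter-peak-interval changes) plus the per-cell excitatory GABA score.
# Per-network rows go to results/pharmacology_metrics.tsv.

suppressPackageStartupMessages(library(calmea))
dir.create("results", showWarnings = FALSE)

cohort <- read.table("results/cohort/cohort.tsv", header = TRUE, sep = "\t")
protocol <- protocol_full_series(baseline_s = 1200)
dur <- protocol_duration(protocol) + 120
tp <- trace_params()

networks <- list()
rows <- NULL
for (i in seq_len(nrow(cohort))) {
  gt <- synthetic_ground_truth(
    n_cells = 60, width_px = 160, height_px = 160, duration_s = dur,
    mode = cohort$mode[i], seed = cohort$seed[i],
    participation_prob = if (cohort$mode[i] == "loosely_synchronous") 0.4 else 0.8,
    per_cell_rate_hz = if (cohort$mode[i] == "synchronous") 0 else 0.012)
  tr <- apply(render_cell_traces(gt, protocol, 0.5,
                                 seed = cohort$seed[i] + 500L), 2, minmax_scale)
  attr(tr, "frame_interval_s") <- 0.5
  qc <- qc_filter(tr, protocol, tp)
  nt <- network_trace(qc$traces, tp)
  pk <- find_peaks(as.numeric(nt), tp$peak_prominence_network, 0.5)
  cl <- classify_network(qc$traces, pk, trace_pars = tp)
  gaba <- apply(qc$traces, 2, gaba_excitatory_response, protocol = protocol,
                params = tp, frame_interval_s = 0.5)
  ems <- lapply(c("GABA", "Bic", "CBX"), function(a)
    epoch_metrics(pk, protocol, a, params = tp))
  networks[[i]] <- list(
    label = cl$label, timepoint = cohort$week[i],
    gaba_responses = gaba, epoch_metrics = ems,
    response_map = data.frame(row = gt$centroids[, 1],
                              col = gt$centroids[, 2],
                              response = apply(tr, 2, gaba_excitatory_response,
                                               protocol = protocol, params = tp,
                                               frame_interval_s = 0.5)))
  rows <- rbind(rows, data.frame(
    network = i, week = cohort$week[i], generated = cohort$mode[i],
    classified = cl$label, participation = round(cl$mean_participation, 2),
    gaba_prom_change = ems[[1]]$prominence_change,
    cbx_interval_change_s = ems[[3]]$interval_change_s,
    median_gaba_score = median(gaba)))
  message(sprintf("network %d (%s, week %d): classified %s", i,
                  cohort$mode[i], cohort$week[i], cl$label))
}
write.table(rows, "results/pharmacology_metrics.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
gaba_long <- do.call(rbind, lapply(seq_along(networks), function(i)
  data.frame(network = i, week = networks[[i]]$timepoint,
             label = networks[[i]]$label,
             gaba_score = networks[[i]]$gaba_responses)))
write.table(gaba_long, "results/gaba_scores.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
message("wrote results/pharmacology_metrics.tsv and results/gaba_scores.tsv")
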