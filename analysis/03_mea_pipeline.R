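#!/usr/bin/env Rscript
# Step 3 — MEA pipeline on a paired synthetic voltage recording.
#
# Renders the voltage counterpart of the representative synchronous
# network (same event schedule), detects spikes with the median-based
# threshold, and writes spike tables, the 2-s rate raster (as PNG and
# table) and the combined network rate.

suppressPackageStartupMessages(library(calmea))
dir.create("results", showWarnings = FALSE)

cohort <- read.table("results/cohort/cohort.tsv", header = TRUE, sep = "\t")
rep_net <- cohort[cohort$mode == "synchronous", ][1, ]

sch <- generate_event_schedule("synchronous", duration_s = 300,
                               network_rate_hz = 0.03, n_cells = 1,
                               seed = rep_net$seed)
r <- render_mea_recording(sch, n_electrodes = 60, sampling_rate_hz = 10000,
                          seed = rep_net$seed + 1L)
true_times <- r$spike_times
rec <- r$recording
r$recording <- NULL; rm(r); invisible(gc(FALSE))  # one voltage copy in memory
rec <- median_reference(rec); invisible(gc(FALSE))
rec <- bandpass_voltage(rec); invisible(gc(FALSE))
st <- detect_spikes(rec)
rm(rec); invisible(gc(FALSE))
message(sprintf("detected %d spikes on %d electrodes (%d inserted)",
                sum(lengths(st$times)), length(st$times),
                sum(lengths(true_times))))

write_spikes_delim(st, "results/representative_spikes.tsv")
raster <- spike_rate_raster(st)
write.table(round(raster, 4), "results/representative_raster.tsv",
            sep = "\t", row.names = FALSE, col.names = FALSE)
write_raster_png(raster, "results/representative_raster.png")

g <- global_spike_rate(st)
pk <- find_peaks(g$value, mea_params()$network_peak_prominence)
pk$time_s <- g$time_s[pk$index]
message(sprintf("network rate: %d activity peaks (prominence >= 0.05), median interval %.1f s",
                nrow(pk), median(diff(pk$time_s))))
message(sprintf("true network events: %d, median interval %.1f s",
                length(sch$network_events), median(diff(sch$network_events))))
write.table(g, "results/representative_global_rate.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
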