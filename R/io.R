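# Plain-text and standard-format IO: multi-page 16-bit TIFF for movies,
# a delimited voltage format with a small header, delimited trace and
# spike tables, JSON ground truth.

#' Write a fluorescence movie as multi-page 16-bit TIFF
#'
#' @param movie a `fluorescence_movie` or 3-d array (counts).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path) {
  dat <- movie_data(movie)
  frames <- lapply(seq_len(dim(dat)[3]), function(f) dat[, , f] / 65535)
  tiff::writeTIFF(frames, path, bits.per.sample = 16)
  invisible(path)
}

#' Read a multi-page TIFF into a movie array
#'
#' @param path TIFF file.
#' @param frame_interval_s frame interval to attach, s.
#' @param protocol optional [pharmacology_protocol()] to attach.
#' @return a `fluorescence_movie` (counts on the 16-bit scale).
#' @export
read_movie_tiff <- function(path, frame_interval_s = 0.5, protocol = NULL) {
  frames <- tiff::readTIFF(path, all = TRUE)
  arr <- array(0, dim = c(dim(frames[[1]])[1:2], length(frames)))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    if (length(dim(fr)) == 3) fr <- fr[, , 1]
    arr[, , f] <- fr * 65535
  }
  structure(list(data = arr, frame_interval_s = frame_interval_s,
                 protocol = protocol),
            class = "fluorescence_movie")
}

#' Write a voltage recording as delimited text
#'
#' Header lines (`# key value`) carry the sampling rate and reference
#' electrode; the body is one row per sample, one column per electrode.
#'
#' @param recording a [voltage_recording()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_voltage_delim <- function(recording, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# sampling_rate_hz %g", recording$sampling_rate_hz),
               sprintf("# reference_index %d", recording$reference_index)),
             con)
  write.table(t(recording$voltages), con, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a delimited voltage recording
#'
#' @param path file written by [write_voltage_delim()].
#' @return a [voltage_recording()].
#' @export
read_voltage_delim <- function(path) {
  hdr <- readLines(path, n = 2)
  fs <- as.numeric(sub("# sampling_rate_hz ", "", hdr[1]))
  ref <- as.integer(sub("# reference_index ", "", hdr[2]))
  v <- as.matrix(read.table(path, skip = 2, sep = "\t"))
  dimnames(v) <- NULL
  voltage_recording(t(v), fs, reference_index = ref)
}

#' Write spike timestamps as a delimited table
#'
#' @param spiketrain a [detect_spikes()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_spikes_delim <- function(spiketrain, path) {
  df <- do.call(rbind, lapply(seq_along(spiketrain$times), function(e) {
    t <- spiketrain$times[[e]]
    if (!length(t)) return(NULL)
    data.frame(electrode = e, timestamp_s = t)
  }))
  if (is.null(df)) df <- data.frame(electrode = integer(0),
                                    timestamp_s = numeric(0))
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a trace matrix as delimited text
#'
#' Rows are frames, columns cell/track ids; re-importable with
#' [read_traces_delim()].
#'
#' @param traces matrix frames x cells.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traces_delim <- function(traces, path) {
  write.table(as.data.frame(traces), path, sep = "\t", row.names = FALSE,
              quote = FALSE)
  invisible(path)
}

#' Read a delimited trace matrix
#'
#' @param path file written by [write_traces_delim()].
#' @param frame_interval_s frame interval to attach, s.
#' @return matrix frames x cells.
#' @export
read_traces_delim <- function(path, frame_interval_s = 0.5) {
  m <- as.matrix(read.table(path, header = TRUE, sep = "\t",
                            check.names = FALSE))
  attr(m, "frame_interval_s") <- frame_interval_s
  m
}

#' Write ground truth as JSON
#'
#' @param ground_truth a [synthetic_ground_truth()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(ground_truth, path) {
  gt <- ground_truth
  jsonlite::write_json(list(
    n_cells = gt$n_cells, width_px = gt$width_px, height_px = gt$height_px,
    duration_s = gt$duration_s,
    centroids = unname(as.data.frame(gt$centroids)),
    radius_px = gt$radius_px,
    classes = gt$classes,
    mode = gt$schedule$mode,
    network_events = gt$schedule$network_events,
    cell_events = gt$schedule$cell_events,
    rise_s = gt$rise_s, decay_s = gt$decay_s),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a segmentation label image as 16-bit TIFF
#'
#' @param segmentation a [watershed_segment()] result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_labels_tiff <- function(segmentation, path) {
  tiff::writeTIFF(segmentation$labels / 65535, path, bits.per.sample = 16)
  invisible(path)
}

#' Export a pseudo-colored per-cell response map as PNG
#'
#' Cells are drawn as filled discs at their centroids, colored from green
#' (strongest depolarization) through black (no response) to red
#' (strongest inhibition), the conventional display for per-cell GABA
#' response maps.
#'
#' @param response_map data frame with `row`, `col`, `response`.
#' @param width_px,height_px field size, pixels.
#' @param path output file.
#' @param radius_px disc radius, px.
#' @return `path`, invisibly.
#' @export
write_response_map_png <- function(response_map, width_px, height_px, path,
                                   radius_px = 4) {
  img <- array(0, dim = c(height_px, width_px, 3))
  lim <- max(abs(response_map$response), 1e-12)
  for (i in seq_len(nrow(response_map))) {
    v <- response_map$response[i] / lim
    col3 <- if (v >= 0) c(0, v, 0) else c(-v, 0, 0)
    r0 <- round(response_map$row[i]); c0 <- round(response_map$col[i])
    rows <- pmax(1, r0 - radius_px + 1):pmin(height_px, r0 + radius_px + 1)
    cols <- pmax(1, c0 - radius_px + 1):pmin(width_px, c0 + radius_px + 1)
    for (r in rows) for (cc in cols) {
      if ((r - 1 - response_map$row[i])^2 +
          (cc - 1 - response_map$col[i])^2 <= radius_px^2)
        img[r, cc, ] <- col3
    }
  }
  png::writePNG(img, path)
  invisible(path)
}
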