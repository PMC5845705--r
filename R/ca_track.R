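# Frame-to-frame linking of segmented cells: gated centroid distances,
# min-cost assignment with per-item non-assignment costs, track filtering
# by age and visibility, and per-frame trace extraction.

#' Tracking parameters
#'
#' @param gating_threshold maximum centroid distance (px) for a candidate
#'   link; beyond it the pair is assigned `gating_cost`.
#' @param gating_cost prohibitive cost for gated-out pairs.
#' @param cost_non_assignment cost of leaving one track or one detection
#'   unassigned.
#' @param min_track_age minimum track age (segmentation steps) to keep.
#' @param min_visibility minimum fraction of steps with a detection.
#' @return a `track_params` list.
#' @export
track_params <- function(gating_threshold = 20, gating_cost = 5000,
                         cost_non_assignment = 500,
                         min_track_age = 20, min_visibility = 0.5) {
  stopifnot(gating_cost > cost_non_assignment, cost_non_assignment > 0,
            min_visibility > 0, min_visibility <= 1)
  as.list(environment())
}

#' Gated centroid cost matrix
#'
#' Entry (i, j) is the Euclidean distance between previous centroid i and
#' new centroid j if within the gating threshold, else the gating cost.
#'
#' @param prev_centroids,new_centroids matrices with columns `row`, `col`
#'   (possibly zero rows).
#' @param params a [track_params()].
#' @return numeric matrix `|prev| x |new|`.
#' @export
build_cost_matrix <- function(prev_centroids, new_centroids,
                              params = track_params()) {
  np <- nrow(prev_centroids); nn <- nrow(new_centroids)
  if (is.null(np)) np <- 0
  if (is.null(nn)) nn <- 0
  if (np == 0 || nn == 0) return(matrix(numeric(0), nrow = np, ncol = nn))
  d <- sqrt(outer(prev_centroids[, 1], new_centroids[, 1], "-")^2 +
              outer(prev_centroids[, 2], new_centroids[, 2], "-")^2)
  d[d > params$gating_threshold] <- params$gating_cost
  d
}

#' Optimal assignment with non-assignment costs
#'
#' Solves the min-cost matching where any row (track) or column
#' (detection) may instead stay unmatched at `cost_non_assignment` each,
#' via the standard augmented square matrix (dummy diagonal blocks at the
#' non-assignment cost, zero lower-right block) and the Hungarian
#' algorithm. A pair is matched only when its cost beats leaving both
#' items unmatched.
#'
#' @param cost_matrix numeric matrix (finite entries).
#' @param params a [track_params()] (uses `cost_non_assignment`).
#' @return list: `matches` (two-column matrix of row/col indices),
#'   `unmatched_prev`, `unmatched_new`, `total_cost`.
#' @export
assign_tracks <- function(cost_matrix, params = track_params()) {
  n <- nrow(cost_matrix); m <- ncol(cost_matrix)
  cna <- params$cost_non_assignment
  if (n == 0 || m == 0) {
    return(list(matches = matrix(integer(0), ncol = 2,
                                 dimnames = list(NULL, c("prev", "new"))),
                unmatched_prev = seq_len(n), unmatched_new = seq_len(m),
                total_cost = cna * (n + m)))
  }
  if (any(!is.finite(cost_matrix))) stop("cost matrix must be finite")
  # an edge costing >= 2 * cna can never beat unmatching both endpoints,
  # so the problem decomposes over connected components of usable edges
  usable <- cost_matrix < 2 * cna
  solve_aug <- function(sub) {
    nr <- nrow(sub); nc <- ncol(sub)
    big <- max(sub, cna) * (nr + nc) + 1
    a <- matrix(big, nr + nc, nr + nc)
    a[seq_len(nr), seq_len(nc)] <- sub
    a[cbind(seq_len(nr), nc + seq_len(nr))] <- cna
    a[cbind(nr + seq_len(nc), seq_len(nc))] <- cna
    a[nr + seq_len(nc), nc + seq_len(nr)] <- 0
    col_of_row <- cpp_hungarian(a)
    matched <- which(col_of_row[seq_len(nr)] <= nc)
    cbind(matched, col_of_row[matched])
  }
  comp_row <- integer(n); comp_col <- integer(m); nc_comp <- 0L
  for (i in seq_len(n)) {
    if (comp_row[i] || !any(usable[i, ])) next
    nc_comp <- nc_comp + 1L
    qr <- i
    while (length(qr)) {
      r <- qr[1]; qr <- qr[-1]
      if (comp_row[r]) next
      comp_row[r] <- nc_comp
      for (j in which(usable[r, ] & comp_col == 0L)) {
        comp_col[j] <- nc_comp
        qr <- c(qr, which(usable[, j] & comp_row == 0L))
      }
    }
  }
  matches <- NULL
  for (k in seq_len(nc_comp)) {
    rr <- which(comp_row == k); cc <- which(comp_col == k)
    if (length(rr) == 1 && length(cc) == 1) {
      matches <- rbind(matches, c(rr, cc))  # single usable edge: matched
      next
    }
    sub <- cost_matrix[rr, cc, drop = FALSE]
    mm <- solve_aug(sub)
    if (nrow(mm))
      matches <- rbind(matches, cbind(rr[mm[, 1]], cc[mm[, 2]]))
  }
  if (is.null(matches))
    matches <- matrix(integer(0), ncol = 2)
  colnames(matches) <- c("prev", "new")
  list(matches = matches,
       unmatched_prev = setdiff(seq_len(n), matches[, 1]),
       unmatched_new = setdiff(seq_len(m), matches[, 2]),
       total_cost = sum(cost_matrix[matches]) +
         cna * (n - nrow(matches)) + cna * (m - nrow(matches)))
}

#' Link segmentations into cell tracks
#'
#' Sequentially assigns each step's detections to open tracks using
#' [build_cost_matrix()] and [assign_tracks()]. Unmatched detections open
#' new tracks; unmatched tracks persist invisibly (their last centroid is
#' used for gating at later steps) until visibility filtering.
#'
#' @param segmentations list of `segmentation` objects (one per step),
#'   e.g. from [segment_movie()].
#' @param params a [track_params()].
#' @return a `cell_tracks` object: list of tracks, each with `id`,
#'   `first_step`, `centroids` (steps x 2, NA when invisible), `regions`
#'   (per-step pixel index list, NULL when invisible) and `visible`
#'   (logical per step); plus `n_steps`.
#' @export
track_cells <- function(segmentations, params = track_params()) {
  n_steps <- length(segmentations)
  tracks <- list()
  next_id <- 1L
  active <- integer(0)   # indices into tracks with >= 1 detection so far
  for (s in seq_len(n_steps)) {
    seg <- segmentations[[s]]
    cen <- as.matrix(seg$centroids[, c("row", "col"), drop = FALSE])
    prev <- if (length(active))
      t(vapply(tracks[active], function(tr) tr$last_centroid, numeric(2)))
    else matrix(numeric(0), nrow = 0, ncol = 2)
    cm <- build_cost_matrix(prev, cen, params)
    asg <- assign_tracks(cm, params)
    if (nrow(asg$matches)) {
      for (k in seq_len(nrow(asg$matches))) {
        ti <- active[asg$matches[k, 1]]
        di <- asg$matches[k, 2]
        tracks[[ti]]$centroids[s, ] <- cen[di, ]
        tracks[[ti]]$regions[[s]] <- seg$pixels[[di]]
        tracks[[ti]]$visible[s] <- TRUE
        tracks[[ti]]$last_centroid <- cen[di, ]
      }
    }
    for (di in asg$unmatched_new) {
      tr <- list(id = next_id, first_step = s,
                 centroids = matrix(NA_real_, n_steps, 2),
                 regions = vector("list", n_steps),
                 visible = logical(n_steps),
                 last_centroid = cen[di, ])
      tr$centroids[s, ] <- cen[di, ]
      tr$regions[[s]] <- seg$pixels[[di]]
      tr$visible[s] <- TRUE
      tracks[[length(tracks) + 1L]] <- tr
      next_id <- next_id + 1L
    }
    active <- seq_along(tracks)
  }
  structure(list(tracks = tracks, n_steps = n_steps), class = "cell_tracks")
}

#' Filter tracks by age and visibility
#'
#' Keeps tracks whose age (steps since creation, counted to the end of the
#' recording) reaches `min_track_age` and whose visible fraction of that
#' age reaches `min_visibility`.
#'
#' @param tracks a `cell_tracks` object.
#' @param params a [track_params()].
#' @param n_steps total number of steps (defaults to the recording's).
#' @return the filtered `cell_tracks`.
#' @export
filter_tracks <- function(tracks, params = track_params(),
                          n_steps = tracks$n_steps) {
  stopifnot(n_steps >= 1)
  keep <- vapply(tracks$tracks, function(tr) {
    age <- n_steps - tr$first_step + 1L
    vis <- sum(tr$visible)
    age >= params$min_track_age && vis / age >= params$min_visibility
  }, logical(1))
  structure(list(tracks = tracks$tracks[keep], n_steps = n_steps),
            class = "cell_tracks")
}

#' @export
print.cell_tracks <- function(x, ...) {
  cat(sprintf("cell_tracks: %d tracks over %d steps\n",
              length(x$tracks), x$n_steps))
  invisible(x)
}

#' Extract normalized single-cell fluorescence traces
#'
#' For every original frame, each track's trace value is the mean pixel
#' intensity over the region of the segmentation step owning that frame
#' (frames are assigned to the nearest block centre); steps where the
#' track was invisible reuse the last-known region (the first known one
#' for leading gaps). Each trace is min-max normalized to \[0, 1\], so 1 is
#' the cell's maximum intensity during the recording; a constant trace
#' maps to zeros.
#'
#' @param movie a `fluorescence_movie` or 3-d array.
#' @param tracks a (filtered) `cell_tracks` object.
#' @param blocks data frame with `start`/`end` frame of each step, as
#'   produced by [preprocess_frames()]/[segment_movie()].
#' @return matrix frames x tracks (colnames = track ids), with attributes
#'   `frame_interval_s` and `protocol` when available from the movie.
#' @export
extract_traces <- function(movie, tracks, blocks) {
  dat <- movie_data(movie)
  d <- dim(dat)
  nf <- d[3]
  m <- matrix(dat, nrow = d[1] * d[2])
  n_steps <- tracks$n_steps
  stopifnot(nrow(blocks) == n_steps)
  centres <- (blocks$start + blocks$end) / 2
  owner <- vapply(seq_len(nf), function(f) which.min(abs(centres - f)),
                  integer(1))
  ntr <- length(tracks$tracks)
  out <- matrix(NA_real_, nrow = nf, ncol = ntr)
  for (k in seq_len(ntr)) {
    tr <- tracks$tracks[[k]]
    if (!any(tr$visible)) stop("track ", tr$id, " has no region at any step")
    regions <- tr$regions
    known <- which(tr$visible)
    for (s in seq_len(n_steps)) {
      if (is.null(regions[[s]])) {
        prior <- known[known < s]
        src <- if (length(prior)) max(prior) else min(known)
        regions[[s]] <- regions[[src]]
      }
    }
    for (s in unique(owner)) {
      fr <- which(owner == s)
      pix <- regions[[s]]
      out[fr, k] <- colMeans(m[pix, fr, drop = FALSE])
    }
  }
  out <- apply(out, 2, minmax_scale)
  colnames(out) <- vapply(tracks$tracks, function(tr) as.character(tr$id), "")
  if (inherits(movie, "fluorescence_movie")) {
    attr(out, "frame_interval_s") <- movie$frame_interval_s
    attr(out, "protocol") <- movie$protocol
  }
  out
}
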