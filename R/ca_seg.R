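# Soma segmentation: block-averaged reference images, morphological
# foreground markers, distance-transform-derived background markers, and a
# marker-controlled watershed on the Sobel gradient magnitude.
# Morphology, Otsu thresholding and the distance transform come from
# EBImage; the marker-imposed Meyer flood is the package's own (compiled).

disc_brush <- function(radius) EBImage::makeBrush(2 * radius + 1, "disc")

#' Segmentation parameters
#'
#' @param frames_to_average frames averaged per reference image.
#' @param stride frames between successive reference images; defaults to
#'   `frames_to_average` (non-overlapping blocks).
#' @param marker_opening_radius disc radius (px) of the opening that
#'   suppresses soma-scale objects when building the top-hat residual;
#'   roughly the soma radius.
#' @param erosion_disk_radius disc radius (px) of the post-top-hat erosion.
#' @param maxima_neighborhood side of the square neighbourhood used to
#'   clean the regional-maxima mask (erode then dilate).
#' @param background_dilation_radius disc radius (px) for dilating the
#'   background ridge markers.
#' @param marker_min_height minimum image height (on the \[0,1\] scale) for a
#'   regional maximum to seed a marker; interprets the thresholding of
#'   high-intensity objects and suppresses noise maxima.
#' @param fg_fill value used to flatten foreground pixels before Otsu
#'   thresholding: `"median"` or `"mean"` of the image.
#' @return a `seg_params` list.
#' @export
seg_params <- function(frames_to_average = 50, stride = NULL,
                       marker_opening_radius = 6, erosion_disk_radius = 2,
                       maxima_neighborhood = 3,
                       background_dilation_radius = 2,
                       marker_min_height = 0.1,
                       fg_fill = c("median", "mean")) {
  fg_fill <- match.arg(fg_fill)
  if (is.null(stride)) stride <- frames_to_average
  stopifnot(frames_to_average >= 1, stride >= 1,
            marker_opening_radius >= 1, erosion_disk_radius >= 1,
            background_dilation_radius >= 1)
  as.list(environment())
}

movie_data <- function(movie) {
  if (inherits(movie, "fluorescence_movie")) movie$data else movie
}

#' Build block-averaged reference images
#'
#' Averages `frames_to_average` consecutive frames (sliding by `stride`)
#' and min-max scales each average to \[0, 1\]; a constant average maps to
#' all zeros.
#'
#' @param movie a `fluorescence_movie` or a height x width x frames array.
#' @param params a [seg_params()].
#' @return list of matrices; attribute `blocks` is a data frame with the
#'   first/last frame of each block.
#' @export
preprocess_frames <- function(movie, params = seg_params()) {
  dat <- movie_data(movie)
  d <- dim(dat)
  if (length(d) != 3 || d[3] == 0) stop("movie must be a non-empty 3-d stack")
  fta <- params$frames_to_average
  if (d[3] < fta) stop("movie has fewer frames than frames_to_average")
  starts <- seq(1L, d[3] - fta + 1L, by = params$stride)
  m <- matrix(dat, nrow = d[1] * d[2])
  out <- vector("list", length(starts))
  for (b in seq_along(starts)) {
    fr <- starts[b]:(starts[b] + fta - 1L)
    avg <- rowMeans(m[, fr, drop = FALSE])
    img <- matrix(minmax_scale(avg), nrow = d[1])
    out[[b]] <- img
  }
  attr(out, "blocks") <- data.frame(start = starts, end = starts + fta - 1L)
  out
}

#' Regional maxima of an image
#'
#' Connected plateaus none of whose neighbouring pixels is higher or
#' equal-and-outside (8-connectivity), restricted to pixels at or above
#' `min_height`.
#'
#' @param img numeric matrix.
#' @param min_height minimum plateau height.
#' @return logical matrix.
#' @export
regional_maxima <- function(img, min_height = 0) {
  dmax <- as.matrix(EBImage::dilate(img, EBImage::makeBrush(3, "box")))
  cand <- (img >= dmax - 1e-12) & (img >= min_height)
  if (!any(cand)) return(cand)
  lab <- as.matrix(EBImage::bwlabel(cand))
  nr <- nrow(img); nc <- ncol(img)
  ok <- rep(TRUE, max(lab))
  for (k in seq_len(max(lab))) {
    pix <- which(lab == k)
    val <- img[pix[1]]
    rows <- ((pix - 1) %% nr) + 1
    cols <- ((pix - 1) %/% nr) + 1
    r0 <- max(1, min(rows) - 1); r1 <- min(nr, max(rows) + 1)
    c0 <- max(1, min(cols) - 1); c1 <- min(nc, max(cols) + 1)
    sub <- img[r0:r1, c0:c1, drop = FALSE]
    subm <- lab[r0:r1, c0:c1, drop = FALSE] == k
    grown <- as.matrix(EBImage::dilate(subm, EBImage::makeBrush(3, "box")))
    ring <- grown & !subm
    if (any(sub[ring] >= val - 1e-12)) ok[k] <- FALSE
  }
  lab > 0 & matrix(ok[pmax(lab, 1)], nrow(img)) & cand
}

#' Foreground (cell) markers
#'
#' Morphological marker pipeline on a \[0, 1\] reference image: opening with
#' a soma-scale disc, top-hat residual (image minus opening), erosion with
#' a radius-2 disc, regional maxima (above `marker_min_height`), then a
#' 3x3 erosion-dilation cleanup of the maxima mask. A maxima component the
#' cleanup would remove entirely (it is already below the cleanup scale)
#' is kept unchanged.
#'
#' @param image reference image scaled to \[0, 1\].
#' @param params a [seg_params()].
#' @return logical marker mask.
#' @export
foreground_markers <- function(image, params = seg_params()) {
  if (all(image == image[1])) return(matrix(FALSE, nrow(image), ncol(image)))
  opened <- as.matrix(EBImage::opening(image, disc_brush(params$marker_opening_radius)))
  tophat <- image - opened
  er <- as.matrix(EBImage::erode(tophat, disc_brush(params$erosion_disk_radius)))
  mx <- regional_maxima(er, params$marker_min_height)
  if (!any(mx)) return(mx)
  box <- EBImage::makeBrush(params$maxima_neighborhood, "box")
  lab <- as.matrix(EBImage::bwlabel(mx))
  cleaned <- as.matrix(EBImage::dilate(EBImage::erode(mx, box), box)) > 0
  surv <- unique(lab[cleaned & lab > 0])
  lost <- setdiff(seq_len(max(lab)), surv)
  out <- cleaned
  if (length(lost)) out[lab %in% lost] <- TRUE
  out
}

#' Background markers
#'
#' Foreground pixels are flattened to the image median (configurable),
#' the image is Otsu-binarized, and the Euclidean distance transform from
#' the foreground objects is flooded with the Meyer watershed; the
#' resulting ridge lines, dilated by a radius-2 disc, are the background
#' markers. Any overlap is removed from the foreground mask so the two
#' marker sets never touch. A degenerate (constant / unthresholdable)
#' image yields an all-border background marker with a warning.
#'
#' @param image reference image scaled to \[0, 1\].
#' @param fg_mask foreground marker mask (same shape).
#' @param params a [seg_params()].
#' @return list with `bg` (background mask) and `fg` (foreground mask with
#'   touching pixels removed).
#' @export
background_markers <- function(image, fg_mask, params = seg_params()) {
  stopifnot(all(dim(image) == dim(fg_mask)))
  img2 <- image
  fill <- if (params$fg_fill == "median") median(image) else mean(image)
  img2[fg_mask] <- fill
  rng <- range(img2)
  border_fallback <- function() {
    warning("degenerate image: using all-border background markers")
    bg <- matrix(FALSE, nrow(image), ncol(image))
    bg[1, ] <- TRUE; bg[nrow(bg), ] <- TRUE
    bg[, 1] <- TRUE; bg[, ncol(bg)] <- TRUE
    list(bg = bg & !fg_mask, fg = fg_mask & !bg)
  }
  if (rng[2] - rng[1] < 1e-12) return(border_fallback())
  th <- EBImage::otsu(EBImage::Image(img2), range = rng)
  bw <- img2 > th
  if (!any(bw) || all(bw)) return(border_fallback())
  dist <- as.matrix(EBImage::distmap(EBImage::Image(1 - bw)))
  seeds <- as.matrix(EBImage::bwlabel(bw))
  ws <- cpp_marker_watershed(dist, seeds)
  bg <- ws == 0
  bg <- as.matrix(EBImage::dilate(bg, disc_brush(params$background_dilation_radius))) > 0
  list(bg = bg, fg = fg_mask & !bg)
}

sobel_kernel <- matrix(c(1, 0, -1, 2, 0, -2, 1, 0, -1), nrow = 3)

#' Marker-controlled watershed segmentation
#'
#' The reference image is filtered with the Sobel horizontal
#' edge-emphasizing kernel and its transpose (replicate padding); the
#' gradient magnitude `sqrt(gx^2 + gy^2)` is flooded by the Meyer
#' watershed with minima imposed at the foreground and background
#' markers. The basin grown from the background markers and the watershed
#' lines are labeled 0; each foreground basin becomes one region.
#'
#' @param image reference image scaled to \[0, 1\].
#' @param fg_mask,bg_mask disjoint marker masks.
#' @param params a [seg_params()].
#' @return a `segmentation`: list with `labels` (integer matrix, 0 =
#'   background/watershed line), `centroids` (data frame `id`, `row`,
#'   `col`, `area_px`; 0-based pixel-centre coordinates, unweighted
#'   means) and `pixels` (list of pixel index vectors per region).
#' @export
watershed_segment <- function(image, fg_mask, bg_mask, params = seg_params()) {
  if (any(fg_mask & bg_mask)) stop("foreground and background markers overlap")
  empty <- function() structure(list(
    labels = matrix(0L, nrow(image), ncol(image)),
    centroids = data.frame(id = integer(0), row = numeric(0),
                           col = numeric(0), area_px = integer(0)),
    pixels = list()), class = "segmentation")
  if (!any(fg_mask)) return(empty())
  gx <- as.matrix(EBImage::filter2(image, sobel_kernel, boundary = "replicate"))
  gy <- as.matrix(EBImage::filter2(image, t(sobel_kernel), boundary = "replicate"))
  grad <- sqrt(gx^2 + gy^2)
  seeds <- as.matrix(EBImage::bwlabel(fg_mask))
  k <- max(seeds)
  bg_label <- k + 1L
  seeds[bg_mask] <- bg_label
  ws <- cpp_marker_watershed(grad, seeds)
  ws[ws == bg_label] <- 0L
  ids <- sort(unique(ws[ws > 0]))
  nr <- nrow(image)
  pixels <- lapply(ids, function(i) which(ws == i))
  cent <- t(vapply(pixels, function(pix) {
    rows <- ((pix - 1) %% nr)
    cols <- ((pix - 1) %/% nr)
    c(mean(rows), mean(cols), length(pix))
  }, numeric(3)))
  labels <- ws
  # relabel compactly 1..K
  if (length(ids) && !identical(ids, seq_along(ids))) {
    map <- integer(max(ids)); map[ids] <- seq_along(ids)
    labels[labels > 0] <- map[labels[labels > 0]]
  }
  structure(list(labels = labels,
                 centroids = data.frame(id = seq_along(ids),
                                        row = cent[, 1], col = cent[, 2],
                                        area_px = as.integer(cent[, 3])),
                 pixels = pixels),
            class = "segmentation")
}

#' @export
print.segmentation <- function(x, ...) {
  cat(sprintf("segmentation: %d regions\n", nrow(x$centroids)))
  invisible(x)
}

#' Segment a whole movie
#'
#' Convenience wrapper: [preprocess_frames()], then markers and
#' [watershed_segment()] per reference image.
#'
#' @param movie a `fluorescence_movie` or 3-d array.
#' @param params a [seg_params()].
#' @return list of `segmentation` objects, attribute `blocks` as in
#'   [preprocess_frames()].
#' @export
segment_movie <- function(movie, params = seg_params()) {
  refs <- preprocess_frames(movie, params)
  out <- vector("list", length(refs))
  for (b in seq_along(refs)) {
    fg <- foreground_markers(refs[[b]], params)
    mk <- background_markers(refs[[b]], fg, params)
    out[[b]] <- watershed_segment(refs[[b]], mk$fg, mk$bg, params)
  }
  attr(out, "blocks") <- attr(refs, "blocks")
  out
}
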