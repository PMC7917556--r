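## ROI detection on fluorescence movie stacks: baseline-subtracted response
## images, maximum-entropy thresholding, watershed labeling, background
## region placement, and best-plane selection.

#' Baseline-subtracted response image
#'
#' Pixelwise `mean(response frames) - mean(baseline frames)`; the standard
#' input of ROI detection (baseline = 15 pre-stimulus frames, response = 5
#' frames during/after stimulation by default in the pipeline).
#'
#' @param movie array `[row, col, frame]`.
#' @param baseline_frames,response_frames integer frame indices; must be
#'   non-empty, within range and disjoint.
#' @return object of class `delta_f_image`: the matrix with the two windows
#'   attached as attributes.
#' @export
delta_f_image <- function(movie, baseline_frames, response_frames) {
  nf <- dim(movie)[3]
  if (length(baseline_frames) < 1 || length(response_frames) < 1)
    stop("window error: window shorter than 1 frame")
  if (any(c(baseline_frames, response_frames) < 1) ||
      any(c(baseline_frames, response_frames) > nf))
    stop("window error: window outside frame range")
  if (length(intersect(baseline_frames, response_frames)) > 0)
    stop("window error: baseline and response windows overlap")
  f0 <- apply(movie[, , baseline_frames, drop = FALSE], c(1, 2), mean)
  f1 <- apply(movie[, , response_frames, drop = FALSE], c(1, 2), mean)
  structure(f1 - f0, class = c("delta_f_image", "matrix"),
            baseline_frames = baseline_frames,
            response_frames = response_frames)
}

#' Maximum-entropy (Kapur) threshold
#'
#' Returns the gray level that maximizes the sum of Shannon entropies of the
#' foreground and background parts of the normalized 256-bin histogram
#' (Kapur's criterion). The image is linearly mapped onto the bins; the
#' returned threshold is on the original intensity scale, and pixels strictly
#' above it are foreground.
#'
#' @param image numeric matrix with at least two distinct values.
#' @param n_bins histogram resolution (default 256).
#' @return threshold intensity (scalar).
#' @export
max_entropy_threshold <- function(image, n_bins = 256) {
  x <- as.numeric(image)
  rng <- range(x, finite = TRUE)
  if (diff(rng) == 0)
    stop("degenerate histogram: constant image")
  bin <- pmin(floor((x - rng[1]) / diff(rng) * n_bins) + 1L, n_bins)
  h <- tabulate(bin, nbins = n_bins)
  p <- h / sum(h)
  P <- cumsum(p)
  ent_term <- ifelse(p > 0, p * log(p), 0)
  E <- cumsum(ent_term)
  Etot <- E[n_bins]
  # candidate thresholds t: background bins 1..t, foreground t+1..n
  t_idx <- which(P > 0 & P < 1)
  if (length(t_idx) == 0)
    stop("degenerate histogram: no separable threshold")
  Hb <- log(P[t_idx]) - E[t_idx] / P[t_idx]
  Hf <- log(1 - P[t_idx]) - (Etot - E[t_idx]) / (1 - P[t_idx])
  best <- t_idx[which.max(Hb + Hf)]
  # upper edge of the best background bin, mapped back to intensity units
  rng[1] + best / n_bins * diff(rng)
}

#' Detect ROIs on a response image
#'
#' Filter (median or Gaussian), maximum-entropy threshold, then watershed on
#' the masked filtered intensity surface to split touching objects; regions
#' below `min_area_px` are dropped. Watersheding the intensity surface
#' (rather than the distance transform of the mask) separates overlapping
#' spots whose union is convex, as long as their intensity profile is
#' bimodal. The returned label image is a stable mask intended to be
#' generated once per cell (from the strongest stimulation) and reused for
#' all recordings.
#'
#' @param dF a [delta_f_image()] or plain numeric matrix.
#' @param filter list with `kind` (`"median"` or `"gaussian"`) and
#'   `size_or_sigma` (median footprint side in px, 4-6 typical; or Gaussian
#'   sigma, 1-3 typical).
#' @param min_area_px minimum ROI area in pixels (default 20).
#' @param watershed_ext neighborhood radius (px) for watershed seed detection;
#'   local maxima closer than this merge into one marker.
#' @param watershed_tol seed tolerance as a fraction of the suprathreshold
#'   intensity range; bumps shallower than this do not found their own ROI.
#' @return object of class `roi_set`: list with `label_image` (integer matrix,
#'   0 = background), `rois` (data.frame: id, centroid_x, centroid_y, area_px,
#'   best_plane (NA until assigned)), `threshold`, `filtered`.
#'   An image with no suprathreshold pixels yields an empty (zero-ROI) set.
#' @export
detect_rois <- function(dF, filter = list(kind = "median", size_or_sigma = 5),
                        min_area_px = 20, watershed_ext = 2,
                        watershed_tol = 0.1) {
  img <- unclass(dF)
  filt <- switch(filter$kind,
    median = {
      sz <- max(1L, floor(filter$size_or_sigma / 2))
      rng <- range(img)
      if (diff(rng) == 0) img else {
        scaled <- (img - rng[1]) / diff(rng)
        as.matrix(EBImage::medianFilter(scaled, size = sz)) *
          diff(rng) + rng[1]
      }
    },
    gaussian = as.matrix(EBImage::gblur(img, sigma = filter$size_or_sigma)),
    stop("unknown filter kind: ", filter$kind))
  if (diff(range(filt)) == 0)
    return(empty_roi_set(dim(img)))
  thr <- max_entropy_threshold(filt)
  mask <- filt > thr
  if (!any(mask))
    return(empty_roi_set(dim(img), threshold = thr, filtered = filt))
  surface <- (filt - thr) * mask
  tol <- watershed_tol * max(surface)
  lab <- EBImage::watershed(EBImage::Image(surface), tolerance = tol,
                            ext = watershed_ext)
  lab <- as.matrix(EBImage::imageData(lab))
  # drop small regions and relabel compactly
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area_px)
  relab <- integer(length(areas))
  relab[keep] <- seq_along(keep)
  lab[lab > 0] <- relab[lab[lab > 0]]
  rois <- roi_table(lab)
  structure(list(label_image = lab, rois = rois, threshold = thr,
                 filtered = filt),
            class = "roi_set")
}

empty_roi_set <- function(dims, threshold = NA_real_, filtered = NULL) {
  structure(list(label_image = matrix(0L, dims[1], dims[2]),
                 rois = roi_table(matrix(0L, dims[1], dims[2])),
                 threshold = threshold, filtered = filtered),
            class = "roi_set")
}

roi_table <- function(lab) {
  ids <- setdiff(sort(unique(as.integer(lab))), 0L)
  if (length(ids) == 0)
    return(data.frame(id = integer(), centroid_x = numeric(),
                      centroid_y = numeric(), area_px = integer(),
                      best_plane = integer()))
  rows <- lapply(ids, function(i) {
    px <- which(lab == i, arr.ind = TRUE)
    data.frame(id = i, centroid_x = mean(px[, 2]), centroid_y = mean(px[, 1]),
               area_px = nrow(px), best_plane = NA_integer_)
  })
  do.call(rbind, rows)
}

#' Place the background-estimation region
#'
#' A 60 x 60 px rectangle at the pillar-side edge of the frame (centered
#' vertically), shifted along that edge if necessary so that it does not
#' overlap any ROI. The per-frame mean over this region defines the
#' background trace.
#'
#' @param frame_dim `c(rows, cols)` of the movie frames (must be >= 60 x 60).
#' @param label_image optional ROI label image to avoid (0 = free).
#' @param anchor which edge is the pillar side: `"left"`, `"right"`, `"top"`,
#'   `"bottom"`.
#' @param size region side length, px.
#' @return list with integer vectors `rows` and `cols` (inclusive index
#'   ranges).
#' @export
background_region <- function(frame_dim, label_image = NULL,
                              anchor = c("left", "right", "top", "bottom"),
                              size = 60) {
  anchor <- match.arg(anchor)
  nr <- frame_dim[1]; nc <- frame_dim[2]
  if (nr < size || nc < size)
    stop("size error: frame smaller than background region")
  along_n <- if (anchor %in% c("left", "right")) nr else nc
  start0 <- max(1L, floor((along_n - size) / 2) + 1L)
  candidates <- unique(c(start0, seq(1L, along_n - size + 1L)))
  for (s in candidates) {
    rows <- if (anchor == "left") s:(s + size - 1L)
            else if (anchor == "right") s:(s + size - 1L)
            else if (anchor == "top") 1:size
            else (nr - size + 1L):nr
    cols <- if (anchor == "left") 1:size
            else if (anchor == "right") (nc - size + 1L):nc
            else s:(s + size - 1L)
    if (is.null(label_image) || all(label_image[rows, cols] == 0))
      return(list(rows = rows, cols = cols))
  }
  stop("no ROI-free background region found along the ", anchor, " edge")
}

#' Select the best imaging plane for an ROI
#'
#' Argmax over planes of the ROI-mean baseline-subtracted response; exact ties
#' are broken toward the central plane.
#'
#' @param stacks list of per-plane movies `[row, col, frame]`.
#' @param roi_pixels logical matrix or integer matrix of pixel indices
#'   (`arr.ind` style) selecting the ROI.
#' @param baseline_frames,response_frames frame windows passed to
#'   [delta_f_image()].
#' @return integer plane index (1-based).
#' @export
best_plane <- function(stacks, roi_pixels, baseline_frames, response_frames) {
  stopifnot(length(stacks) >= 1)
  score <- vapply(stacks, function(mov) {
    dF <- delta_f_image(mov, baseline_frames, response_frames)
    mean(unclass(dF)[roi_pixels])
  }, numeric(1))
  central <- (length(stacks) + 1) / 2
  best <- which(score == max(score))
  if (length(best) > 1) best <- best[which.min(abs(best - central))]
  as.integer(best)
}

#' Mean fluorescence trace over an ROI
#'
#' @param movie array `[row, col, frame]`.
#' @param roi_pixels logical matrix (same frame geometry) or two-column index
#'   matrix selecting the ROI pixels.
#' @return numeric vector, one value per frame.
#' @export
roi_trace <- function(movie, roi_pixels) {
  nf <- dim(movie)[3]
  vapply(seq_len(nf), function(k) mean(movie[, , k][roi_pixels]), numeric(1))
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("ROI set: %d regions (threshold %.3g)\n",
              nrow(x$rois), x$threshold))
  if (nrow(x$rois) > 0) print(x$rois, row.names = FALSE)
  invisible(x)
}
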