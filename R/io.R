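## Plain-text / TIFF round-trips for movies, ROI tables, traces, protocols
## and fit records.

#' Write a movie stack as multi-page TIFF
#'
#' Intensities are stored as 16-bit (scaled by `scale`); one page per frame.
#'
#' @param movie array `[row, col, frame]`.
#' @param path output file.
#' @param scale divisor mapping intensities into [0, 1] for 16-bit storage
#'   (default: the movie maximum).
#' @return `path`, invisibly; the scale used is written alongside as
#'   `<path>.scale.json` so the round-trip is lossless up to quantization.
#' @export
write_movie_tiff <- function(movie, path, scale = NULL) {
  if (is.null(scale)) scale <- max(movie, 1e-12)
  frames <- lapply(seq_len(dim(movie)[3]), function(k)
    pmin(pmax(movie[, , k] / scale, 0), 1))
  tiff::writeTIFF(frames, path, bits.per.sample = 16L)
  jsonlite::write_json(list(scale = scale), paste0(path, ".scale.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a movie stack written by [write_movie_tiff()]
#'
#' @param path TIFF file.
#' @return array `[row, col, frame]` on the original intensity scale.
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE)
  scale_file <- paste0(path, ".scale.json")
  scale <- if (file.exists(scale_file))
    jsonlite::read_json(scale_file)$scale else 1
  arr <- array(0, c(dim(frames[[1]])[1:2], length(frames)))
  for (k in seq_along(frames)) arr[, , k] <- frames[[k]] * scale
  arr
}

#' Write an ROI label image (16-bit TIFF) and table (CSV)
#'
#' @param roiset a [detect_rois()] result.
#' @param label_path,table_path output files (`NULL` to skip either).
#' @return invisibly, the paths written.
#' @export
write_roi_set <- function(roiset, label_path = NULL, table_path = NULL) {
  if (!is.null(label_path))
    tiff::writeTIFF(roiset$label_image / 65535, label_path,
                    bits.per.sample = 16L)
  if (!is.null(table_path))
    utils::write.csv(roiset$rois, table_path, row.names = FALSE)
  invisible(c(label_path, table_path))
}

#' Trace round-trip as CSV (time_s, value, stage)
#'
#' @param trace an `fl_trace`.
#' @param path CSV file.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  df <- data.frame(time_s = (seq_along(trace$samples) - 1) / trace$rate_Hz,
                   value = trace$samples, stage = trace$stage)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a trace CSV written by [write_trace_csv()]
#'
#' @param path CSV file.
#' @param baseline_window,stim_onset_index trace annotations (not stored in
#'   the CSV).
#' @return an `fl_trace`.
#' @export
read_trace_csv <- function(path, baseline_window = NULL,
                           stim_onset_index = NULL) {
  df <- utils::read.csv(path)
  rate <- 1 / stats::median(diff(df$time_s))
  args <- list(samples = df$value, rate_Hz = rate,
               stage = as.character(df$stage[1]))
  if (!is.null(baseline_window)) args$baseline_window <- baseline_window
  if (!is.null(stim_onset_index)) args$stim_onset_index <- stim_onset_index
  do.call(fl_trace, args)
}

#' Protocol round-trip as JSON
#'
#' @param protocol a [make_protocol()] object.
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_protocol_json <- function(protocol, path) {
  jsonlite::write_json(unclass(protocol), path, auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_protocol_json
#' @export
read_protocol_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (x$kind == "step")
    make_protocol("step", levels_mV = x$levels_mV,
                  duration_ms = x$duration_ms, holding_mV = x$holding_mV,
                  seed = x$seed)
  else
    make_protocol("ramp", holding_mV = x$holding_mV,
                  ramp_range_mV = x$ramp_range_mV,
                  ramp_rate_mV_per_ms = x$ramp_rate_mV_per_ms,
                  seed = x$seed)
}

#' Ground truth round-trip as JSON
#'
#' @param gt a [sample_ground_truth()] object.
#' @param path JSON file.
#' @return `path`, invisibly.
#' @export
write_ground_truth_json <- function(gt, path) {
  jsonlite::write_json(list(synapses = gt$synapses, ellipse = gt$ellipse,
                            cell = gt$cell, seed = gt$seed),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
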