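#' Write / read a trace set as CSV + JSON sidecar
#'
#' Traces go to a long-format CSV (`neuron`, `frame`, `value`; zero frames
#' omitted, which suits sparse deconvolved traces), ROIs to a second CSV, and
#' frame rate plus protocol to a JSON sidecar. Intended for modest fixtures
#' and pipeline outputs, not bulk storage.
#'
#' @param traces a `trace_set`.
#' @param dir output directory (created if needed).
#' @param name file stem.
#' @return `read_traceset` returns the reconstructed `trace_set`.
#' @export
write_traceset <- function(traces, dir, name = "traces") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sp <- traces$spike_prob
  nz <- which(sp != 0, arr.ind = TRUE)
  long <- data.frame(neuron = nz[, 1], frame = nz[, 2], value = sp[nz])
  long <- long[order(long$neuron, long$frame), ]
  utils::write.csv(long, file.path(dir, paste0(name, ".csv")), row.names = FALSE)
  utils::write.csv(traces$rois, file.path(dir, paste0(name, "_rois.csv")),
                   row.names = FALSE)
  write_protocol(traces$protocol, file.path(dir, paste0(name, "_protocol.json")))
  jsonlite::write_json(list(frame_rate_hz = traces$frame_rate_hz,
                            n_neurons = nrow(sp), n_frames = ncol(sp)),
                       file.path(dir, paste0(name, "_meta.json")),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @rdname write_traceset
#' @export
read_traceset <- function(dir, name = "traces") {
  meta <- jsonlite::read_json(file.path(dir, paste0(name, "_meta.json")),
                              simplifyVector = TRUE)
  long <- utils::read.csv(file.path(dir, paste0(name, ".csv")))
  rois <- utils::read.csv(file.path(dir, paste0(name, "_rois.csv")))
  proto <- read_protocol(file.path(dir, paste0(name, "_protocol.json")))
  sp <- matrix(0, meta$n_neurons, meta$n_frames)
  sp[cbind(long$neuron, long$frame)] <- long$value
  structure(list(spike_prob = sp, frame_rate_hz = meta$frame_rate_hz,
                 protocol = proto, rois = rois), class = "trace_set")
}

#' Write / read a widefield movie as multi-page TIFF
#'
#' Float32 TIFF, one page per frame, with the schedule in a JSON file next
#' to it. Requires the `tiff` package.
#'
#' @param movie a `widefield_movie` (or plain `H x W x T` array).
#' @param path TIFF path; schedule goes to `<path>.schedule.json`.
#' @return `read_widefield_tiff` returns the `H x W x T` array.
#' @export
write_widefield_tiff <- function(movie, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF output")
  px <- if (inherits(movie, "widefield_movie")) movie$pixels else movie
  sc <- max(px)
  pages <- lapply(seq_len(dim(px)[3]), function(t) px[, , t] / sc)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  if (inherits(movie, "widefield_movie"))
    write_protocol(movie$schedule, paste0(path, ".schedule.json"))
  jsonlite::write_json(list(scale = sc), paste0(path, ".scale.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_widefield_tiff
#' @export
read_widefield_tiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required for TIFF input")
  pages <- tiff::readTIFF(path, all = TRUE)
  sc <- jsonlite::read_json(paste0(path, ".scale.json"), simplifyVector = TRUE)$scale
  arr <- array(0, c(dim(pages[[1]]), length(pages)))
  for (t in seq_along(pages)) arr[, , t] <- pages[[t]] * sc
  arr
}

#' Write a best-frequency map as CSV grids
#'
#' @param bfmap a `bf_map` (matrix form).
#' @param dir output directory.
#' @param name file stem.
#' @export
write_bf_map <- function(bfmap, dir, name = "bf_map") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(bfmap$bf_oct, file.path(dir, paste0(name, "_oct.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(bfmap$amplitude, file.path(dir, paste0(name, "_amp.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.table(bfmap$responsive_mask * 1L,
                     file.path(dir, paste0(name, "_mask.csv")),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(dir)
}
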