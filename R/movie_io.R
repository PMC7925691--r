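#' Write / read a frame stack as multi-page TIFF with a JSON sidecar
#'
#' Frames are scaled into `[0, 1]` for TIFF storage; the scale and offset,
#' together with frame rate, pixel size, direction and stimulus timing, go
#' to `<path>.json` so the stack round-trips numerically (to 16-bit
#' precision). Requires the `tiff` package.
#'
#' @param stack A [frame_stack()].
#' @param path TIFF file path.
#' @return `write_frame_stack()` returns `path` invisibly;
#'   `read_frame_stack()` returns a [frame_stack()].
#' @export
write_frame_stack <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The `tiff` package is required for TIFF I/O.")
  }
  d <- stack$data
  lo <- min(d)
  hi <- max(d)
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(dim(d)[1]), function(t) (d[t, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16)
  meta <- list(frame_rate_hz = stack$frame_rate,
               um_per_pixel = stack$pixel_size,
               direction_deg = stack$direction,
               trial_id = stack$trial_id,
               stim_onset_s = stack$stim_onset,
               value_offset = lo, value_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_frame_stack
#' @export
read_frame_stack <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE)) {
    abort("The `tiff` package is required for TIFF I/O.")
  }
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- jsonlite::read_json(paste0(path, ".json"))
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (t in seq_along(pages)) {
    arr[t, , ] <- pages[[t]] * meta$value_scale + meta$value_offset
  }
  frame_stack(arr, meta$frame_rate_hz, meta$um_per_pixel,
              direction = meta$direction_deg %||% NA,
              trial_id = meta$trial_id %||% NA,
              stim_onset = meta$stim_onset_s %||% NA)
}
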