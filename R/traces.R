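#' Construct a membrane-current trace
#'
#' A `current_trace` is a tibble with columns `time_s` and `current_pA`
#' carrying the sampling rate and recording metadata as attributes. By
#' convention the stored current is the *positive magnitude* of the inward
#' (excitatory) deflection: raw voltage-clamp recordings held at -60 mV show
#' EPSCs as negative-going currents and are sign-flipped at load time, so
#' that every quantal event appears as an upward transient and all reported
#' amplitudes are positive.
#'
#' @param current_pA Numeric vector of current samples (pA, positive-up
#'   EPSC convention).
#' @param sample_rate Sampling rate in Hz (typically 10000 for patch-clamp
#'   recordings digitized at 10 kHz).
#' @param cell_id Optional cell identifier.
#' @param condition Recording condition label, e.g. `"spontaneous"` or
#'   `"asynchronous"`.
#'
#' @return A tibble of class `current_trace` with columns `time_s`,
#'   `current_pA`.
#' @export
#' @examples
#' tr <- current_trace(rnorm(1000), sample_rate = 10000)
#' trace_sample_rate(tr)
current_trace <- function(current_pA, sample_rate, cell_id = NA_character_,
                          condition = "spontaneous") {
  if (!is.numeric(current_pA) || anyNA(current_pA) || any(!is.finite(current_pA))) {
    abort("`current_pA` must be a finite numeric vector.")
  }
  if (!is.numeric(sample_rate) || length(sample_rate) != 1L || sample_rate <= 0) {
    abort("`sample_rate` must be a single positive number (Hz).")
  }
  out <- tibble(
    time_s = seq_along(current_pA) / sample_rate - 1 / sample_rate,
    current_pA = as.numeric(current_pA)
  )
  attr(out, "sample_rate_hz") <- sample_rate
  attr(out, "cell_id") <- cell_id
  attr(out, "condition") <- condition
  class(out) <- c("current_trace", class(out))
  out
}

#' Sampling rate of a current trace
#' @param trace A [current_trace()].
#' @return Sampling rate in Hz.
#' @export
trace_sample_rate <- function(trace) {
  sr <- attr(trace, "sample_rate_hz")
  if (is.null(sr)) abort("Object has no `sample_rate_hz` attribute; is it a current_trace?")
  sr
}

trace_cell_id <- function(trace) {
  id <- attr(trace, "cell_id")
  if (is.null(id)) NA_character_ else id
}

# rebuild a trace with new samples, keeping metadata
trace_with_samples <- function(trace, samples) {
  current_trace(samples, trace_sample_rate(trace),
                cell_id = attr(trace, "cell_id"),
                condition = attr(trace, "condition"))
}

#' Write / read a current trace as CSV with a JSON sidecar
#'
#' The CSV holds two columns (`time_s`, `current_pA`); sampling rate and
#' metadata go to `<path>.json` so the trace round-trips exactly.
#'
#' @param trace A [current_trace()].
#' @param path CSV file path.
#' @return `write_trace_csv()` returns `path` invisibly; `read_trace_csv()`
#'   returns a [current_trace()].
#' @export
write_trace_csv <- function(trace, path) {
  utils::write.csv(as.data.frame(trace[, c("time_s", "current_pA")]),
                   path, row.names = FALSE)
  meta <- list(sample_rate_hz = trace_sample_rate(trace),
               cell_id = trace_cell_id(trace),
               condition = attr(trace, "condition"))
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_trace_csv
#' @export
read_trace_csv <- function(path) {
  df <- utils::read.csv(path)
  meta_path <- paste0(path, ".json")
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path)
    sr <- meta$sample_rate_hz
    cell <- meta$cell_id %||% NA_character_
    cond <- meta$condition %||% "spontaneous"
  } else {
    # infer the rate from the time column
    sr <- 1 / stats::median(diff(df$time_s))
    cell <- NA_character_
    cond <- "spontaneous"
  }
  current_trace(df$current_pA, sr, cell_id = cell, condition = cond)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf("<current_trace> %d samples @ %g Hz (%.2f s), cell %s\n",
              nrow(x), trace_sample_rate(x), nrow(x) / trace_sample_rate(x),
              trace_cell_id(x)))
  NextMethod()
}
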