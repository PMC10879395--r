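#' Construct an LFP recording
#'
#' The universal input container of the package: a uniformly sampled
#' extracellular voltage trace with its sampling rate. All analysis
#' functions accept this object.
#'
#' @param samples Numeric vector of voltages (microvolts). Must be finite
#'   and of length at least 2.
#' @param sampling_rate Sampling rate in Hz (positive).
#' @param start_time Time of the first sample in seconds. Default 0.
#' @param label Free-text label carried through to outputs.
#'
#' @return An object of class `lfp_recording`: a list with elements
#'   `samples`, `sampling_rate`, `start_time`, `label`.
#'
#' @details Time is measured in seconds from the recording start; sample
#'   `i` (1-based) covers the half-open interval
#'   `[start_time + (i-1)/fs, start_time + i/fs)`.
#'
#' @examples
#' rec <- lfp_recording(sin(2 * pi * 8 * seq(0, 2, by = 1e-3)), 1000)
#' lfp_duration(rec)
#' @export
lfp_recording <- function(samples, sampling_rate, start_time = 0, label = "") {
  samples <- as.numeric(samples)
  if (length(samples) < 2) {
    abort("`samples` must contain at least 2 values.", class = "ripplepac_validation_error")
  }
  if (!all(is.finite(samples))) {
    abort("`samples` must be finite (no NA/NaN/Inf).", class = "ripplepac_validation_error")
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1 ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    abort("`sampling_rate` must be a single positive number (Hz).",
          class = "ripplepac_validation_error")
  }
  structure(
    list(samples = samples, sampling_rate = as.numeric(sampling_rate),
         start_time = as.numeric(start_time), label = as.character(label)),
    class = "lfp_recording"
  )
}

#' @export
print.lfp_recording <- function(x, ...) {
  cat(sprintf("<lfp_recording> %s%d samples @ %g Hz (%.3f s)\n",
              if (nzchar(x$label)) paste0(x$label, ": ") else "",
              length(x$samples), x$sampling_rate, lfp_duration(x)))
  invisible(x)
}

#' Duration of a recording in seconds
#' @param recording An [lfp_recording()].
#' @return Duration in seconds (`n_samples / sampling_rate`).
#' @export
lfp_duration <- function(recording) {
  stopifnot(inherits(recording, "lfp_recording"))
  length(recording$samples) / recording$sampling_rate
}

#' @exportS3Method tibble::as_tibble
as_tibble.lfp_recording <- function(x, ...) {
  tibble(
    time_s = x$start_time + (seq_along(x$samples) - 1) / x$sampling_rate,
    voltage_uv = x$samples
  )
}

#' Sample-time vector of a recording
#' @param recording An [lfp_recording()].
#' @return Numeric vector of sample times in seconds.
#' @export
lfp_times <- function(recording) {
  recording$start_time + (seq_along(recording$samples) - 1) / recording$sampling_rate
}
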