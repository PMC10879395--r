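#' Read an LFP recording from disk
#'
#' Two language-neutral formats are supported:
#' \describe{
#'   \item{`csv`}{Comma-separated, `.` decimal, mandatory header row.
#'     Metadata (`sampling_rate`, optionally `start_time`, `label`) is
#'     carried in `# key=value` comment lines before the header. A
#'     `time_s` column, when present, must be regular and consistent with
#'     the declared sampling rate; the voltage column is `voltage_uv`.}
#'   \item{`f32bin`}{Flat little-endian IEEE-754 float32 samples plus a
#'     mandatory JSON sidecar `<path>.json` holding at least
#'     `sampling_rate`.}
#' }
#'
#' @param path Path to the data file.
#' @param format `"csv"` or `"f32bin"`. Default guesses from the file
#'   extension (`.csv` vs anything else).
#' @return A validated [lfp_recording()].
#' @export
read_lfp <- function(path, format = c("auto", "csv", "f32bin")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "f32bin"
  }
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "ripplepac_io_error")
  }
  if (format == "csv") read_lfp_csv(path) else read_lfp_f32bin(path)
}

read_lfp_csv <- function(path) {
  lines <- readLines(path, n = 50L)
  meta <- parse_meta_comments(lines)
  if (is.null(meta$sampling_rate)) {
    abort("CSV recording lacks a `# sampling_rate=` metadata line.",
          class = "ripplepac_format_error")
  }
  fs <- as.numeric(meta$sampling_rate)
  df <- utils::read.csv(path, comment.char = "#")
  vcol <- if ("voltage_uv" %in% names(df)) "voltage_uv" else setdiff(names(df), "time_s")[1]
  if (is.null(vcol) || is.na(vcol)) {
    abort("CSV recording has no voltage column.", class = "ripplepac_format_error")
  }
  samples <- as.numeric(df[[vcol]])
  if (!all(is.finite(samples))) {
    abort("CSV recording contains non-finite samples.",
          class = "ripplepac_validation_error")
  }
  start_time <- as.numeric(meta$start_time %||% 0)
  if ("time_s" %in% names(df)) {
    tt <- as.numeric(df$time_s)
    dt <- diff(tt)
    if (any(dt <= 0) || (length(dt) > 0 && max(abs(dt - 1 / fs)) > 1e-6 / fs + 1e-9)) {
      abort("CSV time column is non-monotonic or inconsistent with sampling_rate.",
            class = "ripplepac_validation_error")
    }
    start_time <- tt[1]
  }
  lfp_recording(samples, fs, start_time = start_time,
                label = meta$label %||% "")
}

read_lfp_f32bin <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0("Missing JSON sidecar: ", sidecar),
          class = "ripplepac_format_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  if (is.null(meta$sampling_rate)) {
    abort("Sidecar lacks `sampling_rate`.", class = "ripplepac_format_error")
  }
  n <- file.size(path) / 4L
  samples <- readBin(path, what = "numeric", n = n, size = 4L, endian = "little")
  if (!all(is.finite(samples))) {
    abort("Binary recording contains non-finite samples.",
          class = "ripplepac_validation_error")
  }
  lfp_recording(samples, as.numeric(meta$sampling_rate),
                start_time = as.numeric(meta$start_time %||% 0),
                label = as.character(meta$label %||% ""))
}

#' Write an LFP recording to disk
#'
#' @param recording An [lfp_recording()].
#' @param path Output path.
#' @param format `"csv"` (text, with `# key=value` metadata lines) or
#'   `"f32bin"` (float32 binary plus JSON sidecar `<path>.json`).
#' @return Invisibly, `path`.
#' @export
write_lfp <- function(recording, path, format = c("csv", "f32bin")) {
  format <- match.arg(format)
  stopifnot(inherits(recording, "lfp_recording"))
  if (format == "csv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("# sampling_rate=%.10g", recording$sampling_rate),
      sprintf("# start_time=%.10g", recording$start_time),
      sprintf("# label=%s", recording$label),
      "voltage_uv"
    ), con)
    writeLines(sprintf("%.9g", recording$samples), con)
  } else {
    writeBin(recording$samples, path, size = 4L, endian = "little")
    jsonlite::write_json(
      list(sampling_rate = recording$sampling_rate,
           start_time = recording$start_time,
           label = recording$label,
           n_samples = length(recording$samples),
           dtype = "float32-le"),
      paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

parse_meta_comments <- function(lines) {
  meta_lines <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (ln in meta_lines) {
    m <- regmatches(ln, regexec("^#\\s*([A-Za-z_][A-Za-z0-9_]*)\\s*=\\s*(.*)$", ln))[[1]]
    if (length(m) == 3) meta[[m[2]]] <- trimws(m[3])
  }
  meta
}

#' Write detected SWR events with provenance
#'
#' Writes the event table as CSV (columns `onset_s`, `offset_s`, `peak_s`,
#' `duration_ms`, `peak_z`) plus a JSON sidecar `<path>.json` recording the
#' detection parameters that produced them (band, threshold_sd,
#' min_duration_ms, baseline), the analyzed immobility time and incidence.
#'
#' @param result An `swr_result` from [detect_swr()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_events <- function(result, path) {
  stopifnot(inherits(result, "swr_result"))
  utils::write.csv(as.data.frame(result$events), path, row.names = FALSE)
  jsonlite::write_json(
    list(
      band_low_hz = result$params$band[1],
      band_high_hz = result$params$band[2],
      threshold_sd = result$params$threshold_sd,
      min_duration_ms = result$params$min_duration_ms,
      boundary_def = result$params$boundary_def,
      baseline_uv = result$baseline,
      envelope_sd_uv = result$envelope_sd,
      analyzed_time_s = result$analyzed_time_s,
      incidence_hz = result$incidence_hz,
      n_events = nrow(result$events),
      n_discarded = result$n_discarded
    ),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read back an SWR event table written by [write_events()]
#'
#' @param path Path to the events CSV; the JSON sidecar `<path>.json` must
#'   exist and carry complete detection provenance.
#' @return An `swr_result` object.
#' @export
read_events <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Events file not found: ", path), class = "ripplepac_io_error")
  }
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    abort(paste0("Missing events sidecar: ", sidecar),
          class = "ripplepac_provenance_error")
  }
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  needed <- c("band_low_hz", "band_high_hz", "threshold_sd", "min_duration_ms")
  missing <- setdiff(needed, names(meta))
  if (length(missing) > 0) {
    abort(paste0("Events sidecar lacks provenance field(s): ",
                 paste(missing, collapse = ", ")),
          class = "ripplepac_provenance_error")
  }
  df <- utils::read.csv(path)
  events <- as_tibble(df[, c("onset_s", "offset_s", "peak_s", "duration_ms", "peak_z"),
                         drop = FALSE])
  new_swr_result(
    events = events,
    params = swr_params(band = c(meta$band_low_hz, meta$band_high_hz),
                        threshold_sd = meta$threshold_sd,
                        min_duration_ms = meta$min_duration_ms),
    analyzed_time_s = meta$analyzed_time_s %||% NA_real_,
    baseline = meta$baseline_uv %||% NA_real_,
    envelope_sd = meta$envelope_sd_uv %||% NA_real_,
    n_discarded = meta$n_discarded %||% 0L
  )
}
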