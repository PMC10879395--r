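#' Construct an immobility interval mask
#'
#' A set of half-open time intervals `[start_s, end_s)` in seconds,
#' typically marking periods of extended immobility to which SWR analysis
#' is confined. Intervals are validated, sorted, and intervals that touch
#' (`end == next start`) are merged; overlapping intervals are an error.
#'
#' @param start_s,end_s Numeric vectors of interval starts and ends
#'   (seconds), equal length.
#' @return A tibble of class `interval_mask` with columns `start_s`,
#'   `end_s`.
#' @examples
#' m <- interval_mask(c(0, 10), c(5, 20))
#' mask_duration(m)
#' @export
interval_mask <- function(start_s, end_s) {
  start_s <- as.numeric(start_s)
  end_s <- as.numeric(end_s)
  if (length(start_s) != length(end_s)) {
    abort("`start_s` and `end_s` must have equal length.",
          class = "ripplepac_validation_error")
  }
  if (length(start_s) == 0) {
    out <- tibble(start_s = numeric(), end_s = numeric())
    class(out) <- c("interval_mask", class(out))
    return(out)
  }
  if (!all(is.finite(start_s)) || !all(is.finite(end_s))) {
    abort("Mask intervals must be finite.", class = "ripplepac_validation_error")
  }
  if (any(end_s <= start_s)) {
    abort("Each interval must satisfy start < end.",
          class = "ripplepac_validation_error")
  }
  ord <- order(start_s)
  start_s <- start_s[ord]; end_s <- end_s[ord]
  if (any(start_s[-1] < end_s[-length(end_s)])) {
    abort("Mask intervals must not overlap.", class = "ripplepac_validation_error")
  }
  # merge touching intervals [a,b) + [b,c) -> [a,c)
  keep_start <- c(TRUE, start_s[-1] > end_s[-length(end_s)])
  grp <- cumsum(keep_start)
  out <- tibble(
    start_s = as.numeric(tapply(start_s, grp, min)),
    end_s = as.numeric(tapply(end_s, grp, max))
  )
  class(out) <- c("interval_mask", class(out))
  out
}

#' Total duration covered by a mask
#' @param mask An [interval_mask()].
#' @return Total seconds covered (sum of interval lengths).
#' @export
mask_duration <- function(mask) {
  sum(mask$end_s - mask$start_s)
}

#' Read an interval mask from CSV
#'
#' Expects a two-column CSV with header `start_s,end_s`. Lines beginning
#' with `#` are treated as metadata comments and skipped.
#'
#' @param path Path to the CSV file.
#' @return A validated [interval_mask()].
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Mask file not found: ", path), class = "ripplepac_io_error")
  }
  df <- utils::read.csv(path, comment.char = "#")
  if (!all(c("start_s", "end_s") %in% names(df))) {
    abort("Mask CSV must have columns start_s,end_s.",
          class = "ripplepac_format_error")
  }
  interval_mask(df$start_s, df$end_s)
}

#' Write an interval mask to CSV
#' @param mask An [interval_mask()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mask <- function(mask, path) {
  utils::write.csv(as.data.frame(mask), path, row.names = FALSE)
  invisible(path)
}

#' Clip a mask to a recording's span
#'
#' Binds a mask to a recording: intervals are intersected with
#' `[start_time, start_time + duration)` and empty remainders dropped, so
#' the bound mask never reports more covered time than the recording holds.
#'
#' @param mask An [interval_mask()].
#' @param recording An [lfp_recording()].
#' @return A clipped [interval_mask()].
#' @export
bind_mask <- function(mask, recording) {
  lo <- recording$start_time
  hi <- recording$start_time + lfp_duration(recording)
  s <- pmax(mask$start_s, lo)
  e <- pmin(mask$end_s, hi)
  keep <- e > s
  interval_mask(s[keep], e[keep])
}

# Logical per-sample membership: sample i covers [t_i, t_i + 1/fs); it is
# in-mask when its start time falls inside an interval.
mask_sample_index <- function(mask, recording) {
  t <- lfp_times(recording)
  inmask <- rep(FALSE, length(t))
  for (k in seq_len(nrow(mask))) {
    inmask <- inmask | (t >= mask$start_s[k] & t < mask$end_s[k])
  }
  inmask
}
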