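#' Pipeline run configuration
#'
#' One object describing a full reproducible run: the inputs (either real
#' recordings on disk or a synthetic cohort), detection / spectrogram /
#' PAC parameters, statistics options, output directory and master seed.
#' Exactly one of `input` and `synthetic` must be given.
#'
#' @param out_dir Output directory (created if absent).
#' @param seed Master seed for all seeded stages (default 0).
#' @param input A data frame (or tibble) of real inputs with columns
#'   `subject_id`, `group`, `lfp` (path), optional `mask` (path) and
#'   `format`; or `NULL`.
#' @param synthetic Either a single [synth_config()], or a list with
#'   elements `profiles`, `n_subjects`, `duration_s` describing a group
#'   fixture for [make_group_fixtures()]; or `NULL`.
#' @param swr An [swr_params()].
#' @param spec Spectrogram options: `window_s`, `spec_window_s`,
#'   `spec_step_s`, `nw`, `k`, `sg_band`, `sg_window`.
#' @param pac PAC options: `phase_band`, `amp_band`, `n_bins`.
#' @param stats Statistics options: `alpha`, `route`.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 0, input = NULL, synthetic = NULL,
                       swr = swr_params(),
                       spec = list(), pac = list(), stats = list()) {
  if (is.null(input) == is.null(synthetic)) {
    abort("Exactly one of `input` and `synthetic` must be supplied.",
          class = "ripplepac_validation_error")
  }
  if (!is.null(input)) {
    req <- c("subject_id", "group", "lfp")
    if (!all(req %in% names(input))) {
      abort("`input` needs columns subject_id, group, lfp.",
            class = "ripplepac_validation_error")
    }
  }
  spec <- modifyList(list(window_s = 0.4, spec_window_s = 0.1,
                          spec_step_s = 0.01, nw = 3, k = 5,
                          sg_band = c(30, 50), sg_window = c(0.001, 0.100)),
                     spec)
  pac <- modifyList(list(phase_band = c(4, 12), amp_band = c(30, 50),
                         n_bins = 18), pac)
  stats <- modifyList(list(alpha = 0.05, route = "auto"), stats)
  structure(list(out_dir = out_dir, seed = as.integer(seed), input = input,
                 synthetic = synthetic, swr = swr, spec = spec, pac = pac,
                 stats = stats),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Executes, per subject: (1) load or simulate the recording, (2) SWR
#' detection, (3) SWR-triggered z-scored spectrogram and slow-gamma
#' power, (4) theta-gamma PAC, then (5) the cross-group statistical
#' report over the four per-subject metrics (incidence, median duration,
#' slow-gamma z, MI). Per-subject outputs (`events.csv`, `zspec.csv`,
#' `pac.json`, each with provenance sidecars) land in
#' `<out_dir>/<subject_id>/`; cohort outputs (`metrics.csv`,
#' `report.json`) and the manifest (`run_manifest.json`, written last) in
#' `<out_dir>`. A failing stage stops that subject's downstream stages,
#' is logged, and flags the manifest incomplete; completed outputs are
#' preserved.
#'
#' @param config A [run_config()].
#' @return The manifest, invisibly: class `run_manifest`, listing
#'   resolved parameters, input checksums, per-stage outputs, timestamps
#'   and completion status.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  logf <- function(level, ...) {
    line <- sprintf("[%s] %s %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    level, sprintf(...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }

  logf("info", "resolving inputs")
  subjects <- resolve_subjects(config)
  checksums <- attr(subjects, "checksums") %||% list()

  outputs <- list()
  errors <- character()
  metrics <- list()
  for (i in seq_len(nrow(subjects))) {
    sid <- subjects$subject_id[i]
    sdir <- file.path(config$out_dir, sid)
    dir.create(sdir, showWarnings = FALSE, recursive = TRUE)
    res <- tryCatch({
      rec <- subjects$recording[[i]]
      msk <- subjects$mask[[i]]
      logf("info", "[%s] detecting SWRs", sid)
      det <- detect_swr(rec, msk, config$swr)
      write_events(det, file.path(sdir, "events.csv"))
      ds <- duration_stats(det, seed = config$seed)
      logf("info", "[%s] %d events, incidence %.3f Hz", sid,
           nrow(det$events), det$incidence_hz)
      zs <- swr_triggered_spectrogram(
        rec, det, window_s = config$spec$window_s,
        spec_window_s = config$spec$spec_window_s,
        spec_step_s = config$spec$spec_step_s,
        nw = config$spec$nw, k = config$spec$k)
      sg <- NA_real_
      if (!identical(zs$n_events, 0L)) {
        write_spectrogram(zs, file.path(sdir, "zspec.csv"))
        sg <- slow_gamma_power(zs, band = config$spec$sg_band,
                               window = config$spec$sg_window)
      }
      pr <- pac_mi(rec, phase_band = config$pac$phase_band,
                   amp_band = config$pac$amp_band,
                   n_bins = config$pac$n_bins, mask = msk)
      jsonlite::write_json(
        c(glance(pr), list(p = pr$p, bin_centers = pr$bin_centers)),
        file.path(sdir, "pac.json"), auto_unbox = TRUE, digits = NA,
        na = "null")
      outputs[[sid]] <- file.path(sid, c("events.csv", "events.csv.json",
                                          "zspec.csv", "zspec.csv.json",
                                          "pac.json"))
      tibble(subject_id = sid, group = subjects$group[i],
             incidence_hz = det$incidence_hz,
             median_duration_ms = ds$median_ms,
             sg_zpower = sg, pac_mi = pr$mi)
    }, error = function(e) {
      logf("error", "[%s] %s", sid, conditionMessage(e))
      errors <<- c(errors, sprintf("%s: %s", sid, conditionMessage(e)))
      NULL
    })
    if (!is.null(res)) metrics[[length(metrics) + 1L]] <- res
  }

  metrics_tbl <- dplyr::bind_rows(metrics)
  if (nrow(metrics_tbl) > 0) {
    utils::write.csv(metrics_tbl, file.path(config$out_dir, "metrics.csv"),
                     row.names = FALSE)
    outputs$cohort <- "metrics.csv"
  }
  if (length(unique(metrics_tbl$group)) >= 2 &&
      all(table(metrics_tbl$group) >= 2)) {
    logf("info", "group report over %d subjects", nrow(metrics_tbl))
    long <- tidyr::pivot_longer(metrics_tbl,
                                cols = c("incidence_hz", "median_duration_ms",
                                         "sg_zpower", "pac_mi"),
                                names_to = "metric", values_to = "value") |>
      dplyr::filter(is.finite(.data$value))
    rep_ <- group_report(long, value, group, metric,
                         alpha = config$stats$alpha,
                         route = config$stats$route)
    write_report(rep_, file.path(config$out_dir, "report.json"))
    outputs$cohort <- c(outputs$cohort, "report.json")
  }

  manifest <- structure(list(
    package_version = as.character(utils::packageVersion("ripplepac")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = config$seed,
    parameters = list(swr = unclass(config$swr), spec = config$spec,
                      pac = config$pac, stats = config$stats,
                      synthetic = if (!is.null(config$synthetic)) "resolved in subjects" else NULL),
    input_checksums = checksums,
    outputs = outputs,
    complete = length(errors) == 0,
    errors = errors
  ), class = "run_manifest")
  jsonlite::write_json(unclass(manifest),
                       file.path(config$out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  logf("info", "run %s", if (manifest$complete) "complete" else "INCOMPLETE")
  invisible(manifest)
}

resolve_subjects <- function(config) {
  if (!is.null(config$input)) {
    inp <- config$input
    recs <- list(); msks <- list(); sums <- list()
    for (i in seq_len(nrow(inp))) {
      fmt <- if ("format" %in% names(inp)) inp$format[i] else "auto"
      recs[[i]] <- read_lfp(inp$lfp[i], format = fmt)
      sums[[inp$lfp[i]]] <- unname(tools::md5sum(inp$lfp[i]))
      msks[[i]] <- if ("mask" %in% names(inp) && !is.na(inp$mask[i]) &&
                       nzchar(inp$mask[i])) {
        sums[[inp$mask[i]]] <- unname(tools::md5sum(inp$mask[i]))
        read_mask(inp$mask[i])
      } else NULL
    }
    out <- tibble(subject_id = inp$subject_id, group = inp$group,
                  recording = recs, mask = msks)
    attr(out, "checksums") <- sums
    return(out)
  }
  syn <- config$synthetic
  if (inherits(syn, "synth_config")) {
    sim <- generate_lfp(syn)
    return(tibble(subject_id = "subject_01", group = "synthetic",
                  recording = list(sim$recording),
                  mask = list(sim$truth$immobility_mask)))
  }
  fx <- make_group_fixtures(
    profiles = syn$profiles %||% c("WT-like", "AD-like", "AD-TMAS-like"),
    n_subjects = syn$n_subjects %||% 7,
    seed = config$seed,
    duration_s = syn$duration_s %||% 240)
  tibble(subject_id = fx$subject_id, group = fx$profile,
         recording = fx$recording,
         mask = purrr::map(fx$truth, "immobility_mask"))
}
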