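#' Pipeline run configuration
#'
#' Collects every tunable analysis parameter with defaults fixed at the
#' values the analyses are defined with: response and differential-activity
#' thresholds of 2 z (and -2), 0.5-s speed windows, 100-ms bins over a
#' -1 s ... +2 s alignment window, history windows k = 1..50, and alpha =
#' 0.05. Values can be overridden programmatically or loaded from a YAML
#' file; every effective value is echoed in the run log.
#'
#' @param overrides Named list of parameter overrides.
#' @return List of class `run_config`.
#' @export
run_config <- function(overrides = list()) {
  cfg <- list(
    response_threshold = 2,
    differential_threshold = 2,
    speed_window_s = 0.5,
    align_window_s = c(-1, 2),
    bin_s = 0.1,
    baseline_bins = 10,
    response_bins = 11:15,
    k_range = 1:50,
    alpha = 0.05,
    reentry_gap_s = 2,
    match_tol_s = 0.5,
    ht_path = "path_1",
    lt_path = "path_2",
    seed = 1
  )
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown)) stop("unknown config key(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(overrides)] <- overrides
  stopifnot(cfg$response_threshold > 0, cfg$differential_threshold > 0,
            cfg$speed_window_s > 0, cfg$bin_s > 0)
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of overrides.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Run the full analysis pipeline on one simulated or recorded mouse
#'
#' Ties the stages together: ROI events -> laps -> speed/expectation
#' annotation -> choice-history metrics -> (optionally) event-aligned
#' calcium classification. Writes tidy CSV outputs plus a plain-text run log
#' echoing the complete configuration. Deterministic given inputs and
#' config.
#'
#' @param sessions Named list (by session label), each element a list with
#'   `tracking` (data frame or CSV path) and `events` (data frame or CSV
#'   path, possibly empty).
#' @param out_dir Output directory (created if needed).
#' @param config A [run_config()].
#' @param geom A [maze_geometry()].
#' @param traces Optional named list (by session) of trace data frames or
#'   CSV paths for the neural stage.
#' @return Invisible list with `laps`, `history`, `neural` results.
#' @export
run_pipeline <- function(sessions, out_dir, config = run_config(),
                         geom = maze_geometry(), traces = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    paste0("mazepe pipeline run, package version ",
           as.character(utils::packageVersion("mazepe"))),
    "configuration:",
    vapply(names(unclass(config)), function(k) {
      paste0("  ", k, " = ", paste(config[[k]], collapse = " "))
    }, character(1))
  )

  all_laps <- list()
  for (s in names(sessions)) {
    tr <- sessions[[s]]$tracking
    if (is.character(tr)) {
      if (!file.exists(tr)) stop("tracking file not found: ", tr)
      tr <- read_tracking(tr)
    }
    ev <- sessions[[s]]$events
    if (is.character(ev)) {
      if (!file.exists(ev)) stop("event log not found: ", ev)
      ev <- read_event_log(ev)
    }
    puff <- ev[ev$event == "puff", , drop = FALSE]
    led <- ev[ev$event == "led", , drop = FALSE]
    roi_ev <- detect_roi_events(tr, geom)
    laps <- segment_laps(roi_ev, geom, puff_log = puff, led_log = led,
                         session = s, reentry_gap_s = config$reentry_gap_s,
                         match_tol_s = config$match_tol_s)
    laps <- annotate_lap_speeds(laps, tr, window = config$speed_window_s)
    laps <- latency_metrics(laps)
    all_laps[[s]] <- laps
    log_lines <- c(log_lines,
                   paste0("session ", s, ": ", nrow(laps), " laps (",
                          sum(laps$lap_class == "full"), " full, ",
                          sum(laps$lap_class == "half"), " half)"))
  }
  laps <- do.call(rbind, all_laps)
  rownames(laps) <- NULL
  write_table_csv(laps, file.path(out_dir, "laps.csv"))

  series <- choice_series(laps, ht_path = config$ht_path)
  hist_res <- history_choice_correlation(series, k_range = config$k_range,
                                         alpha = config$alpha)
  write_table_csv(hist_res$by_k, file.path(out_dir, "history_correlation.csv"))
  switch_tab <- rbind(
    cbind(conditioning_path = config$ht_path,
          post_outcome_switch(laps, config$ht_path, config$lt_path)),
    cbind(conditioning_path = config$lt_path,
          post_outcome_switch(laps, config$lt_path, config$lt_path))
  )
  write_table_csv(switch_tab, file.path(out_dir, "post_threat_switch.csv"))

  neural <- NULL
  if (!is.null(traces)) {
    neural <- list()
    for (s in names(traces)) {
      tr <- traces[[s]]
      if (is.character(tr)) {
        if (!file.exists(tr)) stop("trace file not found: ", tr)
        tr <- read_traces(tr)
      }
      ls <- laps[laps$session == s, , drop = FALSE]
      aligned <- align_to_event(tr, ls$t_enter_threat,
                                window = config$align_window_s,
                                bin = config$bin_s)
      kept <- setdiff(seq_len(nrow(ls)), attr(aligned, "dropped"))
      lap_type <- paste(ifelse(ls$threat_delivered, "threat", "omission"),
                        ls$expectation, sep = "_")[kept]
      zavg <- lap_type_average_z(aligned, lap_type,
                                 n_baseline = config$baseline_bins)
      mag <- response_magnitude(zavg, response_bins = config$response_bins)
      diff <- differential_activity(mag)
      cls <- classify_pe_type(diff, threshold = config$differential_threshold)
      cls$session <- s
      neural[[s]] <- cls
      write_table_csv(
        cls[, c("cell", "session", "d_threat", "d_omission", "label",
                "signed_pe", "unsigned_pe")],
        file.path(out_dir, paste0("pe_classification_", s, ".csv")))
    }
  }
  writeLines(log_lines, log_path)
  invisible(list(laps = laps, history = hist_res, neural = neural))
}
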