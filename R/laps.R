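#' Segment ROI events into laps
#'
#' Walks the ordered ROI event list and cuts it into laps. A *full* lap is an
#' excursion that exits one reward site, passes through a threat site, and
#' enters the other reward site; a *half* lap returns to the starting reward
#' site after visiting a threat site. A reward-to-reward excursion that never
#' enters a threat ROI produces no lap. Each lap is attributed the path of the
#' first threat ROI entered during the excursion; additional threat-ROI visits
#' within the same excursion are absorbed into the lap (with a warning when a
#' different threat ROI is involved).
#'
#' Air-puff and LED log entries are matched to threat-site entries within
#' `match_tol_s` seconds (puffs are triggered 100 ms after entry). A puff that
#' matches no threat-site entry is an error.
#'
#' @param events Event data frame from [detect_roi_events()].
#' @param geom A [maze_geometry()].
#' @param puff_log,led_log Optional data frames with a `time_s` column (one
#'   row per puff / LED pulse), or `NULL`.
#' @param session Session label stored on every lap.
#' @param reentry_gap_s Same-ROI re-entry merge window, see
#'   [merge_roi_reentries()].
#' @param match_tol_s Tolerance for matching puff/LED timestamps to
#'   threat-site entries (seconds).
#' @return Data frame of laps with columns `index`, `session`, `start_site`,
#'   `end_site`, `path`, `lap_class` (`"full"`/`"half"`), `threat_delivered`,
#'   `led`, `t_exit_reward`, `t_enter_threat`, `t_exit_threat`,
#'   `t_enter_end_reward`.
#' @export
segment_laps <- function(events, geom, puff_log = NULL, led_log = NULL,
                         session = NA_character_, reentry_gap_s = 2,
                         match_tol_s = 0.5) {
  stopifnot(all(c("time_s", "roi", "type") %in% names(events)))
  if (is.unsorted(events$time_s)) stop("events must be ordered in time")
  events <- merge_roi_reentries(events, min_gap_s = reentry_gap_s)

  kind <- geom$rois$kind[match(events$roi, geom$rois$roi)]

  laps <- list()
  start_site <- NA_character_; t_exit_reward <- NA_real_
  threat_roi <- NA_character_; t_enter_threat <- NA_real_; t_exit_threat <- NA_real_
  excursion <- FALSE

  for (i in seq_len(nrow(events))) {
    roi <- events$roi[i]; type <- events$type[i]; tm <- events$time_s[i]
    if (kind[i] == "reward" && type == "exit") {
      start_site <- roi; t_exit_reward <- tm
      threat_roi <- NA_character_; t_enter_threat <- NA_real_; t_exit_threat <- NA_real_
      excursion <- TRUE
    } else if (kind[i] == "threat" && excursion) {
      if (type == "enter") {
        if (is.na(threat_roi)) {
          threat_roi <- roi; t_enter_threat <- tm
        } else if (roi != threat_roi) {
          warning("excursion visited more than one threat ROI; ",
                  "lap attributed to the first (", threat_roi, ")")
        }
      } else if (type == "exit" && !is.na(threat_roi) && roi == threat_roi) {
        t_exit_threat <- tm
      }
    } else if (kind[i] == "reward" && type == "enter") {
      if (excursion && !is.na(threat_roi)) {
        laps[[length(laps) + 1]] <- data.frame(
          session = session,
          start_site = start_site,
          end_site = roi,
          path = unname(geom$paths[threat_roi]),
          lap_class = if (roi == start_site) "half" else "full",
          t_exit_reward = t_exit_reward,
          t_enter_threat = t_enter_threat,
          t_exit_threat = t_exit_threat,
          t_enter_end_reward = tm,
          stringsAsFactors = FALSE
        )
      }
      excursion <- FALSE
    }
  }

  if (length(laps) == 0) {
    out <- data.frame(index = integer(0), session = character(0),
                      start_site = character(0), end_site = character(0),
                      path = character(0), lap_class = character(0),
                      threat_delivered = logical(0), led = logical(0),
                      t_exit_reward = numeric(0), t_enter_threat = numeric(0),
                      t_exit_threat = numeric(0), t_enter_end_reward = numeric(0))
    return(out)
  }
  out <- do.call(rbind, laps)
  out$index <- seq_len(nrow(out))

  out$threat_delivered <- match_log_to_entries(puff_log, out$t_enter_threat,
                                               match_tol_s, "puff")
  out$led <- match_log_to_entries(led_log, out$t_enter_threat,
                                  match_tol_s, "led")
  out[, c("index", "session", "start_site", "end_site", "path", "lap_class",
          "threat_delivered", "led", "t_exit_reward", "t_enter_threat",
          "t_exit_threat", "t_enter_end_reward")]
}

# Match a time-stamped boolean log to threat-site entries; every log entry
# must land within tol of some entry time.
match_log_to_entries <- function(log, entry_times, tol, what) {
  flags <- rep(FALSE, length(entry_times))
  if (is.null(log) || nrow(log) == 0) return(flags)
  stopifnot("time_s" %in% names(log))
  for (tm in log$time_s) {
    d <- abs(entry_times - tm)
    j <- which.min(d)
    if (length(j) == 0 || d[j] > tol) {
      stop(what, " at t = ", tm,
           " s matches no threat-site entry within ", tol, " s")
    }
    flags[j] <- TRUE
  }
  flags
}

#' Adaptive path-choice fraction
#'
#' The fraction of laps (full and half) in which the mouse chose the path
#' carrying the lower threat probability.
#'
#' @param laps Lap table (see [segment_laps()]), typically one session.
#' @param lt_path Path id of the low-threat path.
#' @return Proportion in \[0, 1\].
#' @export
adaptive_choice_fraction <- function(laps, lt_path = "path_2") {
  if (is.null(laps) || nrow(laps) == 0) {
    stop("adaptive choice fraction is undefined for a session with zero laps")
  }
  mean(laps$path == lt_path)
}

#' Lap latency metrics
#'
#' Latency to threat = reward-site exit to threat-site entry; latency to
#' reward = threat-site exit to reward-site entry; latency to initiate = time
#' spent in the end reward site before the next lap's reward-site exit
#' (absent for the last lap of a session).
#'
#' @param laps Lap table ordered by `index`, one session.
#' @return `laps` with columns `latency_to_threat`, `latency_to_reward`,
#'   `latency_to_initiate` appended.
#' @export
latency_metrics <- function(laps) {
  stopifnot(!is.unsorted(laps$index))
  laps$latency_to_threat <- laps$t_enter_threat - laps$t_exit_reward
  laps$latency_to_reward <- laps$t_enter_end_reward - laps$t_exit_threat
  n <- nrow(laps)
  init <- rep(NA_real_, n)
  if (n > 1) {
    init[-n] <- laps$t_exit_reward[-1] - laps$t_enter_end_reward[-n]
  }
  laps$latency_to_initiate <- init
  stopifnot(all(laps$latency_to_threat > 0, na.rm = TRUE),
            all(laps$latency_to_reward > 0, na.rm = TRUE))
  laps
}
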