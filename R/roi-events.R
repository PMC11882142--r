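#' Detect ROI entry and exit events from position tracking
#'
#' Scans the tracked body-centre positions sample by sample and emits an
#' ordered event list of ROI entries and exits. An entry is stamped with the
#' time of the first sample inside the ROI; an exit with the time of the first
#' sample no longer inside it. The scan is raw: border jitter that produces
#' rapid exit/re-entry pairs is left in the event list and handled downstream
#' (see [merge_roi_reentries()]).
#'
#' @param tracking Data frame with columns `time_s`, `x_cm`, `y_cm`;
#'   `time_s` strictly increasing.
#' @param geom A [maze_geometry()].
#' @param max_gap_s Sampling gaps longer than this (seconds) raise a warning.
#' @return Data frame `time_s`, `roi`, `type` (`"enter"`/`"exit"`), ordered in
#'   time. Events alternate enter/exit within each ROI; a trajectory ending
#'   inside an ROI has an unmatched final entry.
#' @export
detect_roi_events <- function(tracking, geom, max_gap_s = 1) {
  if (is.null(tracking) || nrow(tracking) == 0) {
    stop("tracking is empty: no positions to scan")
  }
  stopifnot(all(c("time_s", "x_cm", "y_cm") %in% names(tracking)))
  t <- tracking$time_s
  if (any(diff(t) <= 0)) stop("tracking time_s must be strictly increasing")
  if (any(diff(t) > max_gap_s)) {
    warning("tracking contains sampling gaps > ", max_gap_s, " s")
  }

  member <- roi_membership(tracking$x_cm, tracking$y_cm, geom)
  code <- ifelse(is.na(member), ".outside", member)
  change <- c(TRUE, code[-1] != code[-length(code)])
  idx <- which(change)
  seg_roi <- code[idx]

  times <- character(0)
  ev_t <- numeric(0); ev_roi <- character(0); ev_type <- character(0)
  for (s in seq_along(idx)) {
    roi <- seg_roi[s]
    t0 <- t[idx[s]]
    if (roi != ".outside") {
      if (s > 1) { # entering from outside/another ROI
        ev_t <- c(ev_t, t0); ev_roi <- c(ev_roi, roi); ev_type <- c(ev_type, "enter")
      } else {
        # trajectory starts inside an ROI: count as an entry at the first sample
        ev_t <- c(ev_t, t0); ev_roi <- c(ev_roi, roi); ev_type <- c(ev_type, "enter")
      }
    }
    if (s > 1 && seg_roi[s - 1] != ".outside") {
      ev_t <- c(ev_t, t0); ev_roi <- c(ev_roi, seg_roi[s - 1]); ev_type <- c(ev_type, "exit")
    }
  }
  out <- data.frame(time_s = ev_t, roi = ev_roi, type = ev_type,
                    stringsAsFactors = FALSE)
  out[order(out$time_s, out$type != "exit"), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}

#' Merge rapid re-entries into the same ROI
#'
#' Tracking jitter at an ROI border can split one visit into several
#' exit/enter pairs. An exit followed by a re-entry into the same ROI within
#' `min_gap_s` seconds, with no other ROI visited in between, is merged into a
#' single visit by dropping the intervening exit/enter pair.
#'
#' @param events Event data frame from [detect_roi_events()].
#' @param min_gap_s Merge window in seconds.
#' @return Event data frame with merged visits.
#' @export
merge_roi_reentries <- function(events, min_gap_s = 2) {
  if (nrow(events) < 3) return(events)
  drop <- rep(FALSE, nrow(events))
  i <- 1
  while (i <= nrow(events) - 1) {
    if (events$type[i] == "exit") {
      j <- i + 1
      # next event overall; merging only allowed if it is a re-entry into the
      # same ROI (any other ROI event in between blocks the merge)
      if (!drop[j] && events$type[j] == "enter" &&
          events$roi[j] == events$roi[i] &&
          events$time_s[j] - events$time_s[i] < min_gap_s) {
        drop[i] <- TRUE
        drop[j] <- TRUE
        i <- j + 1
        next
      }
    }
    i <- i + 1
  }
  out <- events[!drop, , drop = FALSE]
  rownames(out) <- NULL
  out
}
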