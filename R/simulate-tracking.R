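#' Realize simulated laps as a position-tracking series
#'
#' Converts an agent lap table into a continuous body-centre trajectory
#' sampled at the video rate. The mouse dwells at a home point inside the
#' start reward site, travels along the maze corridor through the lap's
#' threat site at the lap's approach speed until threat-site entry, then
#' continues at the lap's reaction speed into the end reward site, where it
#' dwells again. Re-segmenting the emitted tracking with
#' [detect_roi_events()] + [segment_laps()] reproduces the input laps' path,
#' class and order exactly.
#'
#' @param laps Agent lap table from [simulate_agent()] (one session).
#' @param geom A [maze_geometry()].
#' @param config The [agent_config()] (for dwell time).
#' @param rate Sampling rate in Hz (video: 30).
#' @return List with `tracking` (data frame `time_s`, `x_cm`, `y_cm`),
#'   `events` (data frame `time_s`, `event` with `"puff"`/`"led"` rows) and
#'   `laps`: the input table augmented with scheduled timestamps
#'   `t_exit_reward`, `t_enter_threat`, `t_exit_threat`,
#'   `t_enter_end_reward`.
#' @export
simulate_tracking <- function(laps, geom, config = agent_config(), rate = 30) {
  if (nrow(laps) == 0) {
    return(list(
      tracking = data.frame(time_s = numeric(0), x_cm = numeric(0),
                            y_cm = numeric(0)),
      events = data.frame(time_s = numeric(0), event = character(0)),
      laps = laps
    ))
  }
  dwell <- config$dwell_mean_s
  way_t <- numeric(0); way_x <- numeric(0); way_y <- numeric(0)
  t_cur <- 0
  sched <- data.frame(t_exit_reward = numeric(nrow(laps)),
                      t_enter_threat = numeric(nrow(laps)),
                      t_exit_threat = numeric(nrow(laps)),
                      t_enter_end_reward = numeric(nrow(laps)))
  add_way <- function(t, p) {
    way_t <<- c(way_t, t); way_x <<- c(way_x, p[1]); way_y <<- c(way_y, p[2])
  }
  home0 <- site_home(laps$start_site[1], geom)
  add_way(t_cur, home0)

  for (i in seq_len(nrow(laps))) {
    threat_roi <- names(geom$paths)[geom$paths == laps$path[i]]
    p_start <- site_home(laps$start_site[i], geom)
    # dwell in the start reward site
    t_cur <- t_cur + dwell
    add_way(t_cur, p_start)
    t_dwell_end <- t_cur
    pts <- lap_route(laps$start_site[i], laps$end_site[i], threat_roi, geom)
    entry <- route_entry_point(pts, threat_roi, geom)
    # waypoint times: approach speed up to threat entry, reaction speed after
    prev <- p_start; before_entry <- TRUE
    for (j in seq(2, nrow(pts))) {
      p <- c(pts$x[j], pts$y[j])
      if (before_entry && pts$leg[j] >= entry$leg) {
        # split the leg at the entry point
        d1 <- dist2(prev, entry$p)
        t_cur <- t_cur + d1 / laps$approach_speed[i]
        add_way(t_cur, entry$p)
        sched$t_enter_threat[i] <- t_cur
        before_entry <- FALSE
        d2 <- dist2(entry$p, p)
        t_cur <- t_cur + d2 / laps$reaction_speed[i]
        add_way(t_cur, p)
      } else {
        v <- if (before_entry) laps$approach_speed[i] else laps$reaction_speed[i]
        t_cur <- t_cur + dist2(prev, p) / v
        add_way(t_cur, p)
      }
      prev <- p
    }
    # boundary-crossing times along the realized waypoints
    lap_way <- data.frame(t = way_t, x = way_x, y = way_y)
    sched$t_exit_reward[i] <- crossing_time(lap_way, laps$start_site[i], geom,
                                            after = t_dwell_end - 1e-9,
                                            leaving = TRUE)
    sched$t_exit_threat[i] <- crossing_time(lap_way, threat_roi, geom,
                                            after = sched$t_enter_threat[i],
                                            leaving = TRUE)
    sched$t_enter_end_reward[i] <- crossing_time(lap_way, laps$end_site[i], geom,
                                                 after = sched$t_exit_threat[i],
                                                 leaving = FALSE)
  }
  # final dwell so the last reward entry is followed by samples
  t_cur <- t_cur + dwell
  add_way(t_cur, site_home(laps$end_site[nrow(laps)], geom))

  ts <- seq(0, t_cur, by = 1 / rate)
  tracking <- data.frame(
    time_s = ts,
    x_cm = stats::approx(way_t, way_x, xout = ts, rule = 2)$y,
    y_cm = stats::approx(way_t, way_y, xout = ts, rule = 2)$y
  )
  out_laps <- cbind(laps, sched)
  events <- rbind(
    data.frame(time_s = sched$t_enter_threat[laps$threat_delivered] + 0.1,
               event = rep("puff", sum(laps$threat_delivered)),
               stringsAsFactors = FALSE),
    data.frame(time_s = sched$t_enter_threat[laps$led] + 0.1,
               event = rep("led", sum(laps$led)),
               stringsAsFactors = FALSE)
  )
  events <- events[order(events$time_s), , drop = FALSE]
  rownames(events) <- NULL
  list(tracking = tracking, events = events, laps = out_laps)
}

#' Nominal lap event times without generating tracking
#'
#' Computes the scheduled timestamps (`t_exit_reward`, `t_enter_threat`,
#' `t_exit_threat`, `t_enter_end_reward`) that [simulate_tracking()] would
#' realize, using route distances and the lap's speeds. Useful when only
#' event-aligned analyses (e.g. calcium simulation) are needed.
#'
#' @inheritParams simulate_tracking
#' @return `laps` with the four timestamp columns appended.
#' @export
schedule_lap_times <- function(laps, geom, config = agent_config()) {
  simulate_tracking(laps, geom, config, rate = 30)$laps
}

# ---- internal route machinery ----------------------------------------------

site_home <- function(site, geom) {
  r <- geom$rois[geom$rois$roi == site, ]
  c(r$xmin + (r$xmax - r$xmin) / 2, r$ymin + (r$ymax - r$ymin) / 2)
}

dist2 <- function(p, q) sqrt(sum((p - q)^2))

# corridor waypoints from a reward site's home to a threat site's centre
half_route <- function(site, threat_roi, geom) {
  th <- geom$rois[geom$rois$roi == threat_roi, ]
  centre <- c((th$xmin + th$xmax) / 2, (th$ymin + th$ymax) / 2)
  home <- site_home(site, geom)
  if (site == "reward_1") {
    # move along the wall shared with the threat corner
    pts <- rbind(home, c(home[1], centre[2]), centre)
    if (th$ymin < geom$side / 2) pts <- rbind(home, c(centre[1], home[2]), centre)
  } else {
    pts <- rbind(home, c(home[1], centre[2]), centre)
    if (th$ymin < geom$side / 2) pts <- rbind(home, c(centre[1], home[2]), centre)
  }
  # drop zero-length legs
  keep <- c(TRUE, rowSums(abs(diff(pts))) > 1e-9)
  pts[keep, , drop = FALSE]
}

# full polyline of a lap: start home -> threat centre -> end home
lap_route <- function(start_site, end_site, threat_roi, geom) {
  out_leg <- half_route(start_site, threat_roi, geom)
  back_leg <- half_route(end_site, threat_roi, geom)
  pts <- rbind(out_leg, back_leg[rev(seq_len(nrow(back_leg) - 1)), , drop = FALSE])
  data.frame(x = pts[, 1], y = pts[, 2], leg = seq_len(nrow(pts)))
}

# where along the route the threat ROI is first entered
route_entry_point <- function(pts, threat_roi, geom) {
  for (j in seq(2, nrow(pts))) {
    p0 <- c(pts$x[j - 1], pts$y[j - 1]); p1 <- c(pts$x[j], pts$y[j])
    in0 <- identical(roi_membership(p0[1], p0[2], geom), threat_roi)
    in1 <- identical(roi_membership(p1[1], p1[2], geom), threat_roi)
    if (!in0 && in1) {
      f <- boundary_fraction(p0, p1, threat_roi, geom)
      return(list(p = p0 + f * (p1 - p0), leg = j))
    }
  }
  stop("route never enters ", threat_roi)
}

# fraction along segment p0->p1 where membership of `roi` flips
boundary_fraction <- function(p0, p1, roi, geom) {
  inside <- function(f) {
    p <- p0 + f * (p1 - p0)
    identical(roi_membership(p[1], p[2], geom), roi)
  }
  lo <- 0; hi <- 1
  target <- inside(1)
  for (it in 1:40) {
    mid <- (lo + hi) / 2
    if (inside(mid) == target) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# continuous-time crossing of an ROI boundary along a time-stamped polyline
crossing_time <- function(way, roi, geom, after, leaving) {
  memb <- roi_membership(way$x, way$y, geom)
  in_roi <- !is.na(memb) & memb == roi
  j0 <- max(2, findInterval(after, way$t) + 1)
  for (j in seq(j0, nrow(way))) {
    if (way$t[j] <= after) next
    flip <- if (leaving) in_roi[j - 1] && !in_roi[j] else !in_roi[j - 1] && in_roi[j]
    if (flip) {
      p0 <- c(way$x[j - 1], way$y[j - 1]); p1 <- c(way$x[j], way$y[j])
      f <- boundary_fraction(p0, p1, roi, geom)
      return(way$t[j - 1] + f * (way$t[j] - way$t[j - 1]))
    }
  }
  NA_real_
}
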