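#' Instantaneous speed from position tracking
#'
#' First-order finite differences with no smoothing: the speed attributed to
#' sample *i* is the displacement from sample *i - 1* divided by the elapsed
#' time. The 500-ms averaging windows used downstream already suppress
#' sample-to-sample jitter.
#'
#' @param tracking Data frame `time_s`, `x_cm`, `y_cm`.
#' @return Data frame `time_s`, `speed` (cm/s); one row fewer than `tracking`.
#' @export
instantaneous_speed <- function(tracking) {
  stopifnot(nrow(tracking) >= 2)
  dt <- diff(tracking$time_s)
  dist <- sqrt(diff(tracking$x_cm)^2 + diff(tracking$y_cm)^2)
  data.frame(time_s = tracking$time_s[-1], speed = dist / dt)
}

#' Approach and reaction speed per lap
#'
#' Approach speed is the mean finite-difference speed over the 500-ms window
#' immediately before threat-site entry, `[t_entry - window, t_entry)`;
#' reaction speed over the window immediately after, `[t_entry, t_entry +
#' window)`. A lap whose window falls outside the recording or contains fewer
#' than two speed samples is flagged invalid (`speed_valid = FALSE`) and its
#' speeds set to `NA`.
#'
#' @param laps Lap table with `t_enter_threat`.
#' @param tracking Tracking data frame of the same session.
#' @param window Window length in seconds.
#' @return `laps` with `approach_speed`, `reaction_speed`, `speed_valid`
#'   columns appended.
#' @export
speed_metrics <- function(laps, tracking, window = 0.5) {
  sp <- instantaneous_speed(tracking)
  t0 <- min(tracking$time_s); t1 <- max(tracking$time_s)
  win_mean <- function(lo, hi) {
    idx <- sp$time_s >= lo & sp$time_s < hi
    if (sum(idx) < 2) return(NA_real_)
    mean(sp$speed[idx])
  }
  n <- nrow(laps)
  approach <- reaction <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (i in seq_len(n)) {
    te <- laps$t_enter_threat[i]
    if (is.na(te) || te - window < t0 || te + window > t1) next
    a <- win_mean(te - window, te)
    r <- win_mean(te, te + window)
    approach[i] <- a; reaction[i] <- r
    valid[i] <- !is.na(a) && !is.na(r)
  }
  laps$approach_speed <- approach
  laps$reaction_speed <- reaction
  laps$speed_valid <- valid
  laps
}

#' Median split of approach speeds into fast and slow laps
#'
#' Within a session, laps strictly below the median approach speed are
#' `"slow"`; laps at or above it are `"fast"` (the tie-at-median rule keeps
#' "slow" strictly sub-median). When all speeds are identical every lap is
#' fast and a warning is raised.
#'
#' @param speeds Numeric vector of approach speeds (one session).
#' @return Character vector of `"fast"`/`"slow"` labels (`NA` in, `NA` out).
#' @export
median_split <- function(speeds) {
  ok <- !is.na(speeds)
  if (sum(ok) < 4) stop("median split needs at least 4 laps with valid approach speed")
  med <- stats::median(speeds[ok])
  if (all(speeds[ok] == speeds[ok][1])) {
    warning("all approach speeds identical; every lap labelled 'fast'")
  }
  out <- rep(NA_character_, length(speeds))
  out[ok] <- ifelse(speeds[ok] < med, "slow", "fast")
  out
}

#' Expected vs surprising outcome label
#'
#' A slow approach signals that the mouse expected a threat, a fast approach
#' that it did not. Crossing the speed category with the delivered outcome:
#' fast + threat and slow + omission are *surprising*; slow + threat and
#' fast + omission are *expected*.
#'
#' @param fast_slow Character vector `"fast"`/`"slow"`.
#' @param threat_delivered Logical vector.
#' @return Character vector `"expected"`/`"surprising"`.
#' @export
expectation_label <- function(fast_slow, threat_delivered) {
  stopifnot(length(fast_slow) == length(threat_delivered))
  if (any(is.na(fast_slow) & !is.na(threat_delivered))) {
    stop("expectation label requires a fast/slow label for every lap")
  }
  surprising <- (fast_slow == "fast" & threat_delivered) |
    (fast_slow == "slow" & !threat_delivered)
  ifelse(surprising, "surprising", "expected")
}

#' Annotate a session's laps with speed, median-split and expectation labels
#'
#' Convenience wrapper: computes [speed_metrics()], applies [median_split()]
#' per session and derives the [expectation_label()].
#'
#' @param laps Lap table (may span sessions; the split is per session).
#' @param tracking Tracking for the single session in `laps`, or a named list
#'   of tracking data frames keyed by session label.
#' @param window Speed window in seconds.
#' @return Annotated lap table with `approach_speed`, `reaction_speed`,
#'   `speed_valid`, `fast_slow`, `expectation`.
#' @export
annotate_lap_speeds <- function(laps, tracking, window = 0.5) {
  if (is.data.frame(tracking)) {
    laps <- speed_metrics(laps, tracking, window)
  } else {
    parts <- lapply(split(laps, laps$session), function(ls) {
      speed_metrics(ls, tracking[[ls$session[1]]], window)
    })
    laps <- do.call(rbind, parts)
    laps <- laps[order(laps$index), , drop = FALSE]
    rownames(laps) <- NULL
  }
  laps$fast_slow <- NA_character_
  for (s in unique(laps$session)) {
    i <- laps$session == s
    laps$fast_slow[i] <- median_split(laps$approach_speed[i])
  }
  laps$expectation <- expectation_label(laps$fast_slow, laps$threat_delivered)
  laps
}

#' Speed time course around threat-site entry
#'
#' Bins each lap's finite-difference speed into fixed-width time bins relative
#' to threat-site entry, then averages per bin within lap groups.
#'
#' @param laps Lap table with `t_enter_threat`.
#' @param tracking Tracking data frame of the same session.
#' @param group Factor/character vector, one group label per lap.
#' @param window Two-element numeric, window around entry in seconds.
#' @param bin Bin width in seconds; must divide the window evenly.
#' @return Data frame `group`, `bin_mid`, `mean`, `sem`, `n_laps`. Groups with
#'   no laps are absent.
#' @export
speed_timecourse <- function(laps, tracking, group,
                             window = c(-2, 2), bin = 0.1) {
  nb <- (window[2] - window[1]) / bin
  if (abs(nb - round(nb)) > 1e-8) stop("bin must divide the window evenly")
  nb <- round(nb)
  stopifnot(length(group) == nrow(laps))
  sp <- instantaneous_speed(tracking)

  per_lap <- matrix(NA_real_, nrow(laps), nb)
  for (i in seq_len(nrow(laps))) {
    rel <- sp$time_s - laps$t_enter_threat[i]
    inside <- rel >= window[1] & rel < window[2]
    if (!any(inside)) next
    b <- floor((rel[inside] - window[1]) / bin) + 1
    m <- tapply(sp$speed[inside], factor(b, levels = seq_len(nb)), mean)
    per_lap[i, ] <- as.numeric(m)
  }
  bin_mid <- window[1] + (seq_len(nb) - 0.5) * bin
  out <- lapply(split(seq_len(nrow(laps)), group), function(idx) {
    m <- per_lap[idx, , drop = FALSE]
    data.frame(
      bin_mid = bin_mid,
      mean = colMeans(m, na.rm = TRUE),
      sem = apply(m, 2, function(v) {
        v <- v[!is.na(v)]
        if (length(v) < 2) NA_real_ else stats::sd(v) / sqrt(length(v))
      }),
      n_laps = length(idx)
    )
  })
  out <- do.call(rbind, Map(function(g, d) cbind(group = g, d), names(out), out))
  rownames(out) <- NULL
  out
}
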