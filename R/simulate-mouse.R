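#' Simulate one synthetic mouse end to end
#'
#' Runs the agent over the schedule, realizes per-session tracking and
#' puff/LED event logs, and (optionally) calcium traces for selected
#' sessions. All randomness flows from `seed`, so the same seed reproduces
#' every output exactly.
#'
#' @param config An [agent_config()].
#' @param schedule A [stage_schedule()].
#' @param geom A [maze_geometry()].
#' @param seed Integer seed.
#' @param imaging_sessions Session labels for which calcium traces are
#'   generated (`NULL` for none).
#' @param cells Cell table from [cell_population()] (required when
#'   `imaging_sessions` is given).
#' @param tracking Generate tracking/event logs per session (set `FALSE` for
#'   large behavioral-only cohorts where scheduled lap times suffice).
#' @return List: `agent` (lap table with values, PEs, speeds and, when
#'   timing was computed, scheduled event times), `sessions` (named list
#'   with `tracking` and `events` per session, when requested) and
#'   `calcium` (named list with `traces`/`truth` per imaging session).
#' @export
simulate_mouse <- function(config = agent_config(),
                           schedule = stage_schedule(),
                           geom = maze_geometry(), seed = 1,
                           imaging_sessions = NULL, cells = NULL,
                           tracking = TRUE) {
  set.seed(seed)
  agent <- simulate_agent(config, schedule)
  sessions <- list()
  timed <- list()
  need_timing <- tracking || length(imaging_sessions) > 0
  if (need_timing) {
    for (s in unique(agent$session)) {
      ls <- agent[agent$session == s, , drop = FALSE]
      sim <- simulate_tracking(ls, geom, config)
      timed[[s]] <- sim$laps
      if (tracking) sessions[[s]] <- sim[c("tracking", "events")]
    }
    agent <- do.call(rbind, timed)
    rownames(agent) <- NULL
  }
  calcium <- list()
  for (s in imaging_sessions) {
    stopifnot(!is.null(cells))
    calcium[[s]] <- simulate_calcium(agent[agent$session == s, , drop = FALSE],
                                     cells)
  }
  list(agent = agent, sessions = sessions, calcium = calcium)
}

#' Probe session for neural planted-truth checks
#'
#' A single-session schedule with balanced (50/50) threat probabilities,
#' sized so that each expectation x outcome lap type accumulates well over
#' 15 laps. Balanced outcomes maximize lap-by-lap prediction-error
#' fluctuation, which is what the expectation-differential classification is
#' meant to detect.
#'
#' @param n_laps Laps in the probe session.
#' @param p_threat_ht,p_threat_lt Threat probabilities of the two paths.
#' @return One-row schedule data frame.
#' @export
probe_schedule <- function(n_laps = 240, p_threat_ht = 0.5,
                           p_threat_lt = 0.5) {
  data.frame(session = "probe", stage = "probe",
             p_threat_ht = p_threat_ht, p_threat_lt = p_threat_lt,
             led_policy = "none", n_laps = n_laps,
             stringsAsFactors = FALSE)
}

#' Simulate a planted-truth cohort for the PE-classification pipeline
#'
#' Runs a fast-updating agent through a balanced probe session and attaches
#' calcium traces for a mixed cell population with known coding labels. The
#' probe agent uses a high learning rate so that its threat-value estimate -
#' and therefore its approach speed - fluctuates strongly from lap to lap:
#' expected outcomes then carry near-zero prediction errors and the
#' median-split expectation labels are mostly correct, which is what a
#' validation of the *neural* classification requires.
#'
#' @param seed Integer seed.
#' @param n_cells Number of cells.
#' @param n_laps Laps in the probe session.
#' @param amplitude Transient amplitude in baseline-noise SD units.
#' @param props Cell-type proportions, see [cell_population()].
#' @return List with `laps` (scheduled times, speeds, `fast_slow`,
#'   `expectation`, `lap_type`), `cells` (ground truth) and `traces`.
#' @export
simulate_pe_probe <- function(seed, n_cells = 100, n_laps = 240,
                              amplitude = 4,
                              props = c(outcome_ht = 0.1, outcome_lt = 0.1,
                                        signed_pe = 0.2, unsigned_pe = 0.1,
                                        expectation = 0.1, none = 0.4)) {
  set.seed(seed)
  cfg <- agent_config(alpha_pos = 0.5, alpha_neg = 0.5, beta = 0.5,
                      v0 = c(ht = 0.5, lt = 0.5))
  laps <- simulate_agent(cfg, probe_schedule(n_laps = n_laps))
  laps <- schedule_lap_times(laps, maze_geometry(), cfg)
  laps$fast_slow <- median_split(laps$approach_speed)
  laps$expectation <- expectation_label(laps$fast_slow, laps$threat_delivered)
  laps$lap_type <- paste(ifelse(laps$threat_delivered, "threat", "omission"),
                         laps$expectation, sep = "_")
  cells <- cell_population(n = n_cells, props = props, amplitude = amplitude)
  cal <- simulate_calcium(laps, cells)
  list(laps = laps, cells = cells, traces = cal$traces)
}
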