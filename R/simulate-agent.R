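#' Configuration of the synthetic maze agent
#'
#' A Rescorla-Wagner learner with softmax path choice. The agent keeps one
#' threat-value estimate V per path; after each lap the prediction error
#' `PE = outcome - V(path)` (positive for unexpected threat, negative for
#' unexpected omission) updates V with a learning rate that may differ by PE
#' sign. Paths are chosen by a softmax over `-V` (threat is aversive).
#' Approach speed decreases with the chosen path's value
#' (`base_speed - expectation_slope * V + noise`), and reaction speed
#' increases with the prediction error, so surprising threats produce the
#' fastest escapes and surprising omissions the slowest re-accelerations.
#' In `switch_override` mode ("opsin-like") the agent deterministically takes
#' the other path after every threat lap and otherwise chooses by a fair coin
#' flip: its choices never integrate value estimates, mimicking a phenotype
#' that reacts to each threat without tracking threat probability over laps.
#'
#' @param alpha_pos,alpha_neg Learning rates in \[0, 1\] for positive /
#'   negative prediction errors.
#' @param beta Softmax inverse temperature (> 0).
#' @param v0 Initial path values, length 2 (`ht`, `lt`).
#' @param base_speed Baseline approach speed, cm/s.
#' @param expectation_slope Speed decrease per unit V, cm/s.
#' @param speed_noise_sd Approach-speed noise SD, cm/s.
#' @param base_reaction Baseline reaction speed, cm/s.
#' @param reaction_gain Reaction-speed change per unit PE, cm/s.
#' @param reaction_noise_sd Reaction-speed noise SD, cm/s.
#' @param p_half Probability that a lap returns to the starting reward site
#'   (half lap).
#' @param dwell_mean_s Mean dwell time in the reward site between laps.
#' @param min_speed Lower clip for speeds, cm/s.
#' @param switch_override Force a path switch after every threat lap.
#' @return List of class `agent_config`.
#' @export
agent_config <- function(alpha_pos = 0.1, alpha_neg = 0.1, beta = 2,
                         v0 = c(ht = 0, lt = 0),
                         base_speed = 30, expectation_slope = 20,
                         speed_noise_sd = 3,
                         base_reaction = 25, reaction_gain = 12,
                         reaction_noise_sd = 3,
                         p_half = 0.1, dwell_mean_s = 2, min_speed = 0.5,
                         switch_override = FALSE) {
  stopifnot(alpha_pos >= 0, alpha_pos <= 1, alpha_neg >= 0, alpha_neg <= 1,
            beta > 0, all(v0 >= 0 & v0 <= 1), p_half >= 0, p_half < 1)
  structure(list(
    alpha_pos = alpha_pos, alpha_neg = alpha_neg, beta = beta, v0 = v0,
    base_speed = base_speed, expectation_slope = expectation_slope,
    speed_noise_sd = speed_noise_sd, base_reaction = base_reaction,
    reaction_gain = reaction_gain, reaction_noise_sd = reaction_noise_sd,
    p_half = p_half, dwell_mean_s = dwell_mean_s, min_speed = min_speed,
    switch_override = switch_override
  ), class = "agent_config")
}

#' Simulate the maze agent over a session schedule
#'
#' Runs the Rescorla-Wagner softmax agent lap by lap through every session
#' of `schedule`. `path_1` is the high-threat path and `path_2` the
#' low-threat path (probabilities taken from the schedule's `p_threat_ht` /
#' `p_threat_lt`). LED flags follow the session's `led_policy`.
#' Value estimates carry over between sessions.
#'
#' @param config An [agent_config()].
#' @param schedule A [stage_schedule()] (or compatible data frame).
#' @param seed Optional integer seed.
#' @return Data frame with one row per lap: `session`, `stage`, `lap`,
#'   `path`, `lap_class`, `start_site`, `end_site`, `threat_delivered`,
#'   `led`, `v_ht`, `v_lt` (values before the lap's update), `v_path`, `pe`,
#'   `approach_speed`, `reaction_speed`.
#' @export
simulate_agent <- function(config, schedule, seed = NULL) {
  stopifnot(inherits(config, "agent_config"))
  validate_schedule(schedule)
  if (!is.null(seed)) set.seed(seed)
  V <- c(path_1 = unname(config$v0[1]), path_2 = unname(config$v0[2]))
  site <- "reward_1"
  rows <- vector("list", sum(schedule$n_laps))
  r <- 0
  prev_threat <- FALSE; prev_path <- NA_character_
  for (s in seq_len(nrow(schedule))) {
    p_threat <- c(path_1 = schedule$p_threat_ht[s],
                  path_2 = schedule$p_threat_lt[s])
    for (l in seq_len(schedule$n_laps[s])) {
      if (config$switch_override) {
        # opsin-like one-lap memory: forced alternation after threats and no
        # value integration otherwise
        path <- if (prev_threat) setdiff(c("path_1", "path_2"), prev_path)
        else if (stats::runif(1) < 0.5) "path_1" else "path_2"
      } else {
        p1 <- 1 / (1 + exp(-config$beta * (V["path_2"] - V["path_1"])))
        path <- if (stats::runif(1) < p1) "path_1" else "path_2"
      }
      outcome <- stats::runif(1) < p_threat[path]
      led <- switch(schedule$led_policy[s],
                    none = FALSE,
                    half_of_puffs = outcome && stats::runif(1) < 0.5,
                    all_puffs = outcome,
                    stop("unknown led_policy: ", schedule$led_policy[s]))
      v_before <- V
      pe <- as.numeric(outcome) - V[path]
      alpha <- if (pe > 0) config$alpha_pos else config$alpha_neg
      V[path] <- V[path] + alpha * pe
      approach <- max(config$min_speed,
                      config$base_speed -
                        config$expectation_slope * v_before[path] +
                        stats::rnorm(1, 0, config$speed_noise_sd))
      reaction <- max(config$min_speed,
                      config$base_reaction + config$reaction_gain * pe +
                        stats::rnorm(1, 0, config$reaction_noise_sd))
      half <- stats::runif(1) < config$p_half
      end_site <- if (half) site else setdiff(c("reward_1", "reward_2"), site)
      r <- r + 1
      rows[[r]] <- data.frame(
        session = schedule$session[s],
        stage = if ("stage" %in% names(schedule)) schedule$stage[s] else NA,
        lap = l, path = path,
        lap_class = if (half) "half" else "full",
        start_site = site, end_site = end_site,
        threat_delivered = outcome, led = led,
        v_ht = unname(v_before["path_1"]), v_lt = unname(v_before["path_2"]),
        v_path = unname(v_before[path]), pe = unname(pe),
        approach_speed = approach, reaction_speed = reaction,
        stringsAsFactors = FALSE
      )
      site <- end_site
      prev_threat <- outcome; prev_path <- path
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Outcome-independent control agent
#'
#' Chooses a path by a fair coin flip on every lap, ignoring outcomes;
#' outcomes are Bernoulli draws at the paths' threat probabilities. Used as
#' the null model for calibrating the history-correlation significance rule.
#'
#' @param n_laps Number of laps.
#' @param p_ht,p_lt Threat probabilities of the high- and low-threat paths.
#' @return Choice-series data frame (`lap`, `session`, `path`,
#'   `choice_code`, `threat_delivered`).
#' @export
simulate_coinflip_agent <- function(n_laps, p_ht = 0.75, p_lt = 0.25) {
  choice <- stats::runif(n_laps) < 0.5
  path <- ifelse(choice, "path_1", "path_2")
  p <- ifelse(choice, p_ht, p_lt)
  data.frame(
    lap = seq_len(n_laps), session = "S1", path = path,
    choice_code = as.integer(choice),
    threat_delivered = stats::runif(n_laps) < p,
    stringsAsFactors = FALSE
  )
}

#' History-integrating agent with a planted window length
#'
#' Chooses the high-threat path with probability
#' `epsilon + (1 - 2 epsilon) (1 - est)`, where `est` is the trailing mean
#' of threat outcomes over the last `k_star` visits to that path (0.5 until
#' `k_star` visits have accumulated) and `epsilon` is an exploration floor
#' that keeps both paths sampled. Its choices are therefore driven by
#' exactly the `k_star`-lap trailing threat-probability estimate, so the
#' lagged choice-outcome correlation should peak at (or adjacent to)
#' `k_star`.
#'
#' @param n_laps Number of laps.
#' @param k_star Planted integration window (laps).
#' @param p_ht,p_lt Threat probabilities of the two paths.
#' @param epsilon Exploration floor on the choice probability.
#' @return Choice-series data frame as in [simulate_coinflip_agent()].
#' @export
simulate_integrator_agent <- function(n_laps, k_star = 5,
                                      p_ht = 0.75, p_lt = 0.25,
                                      epsilon = 0.1) {
  ht_outcomes <- numeric(0)
  path <- character(n_laps); threat <- logical(n_laps)
  for (i in seq_len(n_laps)) {
    est <- if (length(ht_outcomes) >= k_star) {
      mean(ht_outcomes[(length(ht_outcomes) - k_star + 1):length(ht_outcomes)])
    } else 0.5
    take_ht <- stats::runif(1) < (epsilon + (1 - 2 * epsilon) * (1 - est))
    path[i] <- if (take_ht) "path_1" else "path_2"
    threat[i] <- stats::runif(1) < (if (take_ht) p_ht else p_lt)
    if (take_ht) ht_outcomes <- c(ht_outcomes, as.numeric(threat[i]))
  }
  data.frame(
    lap = seq_len(n_laps), session = "S1", path = path,
    choice_code = as.integer(path == "path_1"),
    threat_delivered = threat,
    stringsAsFactors = FALSE
  )
}
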