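# shared fixtures: built in code, no files

default_geom <- maze_geometry()

# tracking frame from coordinate vectors at a fixed rate
make_tracking <- function(x, y, rate = 30, t0 = 0) {
  n <- max(length(x), length(y))
  data.frame(time_s = t0 + (seq_len(n) - 1) / rate,
             x_cm = rep_len(x, n), y_cm = rep_len(y, n))
}

# straight run along x = 10 from y0 to y1 at constant speed (cm/s), through
# reward_1 and threat_1
vertical_run <- function(y0 = 5, y1 = 80, speed = 10, rate = 30) {
  y <- seq(y0, y1, by = speed / rate)
  make_tracking(x = rep(10, length(y)), y = y, rate = rate)
}

# minimal event-list builder
ev <- function(time_s, roi, type) {
  data.frame(time_s = time_s, roi = roi, type = type, stringsAsFactors = FALSE)
}

# a small simulated session with tracking, events and agent truth
sim_session <- function(seed = 1, n_laps = 15, p_ht = 0.75, p_lt = 0.25,
                        config = agent_config()) {
  set.seed(seed)
  sch <- data.frame(session = "S1", stage = "probabilistic",
                    p_threat_ht = p_ht, p_threat_lt = p_lt,
                    led_policy = "half_of_puffs", n_laps = n_laps,
                    stringsAsFactors = FALSE)
  agent <- simulate_agent(config, sch)
  sim <- simulate_tracking(agent, default_geom, config)
  sim$agent <- agent
  sim
}

# probe cohort for neural checks: thin wrapper over the package's
# planted-truth generator
sim_probe_cohort <- function(seed, n_cells = 40, n_laps = 240, amplitude = 4,
                             props = c(outcome_ht = 0.1, outcome_lt = 0.1,
                                       signed_pe = 0.2, unsigned_pe = 0.1,
                                       expectation = 0.1, none = 0.4)) {
  simulate_pe_probe(seed, n_cells = n_cells, n_laps = n_laps,
                    amplitude = amplitude, props = props)
}

# full neural reduction: aligned tensor -> z -> magnitudes -> classification
classify_probe <- function(probe) {
  al <- align_to_event(probe$traces, probe$laps$t_enter_threat)
  kept <- setdiff(seq_len(nrow(probe$laps)), attr(al, "dropped"))
  z <- lap_type_average_z(al, probe$laps$lap_type[kept])
  mag <- response_magnitude(z)
  cls <- classify_pe_type(differential_activity(mag))
  list(aligned = al, z = z, mag = mag, cls = cls)
}
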