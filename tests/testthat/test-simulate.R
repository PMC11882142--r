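test_that("learning-rate limits behave analytically", {
  sch <- probe_schedule(n_laps = 100, p_threat_ht = 0.5, p_threat_lt = 0.5)
  # alpha = 0: values never move
  set.seed(40)
  ag0 <- simulate_agent(agent_config(alpha_pos = 0, alpha_neg = 0,
                                     v0 = c(ht = 0.3, lt = 0.3)), sch)
  expect_true(all(ag0$v_ht == 0.3))
  expect_true(all(ag0$v_lt == 0.3))
  # alpha = 1: a path's value equals its last outcome
  set.seed(41)
  ag1 <- simulate_agent(agent_config(alpha_pos = 1, alpha_neg = 1), sch)
  for (p in c("path_1", "path_2")) {
    idx <- which(ag1$path == p)
    if (length(idx) > 1) {
      expect_equal(ag1$v_path[idx[-1]],
                   as.numeric(ag1$threat_delivered[idx[-length(idx)]]))
    }
  }
  # values stay inside [0, 1]
  set.seed(42)
  ag <- simulate_agent(agent_config(), stage_schedule("probabilistic", n_laps = 30))
  expect_true(all(ag$v_ht >= 0 & ag$v_ht <= 1))
  expect_true(all(ag$v_lt >= 0 & ag$v_lt <= 1))
})

test_that("values converge to the planted Bernoulli rates on a 75/25 schedule", {
  sch <- data.frame(session = "S1", stage = "x", p_threat_ht = 0.75,
                    p_threat_lt = 0.25, led_policy = "none", n_laps = 2000)
  set.seed(43)
  v_ht <- v_lt <- numeric(4)
  for (r in 1:4) {
    ag <- simulate_agent(agent_config(beta = 0.5), sch)  # soft choice: both sampled
    late <- ag[ag$lap > 500, ]
    v_ht[r] <- mean(late$v_ht); v_lt[r] <- mean(late$v_lt)
  }
  expect_lt(abs(mean(v_ht) - 0.75), 0.05)
  expect_lt(abs(mean(v_lt) - 0.25), 0.05)
})

test_that("planted value-speed link slows approaches on the high-threat path", {
  sch <- data.frame(session = paste0("P", 1:5), stage = "probabilistic",
                    p_threat_ht = 0.75, p_threat_lt = 0.25,
                    led_policy = "none", n_laps = 40)
  set.seed(44)
  slower_on_ht <- logical(20)
  for (m in 1:20) {
    ag <- simulate_agent(agent_config(), sch)
    late <- ag[ag$session %in% c("P4", "P5"), ]
    slower_on_ht[m] <- mean(late$approach_speed[late$path == "path_1"]) <
      mean(late$approach_speed[late$path == "path_2"])
  }
  # sign test across simulated mice
  expect_lt(binom.test(sum(slower_on_ht), 20, 0.5,
                       alternative = "greater")$p.value, 0.05)
})

test_that("adaptive agents raise adaptive choice; forced switchers do not", {
  sch <- data.frame(session = paste0("P", 1:5), stage = "probabilistic",
                    p_threat_ht = 0.75, p_threat_lt = 0.25,
                    led_policy = "none", n_laps = 50)
  set.seed(45)
  frac <- function(cfg) {
    sapply(1:10, function(m) {
      ag <- simulate_agent(cfg, sch)
      c(first = adaptive_choice_fraction(ag[ag$session == "P1", ]),
        last = adaptive_choice_fraction(ag[ag$session == "P5", ]))
    })
  }
  adaptive <- frac(agent_config())
  override <- frac(agent_config(switch_override = TRUE))
  expect_gt(mean(adaptive["last", ]) - mean(adaptive["first", ]), 0.03)
  expect_gt(mean(adaptive["last", ]), 0.65)
  expect_lt(abs(mean(override["last", ]) - 0.5), 0.1)
  # forced switchers rarely stay on the low-threat path after a threat there
  set.seed(46)
  ag_ov <- simulate_agent(agent_config(switch_override = TRUE), sch)
  stay <- post_outcome_switch(ag_ov, "path_2", lt_path = "path_2")
  expect_true(all(stay$prop_lt_next == 0, na.rm = TRUE))
})

test_that("tracking realization round-trips the lap structure exactly", {
  sim <- sim_session(seed = 46, n_laps = 18)
  evs <- detect_roi_events(sim$tracking, default_geom)
  laps <- segment_laps(evs, default_geom,
                       puff_log = sim$events[sim$events$event == "puff", ],
                       led_log = sim$events[sim$events$event == "led", ])
  expect_equal(nrow(laps), nrow(sim$agent))
  expect_equal(laps$path, sim$agent$path)
  expect_equal(laps$lap_class, sim$agent$lap_class)
  expect_equal(laps$start_site, sim$agent$start_site)
  expect_equal(laps$threat_delivered, sim$agent$threat_delivered)
  expect_equal(laps$led, sim$agent$led)
  # detected entry times within one video frame of the scheduled ones
  expect_lt(max(abs(laps$t_enter_threat - sim$laps$t_enter_threat)), 1 / 30 + 1e-9)
  # scheduled approach speed recovered from the tracking
  sp <- speed_metrics(laps, sim$tracking)
  expect_lt(max(abs(sp$approach_speed - sim$agent$approach_speed)), 1e-6)

  empty <- simulate_tracking(sim$agent[0, ], default_geom)
  expect_equal(nrow(empty$tracking), 0)
})

test_that("calcium transients follow the planted amplitude laws", {
  laps <- data.frame(t_enter_threat = c(10, 30, 50), path = "path_1",
                     threat_delivered = c(TRUE, TRUE, FALSE),
                     led = FALSE, pe = c(0.9, 0.02, -0.5),
                     v_path = c(0.1, 0.98, 0.5))
  cells <- data.frame(cell = c("out", "spe"), type = c("outcome_ht", "signed_pe"),
                      direction = 1, amplitude = 5, noise_sd = 0, led_gain = 1,
                      expected_label = NA, stringsAsFactors = FALSE)
  cal <- simulate_calcium(laps, cells, t_end = 60)
  tr <- cal$traces
  # zero noise: peak of the outcome cell's transient equals the amplitude
  win1 <- tr$time_s >= 10 & tr$time_s < 13
  expect_equal(max(tr$out[win1]), 5, tolerance = 1e-9)
  # no transient on the omission lap for an outcome cell
  win3 <- tr$time_s >= 50 & tr$time_s < 53
  expect_equal(max(abs(tr$out[win3])), 0)
  # signed-PE cell: near-zero transient when the threat was expected (PE ~ 0)
  win2 <- tr$time_s >= 30 & tr$time_s < 33
  expect_lt(max(abs(tr$spe[win2])), 5 * 0.05)
  # and a dip for unexpected omission (negative PE)
  expect_lt(min(tr$spe[win3]), -1)
})

test_that("the same seed reproduces every simulated output exactly", {
  sch <- data.frame(session = c("P1", "P2"), stage = "probabilistic",
                    p_threat_ht = 0.75, p_threat_lt = 0.25,
                    led_policy = "half_of_puffs", n_laps = 8)
  cells <- cell_population(n = 5)
  run <- function() simulate_mouse(config = agent_config(), schedule = sch,
                                   seed = 99, imaging_sessions = "P2",
                                   cells = cells)
  a <- run(); b <- run()
  expect_identical(a$agent, b$agent)
  expect_identical(a$sessions, b$sessions)
  expect_identical(a$calcium, b$calcium)
})
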