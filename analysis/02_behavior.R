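#!/usr/bin/env Rscript
# Behavioral analysis of the simulated cohorts: adaptive path choice per
# session (learning curves), approach speeds per path in the last
# probabilistic session, and the expectation x outcome reaction-speed
# pattern. Group inference uses the package's mixed / repeated-measures
# ANOVA with Greenhouse-Geisser correction.
# Requires analysis/01_simulate_cohort.R to have run.

library(mazepe)

manifest <- read.csv("results/cohort/manifest.csv", stringsAsFactors = FALSE)
read_laps <- function(f) read.csv(f, stringsAsFactors = FALSE)

## adaptive path choice per session ------------------------------------------
rows <- list()
for (i in seq_len(nrow(manifest))) {
  laps <- read_laps(manifest$file[i])
  for (s in unique(laps$session)) {
    rows[[length(rows) + 1]] <- data.frame(
      group = manifest$group[i], mouse = manifest$mouse[i], session = s,
      stage = laps$stage[laps$session == s][1],
      adaptive_pct = 100 * adaptive_choice_fraction(laps[laps$session == s, ]))
  }
}
choice <- do.call(rbind, rows)
write_table_csv(choice, "results/behavior_adaptive_choice.csv")

p_stage <- choice[choice$stage == "probabilistic", ]
tab <- mixed_anova(p_stage, dv = "adaptive_pct", subject = "mouse",
                   within = "session", between = "group")
write_table_csv(tab, "results/behavior_choice_anova.csv")
cat("adaptive choice, probabilistic stage (group x session mixed ANOVA):\n")
print(tab[, c("effect", "df_num", "df_den", "F", "p", "correction_applied")])

ctrl <- p_stage[p_stage$group == "control", ]
tab1 <- one_way_rm_anova(ctrl, dv = "adaptive_pct", subject = "mouse",
                         within = "session")
cat(sprintf("control group session effect: F(%g,%g) = %.3f, p = %.4g\n",
            tab1$df_num_corr, tab1$df_den_corr, tab1$F, tab1$p))

## approach speed by path and the expectation x outcome pattern in P5 --------
rows <- list()
for (i in seq_len(nrow(manifest))) {
  laps <- read_laps(manifest$file[i])
  p5 <- laps[laps$session == "P5", ]
  p5$fast_slow <- median_split(p5$approach_speed)
  p5$expectation <- expectation_label(p5$fast_slow, p5$threat_delivered)
  rows[[length(rows) + 1]] <- data.frame(
    group = manifest$group[i], mouse = manifest$mouse[i],
    speed_ht = mean(p5$approach_speed[p5$path == "path_1"]),
    speed_lt = mean(p5$approach_speed[p5$path == "path_2"]),
    react_surprising_threat = mean(
      p5$reaction_speed[p5$expectation == "surprising" & p5$threat_delivered]),
    react_expected_threat = mean(
      p5$reaction_speed[p5$expectation == "expected" & p5$threat_delivered]),
    react_surprising_omission = mean(
      p5$reaction_speed[p5$expectation == "surprising" & !p5$threat_delivered]),
    react_expected_omission = mean(
      p5$reaction_speed[p5$expectation == "expected" & !p5$threat_delivered]))
}
speeds <- do.call(rbind, rows)
write_table_csv(speeds, "results/behavior_speeds_P5.csv")

ctrl_sp <- speeds[speeds$group == "control", ]
tt <- unpaired_t_test(ctrl_sp$speed_ht, ctrl_sp$speed_lt)
cat(sprintf(paste0("control P5 approach speed ht vs lt: %.1f vs %.1f cm/s, ",
                   "t(%g) = %.3f, p = %.4g\n"),
            mean(ctrl_sp$speed_ht), mean(ctrl_sp$speed_lt),
            tt$df, tt$statistic, tt$p))
cat(sprintf("reaction after surprising vs expected threats: %.1f vs %.1f cm/s\n",
            mean(ctrl_sp$react_surprising_threat),
            mean(ctrl_sp$react_expected_threat)))
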