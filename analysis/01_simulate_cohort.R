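#!/usr/bin/env Rscript
# Simulate the study cohorts used by the downstream analysis scripts:
#  - "control" mice: adaptive Rescorla-Wagner agents (learn threat values)
#  - "stimulated" mice: opsin-like agents that switch paths after every
#    threat but never integrate threat history
# Each mouse runs the full probabilistic paradigm (T1-T5, P1-P5, R1-R5,
# 60 laps/session). Lap tables are written under results/cohort/.

library(mazepe)

seed0 <- 2024
n_per_group <- 6
dir.create("results/cohort", showWarnings = FALSE, recursive = TRUE)

sch <- stage_schedule("probabilistic", n_laps = 60, led_policy = "none")
groups <- list(control = agent_config(),
               stimulated = agent_config(switch_override = TRUE))

manifest <- list()
for (g in names(groups)) {
  for (m in seq_len(n_per_group)) {
    set.seed(seed0 + 100 * match(g, names(groups)) + m)
    laps <- simulate_agent(groups[[g]], sch)
    f <- sprintf("results/cohort/laps_%s_m%02d.csv", g, m)
    write_table_csv(laps, f)
    manifest[[length(manifest) + 1]] <- data.frame(
      group = g, mouse = sprintf("%s_m%02d", g, m), file = f,
      n_laps = nrow(laps))
  }
}
manifest <- do.call(rbind, manifest)
write_table_csv(manifest, "results/cohort/manifest.csv")

cat("simulated", nrow(manifest), "mice x", sum(sch$n_laps), "laps each\n")
cat("groups:", paste(names(groups), collapse = ", "),
    "| schedule:", paste(unique(sch$stage), collapse = " -> "), "\n")
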