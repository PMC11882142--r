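#!/usr/bin/env Rscript
# End-to-end demonstration: simulate one imaged mouse, write its raw-format
# files (tracking, event log, traces), then run the full pipeline from those
# files alone and leave its outputs under results/pipeline_demo/.

library(mazepe)

dir.create("results/pipeline_demo/raw", showWarnings = FALSE, recursive = TRUE)
sch <- data.frame(session = c("P4", "P5"), stage = "probabilistic",
                  p_threat_ht = 0.75, p_threat_lt = 0.25,
                  led_policy = "none", n_laps = 40)
cells <- cell_population(n = 30, amplitude = 4)
mouse <- simulate_mouse(config = agent_config(), schedule = sch, seed = 515,
                        imaging_sessions = "P5", cells = cells)

sessions <- list(); traces <- list()
for (s in names(mouse$sessions)) {
  tp <- file.path("results/pipeline_demo/raw", paste0("tracking_", s, ".csv"))
  ep <- file.path("results/pipeline_demo/raw", paste0("events_", s, ".csv"))
  write_table_csv(mouse$sessions[[s]]$tracking, tp)
  write_table_csv(mouse$sessions[[s]]$events, ep)
  sessions[[s]] <- list(tracking = tp, events = ep)
}
trp <- "results/pipeline_demo/raw/traces_P5.csv"
write_table_csv(mouse$calcium$P5$traces, trp)
traces$P5 <- trp

res <- run_pipeline(sessions, "results/pipeline_demo", traces = traces)
cat("pipeline outputs:\n")
print(list.files("results/pipeline_demo", pattern = "csv|txt"))
cat(sprintf("laps segmented: %d (%d full, %d half)\n",
            nrow(res$laps), sum(res$laps$lap_class == "full"),
            sum(res$laps$lap_class == "half")))
cat(sprintf("adaptive choice P5: %.0f%%\n",
            100 * adaptive_choice_fraction(
              res$laps[res$laps$session == "P5", ])))
labs <- table(res$neural$P5$label)
cat("P5 cell classification:", paste(names(labs), labs, collapse = ", "), "\n")
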