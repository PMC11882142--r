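#!/usr/bin/env Rscript
# How past outcomes drive path choice: post-threat switching per session and
# the lap-lagged correlation between choice and trailing threat-probability
# estimates (window lengths k = 1..50), compared between cohorts.
# Requires analysis/01_simulate_cohort.R to have run.

library(mazepe)

manifest <- read.csv("results/cohort/manifest.csv", stringsAsFactors = FALSE)
p_laps <- function(f) {
  laps <- read.csv(f, stringsAsFactors = FALSE)
  laps[laps$stage == "probabilistic", ]
}

## post-threat switching (proportion choosing lt-p on the next lap) ----------
switch_rows <- list()
for (i in seq_len(nrow(manifest))) {
  laps <- p_laps(manifest$file[i])
  for (cond in c("path_1", "path_2")) {
    po <- post_outcome_switch(laps, conditioning_path = cond)
    po$group <- manifest$group[i]; po$mouse <- manifest$mouse[i]
    po$conditioning_path <- cond
    switch_rows[[length(switch_rows) + 1]] <- po
  }
}
switching <- do.call(rbind, switch_rows)
write_table_csv(switching, "results/history_post_threat_switch.csv")

agg <- aggregate(prop_lt_next ~ group + conditioning_path, switching, mean,
                 na.rm = TRUE)
cat("proportion choosing the low-threat path after a threat:\n")
print(agg)

## lap-lagged choice-outcome correlation -------------------------------------
corr_rows <- list(); sig_rows <- list()
for (i in seq_len(nrow(manifest))) {
  series <- choice_series(p_laps(manifest$file[i]))
  hc <- history_choice_correlation(series, k_range = 1:50)
  by_k <- hc$by_k
  by_k$group <- manifest$group[i]; by_k$mouse <- manifest$mouse[i]
  corr_rows[[length(corr_rows) + 1]] <- by_k
  sig_rows[[length(sig_rows) + 1]] <- data.frame(
    group = manifest$group[i], mouse = manifest$mouse[i],
    path = names(hc$significant_any_k),
    significant = unname(hc$significant_any_k))
}
corr <- do.call(rbind, corr_rows)
sig <- do.call(rbind, sig_rows)
write_table_csv(corr, "results/history_correlation_by_k.csv")
write_table_csv(sig, "results/history_significant_mice.csv")

cat("\nmice with a significant choice-history correlation at any k:\n")
for (p in unique(sig$path)) {
  f1 <- sig$significant[sig$group == "control" & sig$path == p]
  f2 <- sig$significant[sig$group == "stimulated" & sig$path == p]
  res <- tryCatch(count_significant_mice(f1, f2), error = function(e) NULL)
  if (is.null(res)) {
    cat(sprintf("  %s: control %d/%d, stimulated %d/%d (test degenerate)\n",
                p, sum(f1), length(f1), sum(f2), length(f2)))
  } else {
    cat(sprintf("  %s: control %d/%d, stimulated %d/%d, X2(1) = %.3f, p = %.4g\n",
                p, sum(f1), length(f1), sum(f2), length(f2),
                res$statistic, res$p))
  }
}
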