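#!/usr/bin/env Rscript
# Reproductive-isolation events and population structure from the sweep run
# by 02_run_scenarios.R: a Table-2-style event/duration summary per movement
# fraction, and the F trajectories (Figure-2 analogue) for 2.5, 5, 10 and
# 100% movement. Writes results/ri_summary.csv and results/f_trajectories.pdf.

library(dmland)

stats <- read.csv("results/replicate_stats.csv")

rows <- lapply(split(stats, stats$movement_fraction), function(df) {
  per_rep <- lapply(split(df, df$replicate), function(r) {
    event_durations(r$ri_flag[r$generation > 0] == 1)
  })
  durations <- unlist(lapply(per_rep, `[[`, "durations"))
  data.frame(
    movement_pct = 100 * df$movement_fraction[1],
    mean_ri_generations = mean(vapply(per_rep, `[[`, 0, "n_flagged")),
    mean_duration = if (length(durations)) mean(durations) else NA_real_,
    max_duration = if (length(durations)) max(durations) else NA_real_)
})
ri <- do.call(rbind, rows)
ri <- ri[order(-ri$movement_pct), ]
print(ri, row.names = FALSE)
write.csv(ri, "results/ri_summary.csv", row.names = FALSE)

pdf("results/f_trajectories.pdf", width = 7, height = 5)
keep <- stats$movement_fraction %in% c(0.025, 0.05, 0.10, 1.00) &
  stats$replicate == 1 & stats$generation > 0
plot(NULL, xlim = c(0, 1000), ylim = c(0, 0.45),
     xlab = "Generation", ylab = "F = 1 - Ho/He",
     main = "Isolation by distance across movement strategies")
cols <- setNames(c("black", "red3", "dodgerblue3", "grey50"),
                 c("0.025", "0.05", "0.1", "1"))
for (f in unique(stats$movement_fraction[keep])) {
  df <- stats[keep & stats$movement_fraction == f, ]
  lines(df$generation, df$F, col = cols[[as.character(f)]], lwd = 1.5)
}
legend("topleft", legend = paste0(c(2.5, 5, 10, 100), "% movement"),
       col = cols, lwd = 1.5, bty = "n")
dev.off()
cat("Wrote results/ri_summary.csv and results/f_trajectories.pdf\n")
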