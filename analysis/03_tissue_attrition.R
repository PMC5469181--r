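#!/usr/bin/env Rscript

# Whole-epithelium attrition over the adult lifetime.
# Mouse: full Poisson-mixture trajectory (and its linear approximation).
# Human: linear-slope projections for both niche-size estimates and both
# mutational targets.

suppressPackageStartupMessages(library(cryptdrift))
dir.create("results", showWarnings = FALSE)

mouse <- scenario_preset("mouse_si")
curves <- lapply(c("division", "differentiation"), function(tg) {
  scn <- tissue_scenario(mouse$crypt, mouse$dfe, tg, mouse$lifetime_days)
  tr <- tissue_trajectory(scn)
  data.frame(target = tg, time_days = tr$time, fraction = tr$fraction)
})
mouse_tab <- do.call(rbind, curves)
for (tg in c("division", "differentiation")) {
  final <- mouse_tab$fraction[mouse_tab$target == tg]
  cat(sprintf("Mouse, %s-rate mutations: %.3f%% decline over 3 adult years\n",
              tg, (1 - final[length(final)]) * 100))
}

human <- human_scenarios()
cat("\nHuman colon, 75 adult years (linear slope):\n")
print(human, digits = 4)
cat("\nThe 20-cell-niche division scenario tracks the mouse (~0.4-0.5%),\n")
cat("while a 6-cell niche or neutral differentiation-rate mutations give\n")
cat("double-digit percentage declines.\n")

write.table(mouse_tab, "results/attrition_mouse.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
write.table(human, "results/attrition_human.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
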