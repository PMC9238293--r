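#!/usr/bin/env Rscript
# Sweeps the actuator setting from 45 to 65 C in 5 C steps, couples each
# steady temperature field to the circulation model, and summarizes how
# deep heating and the predicted flow increase grow with the setting.

suppressPackageStartupMessages(library(pennesflow))
spacing <- 2

cfg <- default_config(spacing = spacing)
sw <- run_sweep(cfg)
print(sw)

dir.create("results/sweep", recursive = TRUE, showWarnings = FALSE)
write.csv(sw$summary, "results/sweep/summary.csv", row.names = FALSE)

s <- sw$summary
at <- function(probe, depth, col) {
  sub <- s[s$probe == probe & s$coordinate_mm == depth, ]
  stats::setNames(sub[[col]], sub$setting_C)
}
cat("\ntemperature at 2 cm under the actuator centroid, by setting:\n")
print(round(at("depth_actuator", 20, "temperature_C"), 2))
cat("elevation over core at 2 cm spans",
    paste(round(range(at("depth_actuator", 20, "temperature_C") - 37), 2),
          collapse = " to "), "C across the sweep\n")
cat("\nflow fold-change at 2 cm under the centroid, by setting:\n")
print(round(at("flow_depth_actuator", 20, "fold_change"), 2))
cat("\nflow fold-change at 3 cm under the centroid, by setting:\n")
print(round(at("flow_depth_actuator", 30, "fold_change"), 2))
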