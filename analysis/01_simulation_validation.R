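#!/usr/bin/env Rscript
# Source-to-sensor validation study.
#
# 20 directed source networks with low and 20 with high mean local
# efficiency (6 nodes, 6 of the 30 possible connections) drive MVAR
# dynamics for 30 s at 1 kHz, are projected to 204 planar gradiometers and
# perturbed with sensor noise at SNR in {0.1, 1, 3, 10, Inf}.  Each
# recording then runs through the full analysis chain, and we ask whether
# the sensor-level mean local efficiency still separates the two source
# classes at binarization thresholds of 85%, 95% and 99%.
#
# Writes results/simulation_separation.csv (per-cell rank-sum tests) and
# results/simulation_study.csv (per-network measurements).

library(effconn)

dir.create("results", showWarnings = FALSE)

message("Running the simulation study (this takes a few minutes)...")
study <- simulation_study(n_per_class = 20, freq_resolution = 2, seed = 101)
summary <- summarize_simulation_study(study)

write.csv(study, "results/simulation_study.csv", row.names = FALSE)
write.csv(summary, "results/simulation_separation.csv", row.names = FALSE)

truth <- unique(study[c("network", "class", "source_mean_leff")])
p_src <- wilcox.test(source_mean_leff ~ class, truth, exact = FALSE)$p.value

message(sprintf(
  "Source-level classes are cleanly separated (rank-sum p = %.2g).", p_src))
message("Sensor-level separation by SNR and threshold:")
print(summary, digits = 3)

sig <- summary$p_value < 0.05 & summary$median_high > summary$median_low
message(sprintf(
  "%d of %d SNR x threshold cells show significant sensor-level separation.",
  sum(sig, na.rm = TRUE), nrow(summary)))
message(paste0(
  "Note: with the smooth-gain forward model and 30-s recordings, the\n",
  "class difference does not survive projection and refitting; see the\n",
  "methods vignette for the stage-by-stage analysis of where it is lost."))
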