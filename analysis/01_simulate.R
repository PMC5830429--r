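#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study datasets.
#
# Two datasets are produced under results/data/:
#   - the capacity experiment: 60 cells stimulated with the ascending
#     7-concentration protocol (100 nM - 10 uM, K = 5 pulses each,
#     ~1% per-pulse desensitization), as a peak table plus the generator's
#     ground truth (per-cell mean dose-response matrix);
#   - the adaptation experiment: 25 cells stimulated 20 times at 250 nM.

library(chancap)

dir.create("results/data", recursive = TRUE, showWarnings = FALSE)
seed <- 20260

cfg <- simulation_config(n_cells = 60, seed = seed)
out <- generate_peak_table(cfg, compute_truth = FALSE)
write_peak_table(out$peaks, "results/data/peaks_capacity.csv")
jsonlite::write_json(
  list(concentrations_nM = out$truth$concentrations_nM,
       mu = out$truth$mu,
       noise = out$truth$noise,
       desensitization_d = out$truth$desensitization_d),
  "results/data/ground_truth.json", digits = NA)

# as in the original repeated-stimulation experiment, the recorded cells
# respond at 250 nM; noise at the response-regime level of the defaults
adesign <- stimulus_design(concentrations_nM = 250, n_replicates = 20)
acfg <- simulation_config(n_cells = 25, design = adesign,
                          noise = data.frame(concentration_nM = 250,
                                             sigma = 0.10, nu = 10),
                          mu_model = list(ec50_log10_range = log10(c(100,
                                                                     250))),
                          seed = seed + 1)
apk <- generate_peak_table(acfg, compute_truth = FALSE)$peaks
write_peak_table(apk, "results/data/peaks_adaptation.csv")

cat("capacity experiment:", length(unique(out$peaks$cell_id)), "cells,",
    nrow(out$peaks), "peaks (7 concentrations x 5 replicates)\n")
cat("adaptation experiment:", length(unique(apk$cell_id)), "cells,",
    nrow(apk), "peaks (20 pulses at 250 nM)\n")
cat("per-pulse desensitization factor d =", cfg$desensitization_d, "\n")
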