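#!/usr/bin/env Rscript

# Stage 1 of the synthetic VAD study: generate the full experimental grid
# on one synthetic phantom and write each experiment as a fixture
# directory under results/fixtures/.
#
# Mirrors the physical protocol: peak traction force from 30 N to 110 N in
# 20 N steps at 30 N/s; in the manual setup each peak is run once per
# instrumented brain region (the sonomicrometry system drives six channels:
# three fixed plus three brain crystals), with four extra repeats at 70 N
# for the cortical and ventricular sets; in the automatic setup only the
# cortical region under the cup is instrumented, with four repeats at 70 N.

suppressPackageStartupMessages(library(vadstrain))

seed <- 1L
out_root <- "results/fixtures"
dir.create(out_root, recursive = TRUE, showWarnings = FALSE)

layout <- generate_layout(seed = seed)
model <- deformation_model()
regions <- c("cortical_under_cup", "ventricular", "sensorimotor")
peaks <- seq(30, 110, by = 20)

manifest <- list()
k <- 0L
run_one <- function(peak, region, mode, tag) {
  k <<- k + 1L
  exp_k <- simulate_experiment(
    peak = peak, region = region, mode = mode, layout = layout,
    model = model, noise = measurement_noise(seed = seed + k), seed = seed + k)
  dir <- file.path(out_root, tag)
  write_fixture(exp_k, dir)
  manifest[[tag]] <<- list(peak = peak, region = region, mode = mode)
  invisible(dir)
}

for (region in regions) {
  for (peak in peaks) {
    run_one(peak, region, "manual",
            sprintf("manual_%s_%03dN", region, peak))
  }
}
for (region in c("cortical_under_cup", "ventricular")) {
  for (rep in 1:4) {
    run_one(70, region, "manual",
            sprintf("manual_%s_070N_rep%d", region, rep))
  }
}
for (rep in 1:4) {
  run_one(70, "cortical_under_cup", "automatic",
          sprintf("automatic_cortical_under_cup_070N_rep%d", rep))
}

jsonlite::write_json(manifest, file.path(out_root, "experiments.json"),
                     auto_unbox = TRUE, pretty = TRUE)
cat(sprintf("wrote %d synthetic experiments to %s\n", k, out_root))
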