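#!/usr/bin/env Rscript

# Stage 3: peak force vs peak strain. For every fixture, extract the force
# peak and the strain peak of the selected crystal pair, then correlate
# them per setup and region (Pearson r, two-sided p on n - 2 df).
#   results/tables/peaks.csv         one row per experiment
#   results/tables/correlation.csv   r, p, regression line per condition

suppressPackageStartupMessages(library(vadstrain))

fix_root <- "results/fixtures"
tab_dir <- "results/tables"
dir.create(tab_dir, recursive = TRUE, showWarnings = FALSE)
manifest <- jsonlite::fromJSON(file.path(fix_root, "experiments.json"))

peaks <- do.call(rbind, lapply(names(manifest), function(tag) {
  run <- run_fixture(file.path(fix_root, tag))
  m <- manifest[[tag]]
  data.frame(tag = tag, mode = m$mode, region = m$region,
             nominal_peak_N = m$peak,
             force_peak_N = run$peaks$force_peak_N,
             strain_peak = run$peaks$strain_peak,
             pair = paste(run$strain$pair, collapse = "-"),
             D0_mm = run$strain$D0_mm)
}))
write.csv(peaks, file.path(tab_dir, "peaks.csv"), row.names = FALSE,
          quote = FALSE)

corr <- do.call(rbind, lapply(split(peaks, list(peaks$mode, peaks$region),
                                    drop = TRUE), function(g) {
  # conditions with a single nominal force level (e.g. automatic repeats
  # only) have no force variance to correlate against
  if (nrow(g) < 3 || stats::sd(g$strain_peak) == 0 ||
      stats::sd(g$force_peak_N) == 0) return(NULL)
  ct <- correlate_force_strain(g$force_peak_N, g$strain_peak)
  data.frame(mode = g$mode[1], region = g$region[1], n = ct$n,
             r = ct$r, p = ct$p, slope_per_N = ct$slope,
             intercept = ct$intercept,
             significant_at_0.05 = ct$p < 0.05)
}))
write.csv(corr, file.path(tab_dir, "correlation.csv"), row.names = FALSE,
          quote = FALSE)

cat("force-strain correlation per condition:\n")
print(corr, row.names = FALSE, digits = 3)
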