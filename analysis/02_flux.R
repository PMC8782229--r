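#!/usr/bin/env Rscript
# Stage 2: convert the three-point chamber traces to volumetric fluxes
# (l/h) and daily mass output (g/d) via the accumulation-chamber equations.
# Writes results/flux.csv.

library(pacflux)

trial <- read_trial("results")
flux <- flux_table(trial)

for (g in pac_gases()) {
  f <- flux[flux$gas == g, ]
  cat(sprintf(
    "%-4s mean %.4f l/h (sd %.4f) | mean %.2f g/d | %d negative, %d nonlinear\n",
    g, mean(f$flux_lph), sd(f$flux_lph), mean(f$flux_gpd),
    sum(grepl("negative_flux", f$qc_flags)),
    sum(grepl("nonlinear_trace", f$qc_flags))
  ))
}

utils::write.csv(flux, "results/flux.csv", row.names = FALSE)
cat("Wrote results/flux.csv (", nrow(flux), "rows )\n")
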