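#!/usr/bin/env Rscript
# Stage 5: how stable is the animal ranking across days? Pairwise day
# correlations / regressions of fluxes, and top/bottom-10 ranking
# persistence. Writes per-gas correlation matrices and ranking summaries.

library(pacflux)

flux <- utils::read.csv("results/flux.csv", stringsAsFactors = FALSE)

for (g in pac_gases()) {
  dm <- day_correlation_matrix(flux, g)
  print(dm)
  d1 <- dm$correlation[1, -1]
  cat(sprintf("  day 1 vs others: min r = %.2f (day %s), max r = %.2f (day %s)\n",
              min(d1), names(which.min(d1)), max(d1), names(which.max(d1))))
  utils::write.csv(dm$correlation,
                   sprintf("results/day_correlation_%s.csv", g))
  utils::write.csv(dm$r_squared,
                   sprintf("results/day_r_squared_%s.csv", g))

  rk <- ranking_consistency(flux, g, k = 10)
  print(rk)
  utils::write.csv(rk$per_animal, sprintf("results/ranking_%s.csv", g),
                   row.names = FALSE)
}
cat("Wrote day-correlation and ranking CSVs under results/\n")
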