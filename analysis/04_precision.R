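#!/usr/bin/env Rscript
# Stage 4: number-of-days precision curves P_n = 1.96 sqrt(s2_e / n) from
# the fitted error variances, and the day counts needed for benchmark
# targets. Writes results/precision.csv.

library(pacflux)

vc <- utils::read.csv("results/varcomp.csv", stringsAsFactors = FALSE)

curves <- do.call(rbind, lapply(seq_len(nrow(vc)), function(i) {
  precision_curve(vc$var_error[i], 17, gas = vc$gas[i])
}))
utils::write.csv(curves, "results/precision.csv", row.names = FALSE)

for (i in seq_len(nrow(vc))) {
  g <- vc$gas[i]
  s2e <- vc$var_error[i]
  p <- curves[curves$gas == g, ]
  cat(sprintf("%-4s P_1 = %.4g, P_3 = %.4g, P_7 = %.4g, P_17 = %.4g l/h\n",
              g, p$P_n[1], p$P_n[3], p$P_n[7], p$P_n[17]))
  # days to halve / quarter the single-day CI range
  for (frac in c(0.5, 0.25)) {
    tgt <- frac * p$P_n[1]
    cat(sprintf("     target %.4g l/h (%d%% of P_1): %d days\n",
                tgt, round(100 * frac), days_for_precision(s2e, tgt)))
  }
}
cat("Wrote results/precision.csv\n")
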