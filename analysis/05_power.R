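#!/usr/bin/env Rscript

# Stage 5: a priori power analysis and its Monte-Carlo confirmation.
#
# Computes the smallest detectable correlation at n = 146, alpha = 0.05,
# power = 0.80 from the Fisher-z approximation, then confirms it by
# simulation: rejection rates with the effect planted at that magnitude and
# under the null. Writes results/05_power.tsv.

suppressPackageStartupMessages(library(netseg))

n <- 146
r_min <- min_detectable_r(n = n, alpha = 0.05, power = 0.80)
cat(sprintf("Minimum detectable correlation at n = %d: %.4f\n", n, r_min))

mc <- function(rho, reps = 1000, seed0 = 500) {
  mean(vapply(seq_len(reps), function(i) {
    set.seed(seed0 + i)
    x <- rnorm(n)
    y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
    pearson_with_p(x, y)$p < 0.05
  }, logical(1)))
}
power_hat <- mc(0.23)
type1_hat <- mc(0, seed0 = 9500)
cat(sprintf("Monte-Carlo power at r = 0.23: %.3f (target 0.80)\n", power_hat))
cat(sprintf("Monte-Carlo type-I rate:       %.3f (nominal 0.05)\n", type1_hat))

dir.create("results", showWarnings = FALSE)
write.table(data.frame(quantity = c("min_detectable_r", "mc_power", "mc_type1"),
                       value = c(r_min, power_hat, type1_hat)),
            "results/05_power.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
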