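#!/usr/bin/env Rscript
# Body-weight-style comparisons: heteroscedastic groups (irradiated animals
# gain weight more variably than controls) analysed with Welch and
# Brown-Forsythe ANOVA plus Dunnett's T3 pairwise test, the robust toolchain
# used when equal variances cannot be assumed.
suppressPackageStartupMessages(library(gatedlung))

dir.create("results", showWarnings = FALSE)

# high-dose animals plateau ~5 g below controls with larger spread
weights <- withr::with_seed(7L, list(
  control      = rnorm(6, mean = 29.5, sd = 0.8),
  low_dose     = rnorm(6, mean = 27.0, sd = 1.2),
  high_dose    = rnorm(6, mean = 24.0, sd = 2.0)))

cat("Simulated endpoint body weights (g):\n")
print(sapply(weights, function(x) c(mean = mean(x), sd = sd(x))), digits = 3)
cat("\n")
print(welch_anova(weights))
print(brown_forsythe(weights))
cat("\nDunnett T3 pairwise comparisons:\n")
t3 <- dunnett_t3(weights)
print(as.data.frame(t3), digits = 3)

utils::write.csv(as.data.frame(t3), "results/weight_dunnett_t3.csv",
                 row.names = FALSE)
cat("\nWrote results/weight_dunnett_t3.csv\n")
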