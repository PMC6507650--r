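#!/usr/bin/env Rscript
# Chromosome mis-segregation rates and the inferred probability of
# carrying at least one aneuploid chromosome, from the scored
# chromosome-V counts shipped with the package, plus a binomial
# calibration check of the estimator on simulated counts.

library(sacsize)
set.seed(20260925)
dir.create("results", showWarnings = FALSE)

counts <- read.csv(system.file("extdata", "misseg_counts.csv",
                               package = "sacsize"))
s <- aneuploidy_summary(counts, aggregate = "mean_p")
s_pooled <- aneuploidy_summary(counts, aggregate = "pooled")

per_rep <- s$per_replicate
per_rep$rate_pct <- round(100 * per_rep$rate, 2)
write.csv(per_rep, "results/misseg_rates.csv", row.names = FALSE)

agg <- merge(s$per_condition, s_pooled$per_condition,
             by = "condition", suffixes = c("_mean_p", "_pooled"))
write.csv(agg, "results/aneuploidy_probabilities.csv", row.names = FALSE)

for (i in seq_len(nrow(per_rep))) {
  message(sprintf("%-18s replicate %d: %5.2f%% (%d/%d)",
                  per_rep$condition[i], per_rep$replicate[i],
                  per_rep$rate_pct[i], per_rep$n_missegregating[i],
                  per_rep$n_total[i]))
}
message(sprintf(
  "P(>=1 aneuploid chromosome), replicate-averaged: %.0f%% for tub2-401 at 22C, %.0f%% for GAL1-MAD2 on galactose.",
  100 * agg$p_aneuploid_mean_p[agg$condition == "tub2-401_22C"],
  100 * agg$p_aneuploid_mean_p[agg$condition == "GAL1-MAD2_YEPRG"]))

# estimator calibration: binomial counts at a known true rate
true_R <- 0.05
est <- replicate(1000, {
  cc <- simulate_misseg_counts(true_R, 200)
  aneuploidy_probability(misseg_rate(cc$n_missegregating, cc$n_total))
})
message(sprintf(
  "Calibration at true R = %.2f (n = 200 scored cells): mean estimated P = %.2f vs true P = %.2f.",
  true_R, mean(est), aneuploidy_probability(true_R)))
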