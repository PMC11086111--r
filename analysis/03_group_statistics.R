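#!/usr/bin/env Rscript

# Stage 3: the inferential layer.
#
# Sex comparison of every parameter (Shapiro-Wilk-gated Student's t or
# Mann-Whitney U, Cohen's d with the average-variance denominator), the
# height-posture Pearson correlations with the p < 0.05 & r > 0.45
# relevance rule, and test-retest reliability (ICC(3,k), SEM, MDC95) over
# the retest subgroup. Writes the three report tables under results/.

suppressMessages(library(posturekit))

profiles <- utils::read.csv("results/profiles.csv", stringsAsFactors = FALSE)
names(profiles) <- sub("\\.(deg|pd)$", "", names(profiles))

sex_tab <- sex_comparison_table(profiles)
utils::write.csv(sex_tab, "results/sex_comparison.csv", row.names = FALSE)
cat("largest sex effects (|d|):\n")
print(utils::head(sex_tab[order(-abs(sex_tab$d)), c("parameter", "mean_men", "mean_women", "p_value", "stars", "d")], 6),
      row.names = FALSE, digits = 3)

corr <- height_correlations(profiles)
utils::write.csv(corr, "results/height_correlations.csv", row.names = FALSE)
cat("\nheight correlations flagged relevant (p < 0.05, r > 0.45):\n")
print(corr[corr$relevant, c("parameter", "pearson_r", "p_value")],
      row.names = FALSE, digits = 3)

rel <- reliability_table(profiles)
utils::write.csv(rel, "results/reliability.csv", row.names = FALSE)
cat(sprintf(
  "\nreliability over %d retest subjects: ICC(3,k) range %.2f-%.2f\n",
  rel$n[1], min(rel$icc_3k), max(rel$icc_3k)
))
print(rel[order(rel$icc_3k), ][1:3, ], row.names = FALSE, digits = 3)
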