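#!/usr/bin/env Rscript
# Stage 3 -- group comparison of the biomarkers.
#
# Wilcoxon rank-sum tests compare stroke vs healthy for the per-pair
# MCCC and delay summaries; each 11-comparison family is corrected
# with the Benjamini-Hochberg adjustment (reproduction dialect:
# p * m / rank without the step-up pass, the form the published
# comparison table uses). Stars: * < 0.05, ** < 0.01, *** < 0.001 on
# the adjusted values.
#
# Reads results/analysis/features.csv; writes
# results/analysis/comparisons.csv (already produced by stage 2; this
# stage re-derives it from the feature table and prints it).

library(slfomark)

feat <- read.csv("results/analysis/features.csv", check.names = FALSE)
pairs <- paste(default_pairs()$a, default_pairs()$b, sep = "-")

cm <- compare_groups(feat, feat$group, columns = paste0("mccc_", pairs))
cd <- compare_groups(feat, feat$group, columns = paste0("delay_", pairs))
tab <- data.frame(pair = pairs,
                  mccc_p = signif(cm$p_value, 3),
                  mccc_adj = signif(cm$adjusted_p, 3),
                  mccc = cm$tier,
                  delay_p = signif(cd$p_value, 3),
                  delay_adj = signif(cd$adjusted_p, 3),
                  delay = cd$tier)
print(tab, row.names = FALSE)
write.csv(tab, "results/analysis/comparison_table.csv", row.names = FALSE)
cat(sprintf("\n%d/%d MCCC and %d/%d delay comparisons significant after adjustment\n",
            sum(cm$adjusted_p < 0.05), length(pairs),
            sum(cd$adjusted_p < 0.05), length(pairs)))
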