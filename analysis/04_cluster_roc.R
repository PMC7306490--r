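#!/usr/bin/env Rscript
# Stage 4 -- unsupervised discrimination by fuzzy c-means.
#
# Two feature sets are clustered with k = 2, b = 2 (the convention),
# epsilon = 1e-5: (i) the LE-RE MCCC summary, and (ii) the four
# finger-toe delay summaries. Cluster-to-class assignment uses only
# the center geometry (lower MCCC center / larger delay center =
# stroke-like), keeping the clustering unsupervised; each subject's
# membership in the stroke-like cluster is then scored against the
# true labels with an ROC curve.
#
# Reads results/analysis/features.csv; writes ROC tables under
# results/analysis/.

library(slfomark)

config <- pipeline_config(seed = 20260101L)
feat <- read.csv("results/analysis/features.csv", check.names = FALSE)

cl_mccc <- fcm_classify(feat["mccc_LE-RE"], labels = feat$group,
                        stroke_like = "low", config = config)
delay_cols <- paste0("delay_", c("LF-LT", "RF-LT", "LF-RT", "RF-RT"))
cl_delay <- fcm_classify(feat[delay_cols], labels = feat$group,
                         stroke_like = "high", config = config)

cat(sprintf("LE-RE MCCC clustering:  AUC = %.2f (%d subjects)\n",
            cl_mccc$roc$auc, length(cl_mccc$kept)))
cat(sprintf("F-T delay clustering:   AUC = %.2f (%d subjects, %d dropped for missing delays)\n",
            cl_delay$roc$auc, length(cl_delay$kept),
            nrow(feat) - length(cl_delay$kept)))

write.csv(cl_mccc$roc$curve, "results/analysis/roc_mccc_le_re.csv",
          row.names = FALSE)
write.csv(cl_delay$roc$curve, "results/analysis/roc_delay_ft.csv",
          row.names = FALSE)

# three-cluster variant on the same features (exploratory)
cl3 <- fcm_classify(feat[delay_cols], config = config, k = 3)
cat(sprintf("k = 3 delay clustering: sizes %s\n",
            paste(table(fcm_predict(cl3$model,
                                    as.matrix(feat[delay_cols])[cl3$kept, ])$labels),
                  collapse = "/")))
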