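#!/usr/bin/env Rscript
# Build the deterministic calibrated fixture cohort and classify every
# participant's exposure interval at the 2 calls/week threshold.
# Writes: results/classification.csv, results/exposure_group_summary.csv

suppressPackageStartupMessages(library(exposim))
dir.create("results", showWarnings = FALSE)

fx <- build_table1_fixture()
cls_tab <- classification_table(fx, threshold = 2)
write.csv(cls_tab, "results/classification.csv", row.names = FALSE)

mid <- (cls_tab$lower + cls_tab$upper) / 2
summ <- do.call(rbind, lapply(split(mid, cls_tab$class), function(m) {
  data.frame(n = length(m), q25 = quantile(m, 0.25), median = median(m),
             q75 = quantile(m, 0.75), mean = mean(m), row.names = NULL)
}))
summ <- cbind(group = levels(cls_tab$class), summ)
write.csv(summ, "results/exposure_group_summary.csv", row.names = FALSE)

cat("Exposure-group structure of the calibrated fixture cohort:\n\n")
print(summ, row.names = FALSE, digits = 4)
cat(sprintf("\nExposed-group (n = %d) mean interval midpoint: %.3f calls/week\n",
            sum(cls_tab$class != "none"), mean(mid[cls_tab$class != "none"])))
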