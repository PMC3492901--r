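#!/usr/bin/env Rscript
# Step 4: outlier proportions, candidate vs control.
#
# Under neutrality the proportion of DHEW outliers should not differ
# between candidate and control genes; an excess among candidates would
# point at selection on the candidate set. With the simulated study the
# truth table says which genes actually carry the sweep scenario, so the
# scan's hits can be checked against it.

library(dhewscan)

outliers <- read.delim("results/run/outliers.tsv")
truth <- read.delim("results/study/truth.tsv")

prop <- summarize_outliers(outliers)
cat("outlier percentage per species x category:\n")
print(prop, row.names = FALSE)
write.table(prop, "results/outlier_proportions.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

called <- outliers$gene_id[!is.na(outliers$outlier) & outliers$outlier]
swept <- truth$gene_id[truth$scenario == "star_sweep"]
cat(sprintf("\n%d genes called, %d sweep genes simulated, %d recovered\n",
            length(called), length(swept), length(intersect(called, swept))))
if (length(setdiff(called, swept)) > 0) {
  cat("false positives:", paste(setdiff(called, swept), collapse = ", "), "\n")
}
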