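#!/usr/bin/env Rscript
# Step 1: generate the synthetic resequencing study.
#
# Four species, two gene categories (candidate / control), per-gene
# parameters drawn from study-shaped ranges: 3-12 haploid sequences,
# 380-401 bp amplicons, per-site theta 0.001-0.01, outgroup divergence
# 0.01-0.09, 60% coding, low rates of injected missing/indel/triallelic
# defect columns. A small fraction of candidate genes carries the sweep
# caricature so the outlier machinery has something to find.

library(dhewscan)

out <- "results/study"
manifest <- generate_study(list(
  species = c("Aalba", "Ldecidua", "Pcembra", "Pmugo"),
  genes_per_category = c(candidate = 8L, control = 5L),
  sweep_fraction = 0.15,
  seed = 20260928L
), out)

cat(sprintf("wrote %d genes under %s\n", nrow(manifest), out))
print(table(manifest$species, manifest$category))
truth <- read.delim(file.path(out, "truth.tsv"))
cat(sprintf("scenarios: %s\n",
            paste(names(table(truth$scenario)), table(truth$scenario),
                  collapse = ", ", sep = "=")))
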