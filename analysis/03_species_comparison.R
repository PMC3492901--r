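#!/usr/bin/env Rscript
# Step 3: across-locus bootstrap comparison of species means.
#
# Rebuilds the per-species bootstrap summaries of theta_pi and divergence
# from the per-gene table and calls every species pair significant or not
# by 95% CI overlap, the same decision rule the per-run summary table is
# built from.

library(dhewscan)

div <- read.delim("results/run/diversity.tsv")
species <- sort(unique(div$species))

compare_table <- function(stat) {
  sums <- lapply(species, function(sp) {
    bootstrap_mean_ci(div[[stat]][div$species == sp & div$category == "candidate"],
                      reps = 10000, seed = derive_seed(20260928L, paste(sp, stat)),
                      statistic_name = stat, species = sp)
  })
  names(sums) <- species
  out <- data.frame()
  for (i in seq_along(species)) {
    for (j in seq_along(species)) {
      if (i < j) {
        out <- rbind(out, data.frame(
          a = species[i], b = species[j], statistic = stat,
          verdict = compare_species(sums[[i]], sums[[j]])))
      }
    }
  }
  list(summaries = sums, pairs = out)
}

dir.create("results", showWarnings = FALSE)
for (stat in c("theta_pi", "dxy")) {
  res <- compare_table(stat)
  cat("\n== ", stat, " (candidate genes) ==\n")
  for (s in res$summaries) print(s)
  print(res$pairs, row.names = FALSE)
  write.table(res$pairs, sprintf("results/species_pairs_%s.tsv", stat),
              sep = "\t", quote = FALSE, row.names = FALSE)
}
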