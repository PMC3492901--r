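test_that("worked matrix reproduces the enumerated diversity values", {
  f <- worked_filtered()
  expect_equal(segregating_sites(f), 2L)
  expect_equal(theta_pi(f), 7 / 60, tolerance = 1e-12)
  expect_equal(theta_pi(f, per_site = FALSE), 7 / 6, tolerance = 1e-12)
  expect_equal(theta_w(f), 2 / ((11 / 6) * 10), tolerance = 1e-12)
  expect_equal(dxy(f, outgroup_consensus(f)), 5 / 40, tolerance = 1e-12)
})

test_that("degenerate inputs give the documented values", {
  mono <- aln_from_strings(c("ACGT", "ACGT", "ACGT"))
  fm <- filter_sites(mono)
  expect_equal(segregating_sites(fm), 0L)
  expect_equal(theta_pi(fm), 0)
  expect_equal(theta_w(fm), 0)
  # two sequences differing at 1 of 100 sites
  s <- paste(rep("A", 100), collapse = "")
  s2 <- paste0(substr(s, 1, 99), "T")
  f2 <- filter_sites(aln_from_strings(c(s, s2)))
  expect_equal(theta_pi(f2), 0.01)
  expect_equal(theta_w(f2), 0.01)  # n = 2: a1 = 1, pi and thetaw coincide
})

test_that("theta_pi equals theta_w exactly for n = 2 and is row-order invariant", {
  set.seed(11)
  for (i in 1:20) {
    g <- generate_gene(synthetic_gene_spec(n = 2, L = 150, theta_site = 0.01,
                                           seed = 100 + i))
    f <- filter_sites(g$aln)
    expect_equal(theta_pi(f), theta_w(f), tolerance = 1e-12)
  }
  g <- generate_gene(synthetic_gene_spec(n = 8, L = 200, theta_site = 0.01,
                                         seed = 5))
  f <- filter_sites(g$aln)
  perm <- f
  perm$matrix <- f$matrix[sample(nrow(f$matrix)), ]
  expect_equal(theta_pi(perm), theta_pi(f), tolerance = 1e-12)
})

test_that("dxy renormalizes over consensus-resolved sites", {
  f <- worked_filtered()
  cons <- rep("N", 10)
  cons[1] <- "A"   # single usable, matching column
  expect_equal(dxy(f, cons), 0)
  expect_true(is.na(dxy(f, rep("N", 10))))
  expect_equal(dxy(f, strsplit("AAAAAAAAAA", "")[[1]]), 0.125)
})

test_that("category diversity recombines to total diversity by site counts", {
  g <- generate_gene(synthetic_gene_spec(n = 8, L = 300, theta_site = 0.01,
                                         coding_fraction = 0.5, seed = 23))
  aln <- g$aln
  f <- filter_sites(aln)
  ann <- classify_sites(f, g$coding, aln = aln)
  cd <- category_diversity(f, ann)
  # weighted recombination over noncoding + coding categories must equal
  # pi restricted to non-excluded sites
  keep <- ann$site_category != "mixed_excluded"
  weights <- c(noncoding = ann$noncoding_sites,
               synonymous = ann$syn_sites,
               nonsynonymous = ann$nonsyn_sites)
  pis <- cd$pi_by_category[names(weights)]
  pis[is.na(pis)] <- 0
  total <- sum(pis * weights) / sum(weights)
  direct <- dhewscan:::pairwise_diff_total(f$matrix, which(keep)) / sum(weights)
  expect_equal(total, direct, tolerance = 1e-9)
})

test_that("genes with purely noncoding variation have zero coding diversity", {
  # coding interval covers a monomorphic middle; variation in the flanks
  seqs <- c("TTTATGCCCAAA", "TTAATGCCCAAA", "TTAATGCCCAAC", "TTAATGCCCAAC")
  aln <- aln_from_strings(seqs, outgroup = "TTTATGCCCAAA")
  f <- filter_sites(aln)
  ann <- classify_sites(f, data.frame(start = 3, end = 9, frame = 0),
                        aln = aln)
  cd <- category_diversity(f, ann)
  expect_equal(unname(cd$pi_by_category["synonymous"]), 0)
  expect_equal(unname(cd$pi_by_category["nonsynonymous"]), 0)
  expect_gt(cd$pi_by_category["noncoding"], 0)
})

test_that("Ka/Ks counts fixed coding differences against fractional sites", {
  # ingroup fixed GGA, outgroup GGG: one synonymous difference
  aln <- aln_from_strings(rep(c("ATGGGA"), 4), outgroup = "ATGGGG")
  f <- filter_sites(aln)
  ann <- classify_sites(f, data.frame(start = 0, end = 6, frame = 0),
                        aln = aln)
  kk <- ka_ks(f, ann, outgroup_consensus(f), aln = aln)
  expect_equal(kk$syn_diffs, 1)
  expect_equal(kk$nonsyn_diffs, 0)
  expect_equal(kk$Ks, 1 / ann$syn_sites)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$ratio, 0)  # Ka = 0 over Ks > 0
})

test_that("identical ingroup and outgroup give zero divergence and NA ratio", {
  aln <- aln_from_strings(rep("ATGGGACCC", 4), outgroup = "ATGGGACCC")
  f <- filter_sites(aln)
  ann <- classify_sites(f, data.frame(start = 0, end = 9, frame = 0),
                        aln = aln)
  kk <- ka_ks(f, ann, outgroup_consensus(f), aln = aln)
  expect_equal(kk$Ka, 0)
  expect_equal(kk$Ks, 0)
  expect_true(is.na(kk$ratio))
})
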