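test_that("defect-free genes pass the site filter untouched", {
  g <- generate_gene(synthetic_gene_spec(n = 6, L = 300, theta_site = 0.008,
                                         seed = 12))
  f <- filter_sites(g$aln)
  expect_equal(f$L, 300L)
  expect_equal(nrow(f$removal_log), 0L)
  expect_equal(segregating_sites(f), g$truth$S_true)
})

test_that("pre-defect variable columns are exactly biallelic", {
  for (seed in 1:10) {
    g <- generate_gene(synthetic_gene_spec(n = 10, L = 300,
                                           theta_site = 0.01, seed = seed))
    nall <- apply(g$aln$ingroup, 2, function(cc) length(unique(cc)))
    expect_true(all(nall <= 2))
    expect_equal(sort(which(nall == 2) - 1L),
                 sort(as.integer(g$truth$variant_columns)))
  }
})

test_that("the removal log recovers the injected defect columns exactly", {
  g <- generate_gene(synthetic_gene_spec(
    n = 8, L = 400, theta_site = 0.005,
    defect_rates = c(missing_col = 0.03, indel_col = 0.02,
                     triallelic_col = 0.02), seed = 99))
  rl <- filter_sites(g$aln)$removal_log
  expect_equal(sort(rl$column[rl$reason == "missing"]),
               sort(as.integer(g$truth$missing_cols)))
  expect_equal(sort(rl$column[rl$reason == "indel"]),
               sort(as.integer(g$truth$indel_cols)))
  expect_equal(sort(rl$column[rl$reason == "infinite_sites_violation"]),
               sort(as.integer(g$truth$triallelic_cols)))
})

test_that("polarization recovers the simulator's derived states", {
  # an outgroup substitution that hits a polymorphic column misdirects or
  # blocks polarization there by design; the expected misdirection rate is
  # about divergence/3, so a low-divergence outgroup isolates the
  # polarization logic itself
  total <- 0L; correct <- 0L
  for (seed in 1:20) {
    g <- generate_gene(synthetic_gene_spec(n = 8, L = 400,
                                           theta_site = 0.008,
                                           outgroup_divergence = 0.02,
                                           seed = 200 + seed))
    f <- filter_sites(g$aln)
    pol <- polarize(f, outgroup_consensus(f))
    truth <- setNames(g$truth$derived_count, g$truth$variant_columns)
    total <- total + length(pol$counts)
    correct <- correct + sum(pol$counts ==
                               truth[as.character(pol$sites)])
  }
  expect_gte(correct / total, 0.99)
})

test_that("Dxy across many genes recovers the configured divergence", {
  dx <- numeric(400)
  for (i in seq_along(dx)) {
    g <- generate_gene(synthetic_gene_spec(n = 6, L = 300,
                                           theta_site = 0.003,
                                           outgroup_divergence = 0.06,
                                           seed = 3000 + i))
    f <- filter_sites(g$aln)
    dx[i] <- dxy(f, outgroup_consensus(f))
  }
  expect_equal(mean(dx), 0.06, tolerance = 0.10)
})

test_that("the sweep caricature produces the joint sweep signature", {
  set.seed(55)
  stats <- t(replicate(100, replicate_stats(
    dhewscan:::star_sweep_replicate(12, 5))))
  expect_lt(mean(stats[, "D"], na.rm = TRUE), -1)
  expect_lt(mean(stats[, "H"], na.rm = TRUE), -1)
  expect_gt(mean(stats[, "F"], na.rm = TRUE), 0.5)
})

test_that("generate_study writes a complete, seed-stable directory tree", {
  cfg <- list(species = c("A", "B"), genes_per_category = c(candidate = 3L,
                                                            control = 2L),
              seed = 8)
  d1 <- file.path(tempfile("s1"))
  d2 <- file.path(tempfile("s2"))
  m1 <- generate_study(cfg, d1)
  m2 <- generate_study(cfg, d2)
  expect_equal(nrow(m1), 10L)
  expect_true(all(file.exists(file.path(d1, m1$file))))
  expect_true(file.exists(file.path(d1, "annotations.tsv")))
  expect_true(file.exists(file.path(d1, "truth.tsv")))
  # byte-identical regeneration from the same master seed
  for (f in file.path("fasta", paste0(m1$gene_id, ".fa"))) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_identical(readLines(file.path(d1, "manifest.tsv")),
                   readLines(file.path(d2, "manifest.tsv")))
})
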