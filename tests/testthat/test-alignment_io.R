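test_that("FASTA reading partitions ingroup and outgroup by header tag", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">sp|g|h1", "ACGTACGT", ">sp|g|h2", "ACGTACGA",
               ">sp|g|h3", "ACGTACGA", ">sp|g|h4", "ACTTACGA",
               ">Ptaeda|g", "ACGTACGA"), path)
  aln <- read_gene_fasta(path, outgroup_tag = "Ptaeda")
  expect_equal(aln$n, 4L)
  expect_equal(nrow(aln$outgroup), 1L)
  expect_equal(ncol(aln$ingroup), 8L)
})

test_that("ragged alignments and missing outgroups are flagged", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACG", ">Ptaeda", "ACGT"), path)
  expect_error(read_gene_fasta(path, "Ptaeda"), "unequal lengths")

  path2 <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">b", "ACGA"), path2)
  expect_warning(aln <- read_gene_fasta(path2, "Ptaeda"), "outgroup tag")
  expect_equal(nrow(aln$outgroup), 0L)
  expect_equal(aln$n, 2L)
})

test_that("synthetic genes round-trip through write and read identically", {
  g <- generate_gene(synthetic_gene_spec(
    n = 6, L = 120, theta_site = 0.01,
    defect_rates = c(missing_col = 0.05, indel_col = 0.03,
                     triallelic_col = 0.03), seed = 17))
  path <- tempfile(fileext = ".fa")
  write_gene_fasta(g$aln, path)
  back <- read_gene_fasta(path, "Ptaeda", gene_id = g$aln$gene_id,
                          species = g$aln$species)
  expect_identical(back$ingroup, g$aln$ingroup)
  expect_identical(back$outgroup, g$aln$outgroup)
})

test_that("primer masking Ns out the flanks and leaves the interior", {
  mat <- matrix("A", nrow = 3, ncol = 100,
                dimnames = list(paste0("s", 1:3), NULL))
  mat[1, 50] <- "C"
  aln <- gene_alignment(mat, gene_id = "g",
                        primer_intervals = list(fwd = c(0, 20),
                                                rev = c(80, 100)))
  m <- mask_primers(aln)
  expect_true(all(m$ingroup[, c(1:20, 81:100)] == "N"))
  expect_identical(m$ingroup[, 21:80], aln$ingroup[, 21:80])
  expect_equal(m$masked_columns, c(0:19, 80:99))

  # no intervals -> identity; bad intervals -> config error
  expect_identical(mask_primers(gene_alignment(mat))$ingroup, mat)
  aln$primer_intervals <- list(fwd = c(0, 60), rev = c(40, 100))
  expect_error(mask_primers(aln), "overlapping")
})

test_that("masked columns are removed downstream as primer_masked", {
  mat <- matrix("A", nrow = 3, ncol = 30,
                dimnames = list(paste0("s", 1:3), NULL))
  aln <- gene_alignment(mat, primer_intervals = list(fwd = c(0, 5),
                                                     rev = c(25, 30)))
  f <- filter_sites(mask_primers(aln))
  expect_equal(f$L, 20L)
  expect_setequal(f$removal_log$reason, "primer_masked")
  expect_equal(sort(f$removal_log$column), c(0:4, 25:29))
})

test_that("site filtering drops missing, indel and triallelic columns only", {
  aln <- aln_from_strings(c("AATAAAGAAA",
                            "AATAACGAAA",
                            "ANTA-CTAAA",
                            "AATAACTAAA"))
  # col 2 has N (missing), col 5 has gap (indel), col 7 has {G,G,T,T}? ->
  # col 7 is biallelic; col 6 {A,C,C,C} biallelic; build a true triallelic:
  aln$ingroup[1, 10] <- "G"; aln$ingroup[2, 10] <- "C"
  f <- filter_sites(aln)
  log <- f$removal_log
  expect_equal(log$reason[log$column == 1], "missing")
  expect_equal(log$reason[log$column == 4], "indel")
  expect_equal(log$reason[log$column == 9], "infinite_sites_violation")
  expect_equal(f$L, 10L - nrow(log))
  # every original column appears exactly once across retained + removed
  expect_setequal(c(f$retained_columns, log$column), 0:9)
  # retained columns are complete and at most biallelic
  expect_true(all(apply(f$matrix, 2, function(cc)
    length(unique(cc)) <= 2 && all(cc %in% c("A", "C", "G", "T")))))
})

test_that("filtering is idempotent", {
  g <- generate_gene(synthetic_gene_spec(
    n = 6, L = 200, theta_site = 0.01,
    defect_rates = c(missing_col = 0.05, indel_col = 0.05,
                     triallelic_col = 0.05), seed = 3))
  f1 <- filter_sites(g$aln)
  again <- gene_alignment(f1$matrix, f1$outgroup, gene_id = "again")
  f2 <- filter_sites(again)
  expect_identical(f2$matrix, f1$matrix)
  expect_equal(nrow(f2$removal_log), 0L)
})

test_that("outgroup consensus takes strict majorities and Ns ties", {
  aln <- aln_from_strings(c("AAAA", "AAAA"),
                          outgroup = c("AAAG", "AATG", "GCTA"))
  cons <- outgroup_consensus(aln)
  expect_equal(cons[1], "A")        # A,A,G -> A
  expect_equal(cons[3], "T")        # A,T,T -> T
  expect_equal(cons[4], "G")        # G,G,A -> G
  # a clean tie and an all-missing column
  aln2 <- aln_from_strings(c("AA", "AA"), outgroup = c("AG", "GN"))
  expect_equal(outgroup_consensus(aln2), c("N", "G"))
  aln3 <- aln_from_strings(c("AA", "AA"), outgroup = c("CN", "-N"))
  expect_equal(outgroup_consensus(aln3), c("C", "N"))
  # single outgroup row is its own consensus
  aln4 <- aln_from_strings(c("AA", "AA"), outgroup = c("CT"))
  expect_equal(outgroup_consensus(aln4), c("C", "T"))
})
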