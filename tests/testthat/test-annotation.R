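# a fully coding alignment from codon strings, with an optional variant
coding_aln <- function(consensus_codons, variant_row = NULL) {
  seqs <- rep(paste(consensus_codons, collapse = ""), 4)
  if (!is.null(variant_row)) seqs[4] <- variant_row
  aln_from_strings(seqs, outgroup = paste(consensus_codons, collapse = ""))
}

test_that("polymorphic codon positions classify by amino-acid change", {
  # GGA -> GGG at 3rd position: Gly/Gly, synonymous
  aln <- coding_aln(c("ATG", "GGA"), "ATGGGG")
  f <- filter_sites(aln)
  ann <- classify_sites(f, data.frame(start = 0, end = 6, frame = 0),
                        aln = aln)
  expect_equal(ann$site_category[6], "synonymous")

  # AAA -> GAA at 1st position: Lys -> Glu, nonsynonymous
  aln2 <- coding_aln(c("ATG", "AAA"), "ATGGAA")
  f2 <- filter_sites(aln2)
  ann2 <- classify_sites(f2, data.frame(start = 0, end = 6, frame = 0),
                         aln = aln2)
  expect_equal(ann2$site_category[4], "nonsynonymous")
})

test_that("sites outside coding intervals are noncoding and counted once", {
  aln <- coding_aln(c("ATG", "CCC", "TTT"))
  f <- filter_sites(aln)
  ann <- classify_sites(f, data.frame(start = 3, end = 9, frame = 0),
                        aln = aln)
  expect_equal(sum(ann$site_category == "noncoding"), 3L)
  expect_equal(ann$noncoding_sites, 3)
  expect_equal(ann$silent_sites, ann$noncoding_sites + ann$syn_sites)
})

test_that("fractional site counting follows the Nei-Gojobori rule", {
  # CCC (Pro, 4-fold): 3rd position contributes 1.0 synonymous site,
  # 1st and 2nd positions 0 (all changes nonsynonymous)
  aln <- coding_aln(c("CCC"))
  f <- filter_sites(aln)
  ann <- classify_sites(f, data.frame(start = 0, end = 3, frame = 0),
                        aln = aln)
  expect_equal(ann$f_syn, c(0, 0, 1))
  # no second-position change of any sense codon is synonymous
  for (codon in c("ATG", "GGA", "TTA", "AAA")) {
    a <- coding_aln(c(codon))
    an <- classify_sites(filter_sites(a),
                         data.frame(start = 0, end = 3, frame = 0), aln = a)
    expect_equal(an$f_syn[2], 0)
  }
})

test_that("category totals match a brute-force per-codon enumeration", {
  set.seed(41)
  gc_table <- Biostrings::GENETIC_CODE
  sense <- names(gc_table)[gc_table != "*"]
  codons <- sample(sense, 30, replace = TRUE)
  aln <- coding_aln(codons)
  f <- filter_sites(aln)
  ann <- classify_sites(f, data.frame(start = 0, end = 90, frame = 0),
                        aln = aln)
  # independent oracle: per codon position, count synonymous single-base
  # changes directly against the code table (stops nonsynonymous)
  oracle_syn <- 0
  for (cd in codons) {
    b <- strsplit(cd, "")[[1]]
    for (k in 1:3) {
      for (alt in setdiff(c("A", "C", "G", "T"), b[k])) {
        mut <- b; mut[k] <- alt
        mcd <- paste(mut, collapse = "")
        if (gc_table[mcd] != "*" && gc_table[mcd] == gc_table[cd]) {
          oracle_syn <- oracle_syn + 1 / 3
        }
      }
    }
  }
  expect_equal(ann$syn_sites, oracle_syn, tolerance = 1e-12)
  expect_equal(ann$syn_sites + ann$nonsyn_sites, 90 - ann$mixed_excluded,
               tolerance = 1e-9)
})

test_that("uniform codon usage gives a synonymous fraction near one quarter", {
  set.seed(7)
  gc_table <- Biostrings::GENETIC_CODE
  sense <- names(gc_table)[gc_table != "*"]
  codons <- sample(sense, 100, replace = TRUE)
  aln <- coding_aln(codons)
  ann <- classify_sites(filter_sites(aln),
                        data.frame(start = 0, end = 300, frame = 0),
                        aln = aln)
  frac <- ann$syn_sites / (ann$syn_sites + ann$nonsyn_sites)
  expect_gt(frac, 0.20)
  expect_lt(frac, 0.30)
})

test_that("codons with unresolvable context are excluded from totals", {
  # internal stop in the consensus context
  aln <- coding_aln(c("ATG", "TAA", "CCC"), "ATGTAACCG")
  f <- filter_sites(aln)
  ann <- classify_sites(f, data.frame(start = 0, end = 9, frame = 0),
                        aln = aln)
  expect_true(all(ann$site_category[4:6] == "mixed_excluded"))
  # partial codon at the interval edge
  ann2 <- classify_sites(f, data.frame(start = 0, end = 8, frame = 0),
                         aln = aln)
  expect_true(all(ann2$site_category[7:8] == "mixed_excluded"))
  # categories always partition the retained sites
  tot <- sum(ann$site_category == "noncoding") +
    sum(ann$site_category %in% c("synonymous", "nonsynonymous")) +
    ann$mixed_excluded
  expect_equal(tot, f$L)
})

test_that("percentages use half-up rounding and NA on empty denominators", {
  expect_equal(percent(4362, 23299, 2), 18.72)
  expect_equal(percent(83, 146, 0), 57)
  expect_equal(percent(0, 100, 2), 0)
  expect_equal(percent(1, 8, 1), 12.5)
  expect_equal(percent(1, 16, 1), 6.3)   # 6.25 rounds half-up
  expect_true(is.na(percent(5, 0, 2)))
})
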