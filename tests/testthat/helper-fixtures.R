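# Worked 4 x 10 example: three haplotypes, two segregating sites (columns
# 9 and 10, 1-based), all-ancestral outgroup. Known by enumeration:
#   S = 2, theta_pi = 7/6 per locus, haplotype counts 1,1,2,
#   derived counts 2 (col 9) and 3 (col 10), r^2 between the sites 1/3.
worked_alignment <- function(outgroup_seq = "AAAAAAAAAA") {
  rows <- c("AAAAAAAAAA", "AAAAAAAAAT", "AAAAAAAATT", "AAAAAAAATT")
  mat <- do.call(rbind, strsplit(rows, ""))
  rownames(mat) <- paste0("sp|gene1|h", 1:4)
  out <- matrix(strsplit(outgroup_seq, "")[[1]], nrow = 1,
                dimnames = list("Ptaeda|gene1", NULL))
  gene_alignment(mat, out, gene_id = "gene1", species = "sp")
}

worked_filtered <- function(...) filter_sites(worked_alignment(...))

# build a gene_alignment from character strings
aln_from_strings <- function(ingroup, outgroup = NULL, ...) {
  mat <- do.call(rbind, strsplit(ingroup, ""))
  rownames(mat) <- names(ingroup) %||% paste0("s", seq_along(ingroup))
  out <- if (!is.null(outgroup)) {
    m <- do.call(rbind, strsplit(outgroup, ""))
    rownames(m) <- names(outgroup) %||% paste0("Ptaeda", seq_along(outgroup))
    m
  }
  gene_alignment(mat, out, ...)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force estimators used as oracles (straight loops,
# sharing no code with the package internals).
brute_pi_locus <- function(mat) {
  n <- nrow(mat)
  tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + sum(mat[i, ] != mat[j, ])
  }
  tot / (n * (n - 1) / 2)
}

brute_tajima_d <- function(mat) {
  n <- nrow(mat)
  S <- sum(apply(mat, 2, function(cc) length(unique(cc)) > 1))
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  (brute_pi_locus(mat) - S / a1) /
    sqrt(c1 / a1 * S + c2 / (a1^2 + a2) * S * (S - 1))
}

brute_normalized_h <- function(mat, ancestral) {
  n <- nrow(mat)
  counts <- c()
  for (j in seq_len(ncol(mat))) {
    der <- sum(mat[, j] != ancestral[j])
    if (der > 0 && der < n) counts <- c(counts, der)
  }
  S <- length(counts)
  pi_l <- brute_pi_locus(mat)
  theta_l <- sum(counts) / (n - 1)
  a1 <- sum(1 / (1:(n - 1))); a2 <- sum(1 / (1:(n - 1))^2)
  tw <- S / a1
  tsq <- S * (S - 1) / (a1^2 + a2)
  bn1 <- sum(1 / (1:n)^2)
  v <- tw * (n - 2) / (6 * (n - 1)) +
    tsq * (18 * n^2 * (3 * n + 2) * bn1 -
             (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  (pi_l - theta_l) / sqrt(v)
}
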