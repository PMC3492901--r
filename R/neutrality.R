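#' Tajima's D
#'
#' Normalized difference between the pairwise diversity estimator and the
#' Watterson estimator at the locus scale, with the 1989 variance
#' constants: a1, a2 the (squared-)harmonic numbers, b1 = (n+1)/(3(n-1)),
#' b2 = 2(n^2+n+3)/(9n(n-1)), c1 = b1 - 1/a1,
#' c2 = b2 - (n+2)/(a1 n) + a2/a1^2, e1 = c1/a1, e2 = c2/(a1^2 + a2), and
#' D = (pi_locus - S/a1) / sqrt(e1 S + e2 S (S-1)).
#'
#' @param S number of segregating sites (D is NA when `S == 0`)
#' @param theta_pi_locus mean pairwise difference per locus (not per site)
#' @param n sample size (>= 2; >= 4 recommended for a meaningful variance)
#' @return Tajima's D, or NA when undefined
#' @export
tajima_d <- function(S, theta_pi_locus, n) {
  stopifnot(n >= 2)
  if (is.na(S) || S == 0) return(NA_real_)
  a1 <- a1_n(n); a2 <- a2_n(n)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  denom <- sqrt(e1 * S + e2 * S * (S - 1))
  if (denom == 0) return(NA_real_)
  (theta_pi_locus - S / a1) / denom
}

# Fay & Wu's normalized H from unfolded derived-allele counts (Zeng et al.
# 2006 normalization). counts: derived count per polarizable segregating
# site, each in [1, n-1].
fw_h_from_counts <- function(counts, n) {
  S <- length(counts)
  if (S == 0L) return(NA_real_)
  npairs <- n * (n - 1) / 2
  pi_locus <- sum(counts * (n - counts)) / npairs
  theta_l <- sum(counts) / (n - 1)
  a1 <- a1_n(n); a2 <- a2_n(n)
  theta_w <- S / a1
  theta_sq <- S * (S - 1) / (a1^2 + a2)
  bn1 <- a2 + 1 / n^2  # sum_{i=1}^{n} 1/i^2
  var_hl <- theta_w * (n - 2) / (6 * (n - 1)) +
    theta_sq * (18 * n^2 * (3 * n + 2) * bn1 -
                  (88 * n^3 + 9 * n^2 - 13 * n + 6)) / (9 * n * (n - 1)^2)
  if (var_hl <= 0) return(NA_real_)
  (pi_locus - theta_l) / sqrt(var_hl)
}

#' Polarize segregating sites against the outgroup consensus
#'
#' At each segregating column of the filtered matrix, if the outgroup
#' consensus character equals one of the two ingroup alleles the other
#' allele is called derived; columns where the consensus is N or carries a
#' third allele are counted as unpolarized and excluded from the unfolded
#' spectrum.
#'
#' @param f a `filtered_alignment`
#' @param consensus outgroup consensus over the retained columns (character
#'   vector of length `f$L`, or a single string)
#' @return object of class `polarized_spectrum`: list with `n`, `counts`
#'   (derived-allele count per polarizable site), `sites` (0-based retained
#'   column positions of those sites) and `unpolarized`
#' @export
polarize <- function(f, consensus) {
  consensus <- as_char_vector(consensus, f$L)
  mat <- f$matrix
  n <- nrow(mat)
  seg <- which(apply(mat, 2L, function(col) length(unique(col)) == 2L))
  counts <- integer(0)
  sites <- integer(0)
  unpolarized <- 0L
  for (j in seg) {
    alleles <- unique(mat[, j])
    anc <- consensus[j]
    if (is.na(anc) || !(anc %in% alleles)) {
      unpolarized <- unpolarized + 1L
    } else {
      derived <- setdiff(alleles, anc)
      counts <- c(counts, sum(mat[, j] == derived))
      sites <- c(sites, f$retained_columns[j])
    }
  }
  structure(list(n = n, counts = counts, sites = sites,
                 unpolarized = unpolarized),
            class = "polarized_spectrum")
}

#' Fay & Wu's normalized H
#'
#' Contrast of pairwise diversity against the high-frequency-weighted
#' estimator theta_L = sum(i * S_i) / (n - 1), computed on the polarizable
#' sites of the unfolded spectrum and normalized by the variance of
#' Zeng et al. (2006), with theta estimated by S/a1 and theta^2 by
#' S(S-1)/(a1^2 + a2) (S restricted to polarizable sites). Strongly
#' negative values indicate an excess of high-frequency derived alleles,
#' the hitchhiking signature.
#'
#' @param spectrum a `polarized_spectrum` from [polarize()]
#' @param normalized if `FALSE`, return the raw numerator
#'   theta_pi - theta_L instead (exposed for debugging)
#' @return the statistic, or NA when no site is polarizable
#' @export
fay_wu_h <- function(spectrum, normalized = TRUE) {
  counts <- spectrum$counts
  n <- spectrum$n
  if (length(counts) == 0L) return(NA_real_)
  if (!normalized) {
    npairs <- n * (n - 1) / 2
    return(sum(counts * (n - counts)) / npairs - sum(counts) / (n - 1))
  }
  fw_h_from_counts(counts, n)
}

#' Ewens-Watterson haplotype homozygosity F
#'
#' Haplotypes are the distinct full rows of the filtered (complete-data)
#' matrix; F = sum of squared haplotype relative frequencies. F lies in
#' \[1/n, 1\] and rises after selective sweeps.
#'
#' @param f a `filtered_alignment`
#' @return F
#' @export
ewens_watterson_f <- function(f) {
  mat <- f$matrix
  n <- nrow(mat)
  key <- if (ncol(mat) == 0L) rep("", n) else
    apply(mat, 1L, paste, collapse = "")
  sum((table(key) / n)^2)
}

#' Kelly's ZnS
#'
#' Mean of the squared correlation r^2 = D^2 / (p(1-p)q(1-q)) over all
#' S(S-1)/2 pairs of segregating sites; allele labelling is arbitrary
#' because r^2 is label-invariant.
#'
#' @param f a `filtered_alignment` with at least 2 segregating sites
#'   (NA otherwise)
#' @return ZnS in \[0, 1\], or NA
#' @export
kelly_zns <- function(f) {
  mat <- f$matrix
  seg <- which(apply(mat, 2L, function(col) length(unique(col)) == 2L))
  if (length(seg) < 2L) return(NA_real_)
  bin <- vapply(seg, function(j) {
    as.integer(mat[, j] == mat[1L, j])
  }, integer(nrow(mat)))
  zns_from_01(bin)
}

#' All four neutrality statistics for one gene
#'
#' Convenience wrapper returning Tajima's D, normalized H, Ewens-Watterson
#' F and Kelly's ZnS for a filtered alignment, with the locus-scale
#' pairwise diversity they share.
#'
#' @param f a `filtered_alignment`
#' @param consensus outgroup consensus over retained columns (for H); may
#'   be NULL, in which case H is NA
#' @return list with `S`, `theta_pi_locus`, `D`, `H`, `F`, `Zns`, and the
#'   `spectrum` used for H (NULL without consensus)
#' @export
neutrality_stats <- function(f, consensus = NULL) {
  S <- segregating_sites(f)
  pi_locus <- theta_pi(f, per_site = FALSE)
  spec <- NULL
  H <- NA_real_
  if (!is.null(consensus)) {
    spec <- polarize(f, consensus)
    H <- fay_wu_h(spec)
  }
  list(S = S,
       theta_pi_locus = pi_locus,
       D = tajima_d(S, pi_locus, nrow(f$matrix)),
       H = H,
       F = ewens_watterson_f(f),
       Zns = kelly_zns(f),
       spectrum = spec)
}
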