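# pairwise-difference machinery shared by theta_pi and the per-category
# estimators: total mean pairwise differences contributed by a set of
# columns of the filtered matrix
pairwise_diff_total <- function(mat, cols = seq_len(ncol(mat))) {
  n <- nrow(mat)
  npairs <- n * (n - 1) / 2
  if (length(cols) == 0L) return(0)
  per_col <- vapply(cols, function(j) {
    tab <- table(mat[, j])
    (npairs - sum(tab * (tab - 1) / 2)) / npairs
  }, numeric(1))
  sum(per_col)
}

#' Number of segregating sites
#'
#' Retained columns with exactly two ingroup alleles. After
#' [filter_sites()] no column can carry more than two, so each column
#' contributes at most 1.
#'
#' @param f a `filtered_alignment`
#' @return integer count
#' @export
segregating_sites <- function(f) {
  if (f$L == 0L) return(0L)
  sum(apply(f$matrix, 2L, function(col) length(unique(col))) == 2L)
}

#' Pairwise nucleotide diversity (theta_pi)
#'
#' Average number of differences over all n(n-1)/2 sequence pairs, per site
#' (`per_site = TRUE`, the default) or for the whole locus.
#'
#' @param f a `filtered_alignment` with `n >= 2`; NA when `L = 0`
#' @param per_site divide by the number of retained sites?
#' @return theta_pi
#' @export
theta_pi <- function(f, per_site = TRUE) {
  if (f$L == 0L) return(NA_real_)
  tot <- pairwise_diff_total(f$matrix)
  if (per_site) tot / f$L else tot
}

#' Watterson's estimator (theta_w)
#'
#' S / (a1 L) per site with a1 the harmonic number of n - 1, or S / a1 for
#' the whole locus.
#'
#' @inheritParams theta_pi
#' @return theta_w
#' @export
theta_w <- function(f, per_site = TRUE) {
  if (f$L == 0L) return(NA_real_)
  S <- segregating_sites(f)
  val <- S / a1_n(nrow(f$matrix))
  if (per_site) val / f$L else val
}

#' Per-site divergence to the outgroup consensus (Dxy)
#'
#' Average over ingroup rows of (differences to the consensus / usable
#' sites), where usable sites exclude columns at which the consensus is N
#' (unresolved majority or missing outgroup data); the denominator is
#' renormalized to those usable sites.
#'
#' @param f a `filtered_alignment`
#' @param consensus outgroup consensus over the retained columns
#' @return Dxy per site, or NA when no site is usable
#' @export
dxy <- function(f, consensus) {
  consensus <- as_char_vector(consensus, f$L)
  usable <- which(!is.na(consensus))
  if (length(usable) == 0L) return(NA_real_)
  mat <- f$matrix[, usable, drop = FALSE]
  cons <- consensus[usable]
  per_row <- apply(mat, 1L, function(row) sum(row != cons)) / length(usable)
  mean(per_row)
}

#' Diversity restricted to site categories
#'
#' theta_pi and theta_w over each annotation category's columns, dividing
#' by that category's (fractional) site count; `silent` pools noncoding
#' and synonymous sites. Categories with zero sites are NA.
#'
#' @param f a `filtered_alignment`
#' @param ann a `site_annotation`
#' @return list with `pi_by_category` and `thetaw_by_category`, each a
#'   named numeric vector over `noncoding`, `synonymous`, `nonsynonymous`,
#'   `silent`
#' @export
category_diversity <- function(f, ann) {
  stopifnot(length(ann$site_category) == f$L)
  cat <- ann$site_category
  coding <- !(cat %in% c("noncoding", "mixed_excluded"))
  a1 <- a1_n(nrow(f$matrix))
  seg <- apply(f$matrix, 2L, function(col) length(unique(col)) == 2L)

  one <- function(cols, denom) {
    if (denom <= 0) return(c(pi = NA_real_, tw = NA_real_))
    c(pi = pairwise_diff_total(f$matrix, cols) / denom,
      tw = sum(seg[cols]) / a1 / denom)
  }
  nc <- one(which(cat == "noncoding"), ann$noncoding_sites)
  # variation at synonymous/nonsynonymous sites: polymorphic columns carry
  # the signal; fractional site counts are the denominators
  sy <- one(which(cat == "synonymous"), ann$syn_sites)
  ns <- one(which(cat == "nonsynonymous"), ann$nonsyn_sites)
  si <- one(which(cat %in% c("noncoding", "synonymous")), ann$silent_sites)
  list(
    pi_by_category = c(noncoding = unname(nc["pi"]),
                       synonymous = unname(sy["pi"]),
                       nonsynonymous = unname(ns["pi"]),
                       silent = unname(si["pi"])),
    thetaw_by_category = c(noncoding = unname(nc["tw"]),
                           synonymous = unname(sy["tw"]),
                           nonsynonymous = unname(ns["tw"]),
                           silent = unname(si["tw"]))
  )
}

#' Synonymous and nonsynonymous divergence (Ka, Ks)
#'
#' Coding differences between the ingroup majority consensus and the
#' outgroup consensus, classified codon-by-codon with mutational-pathway
#' averaging (paths through stop codons excluded), divided by the
#' annotation's fractional nonsynonymous and synonymous site counts.
#' Codons with unresolved context on either side are skipped. The ratio is
#' NA when Ks = 0 (the raw numerators and denominators are returned so
#' small-denominator instability stays visible).
#'
#' @param f a `filtered_alignment`
#' @param ann a `site_annotation`
#' @param consensus outgroup consensus over the retained columns
#' @param aln optional originating `gene_alignment` for ingroup codon
#'   context at filtered-out positions
#' @return list with `Ka`, `Ks`, `ratio`, `nonsyn_diffs`, `syn_diffs`,
#'   `nonsyn_sites`, `syn_sites`
#' @export
ka_ks <- function(f, ann, consensus, aln = NULL) {
  consensus <- as_char_vector(consensus, f$L)
  coding <- ann$coding_intervals
  if (ann$syn_sites + ann$nonsyn_sites <= 0) {
    return(list(Ka = NA_real_, Ks = NA_real_, ratio = NA_real_,
                nonsyn_diffs = 0, syn_diffs = 0,
                nonsyn_sites = ann$nonsyn_sites, syn_sites = ann$syn_sites))
  }
  rc <- f$retained_columns
  ing_cons_retained <- ingroup_consensus(f$matrix)
  context_base <- function(col0) {
    if (!is.null(aln)) {
      return(ingroup_consensus(aln$ingroup[, col0 + 1L, drop = FALSE]))
    }
    j <- match(col0, rc)
    if (is.na(j)) "N" else ing_cons_retained[j]
  }
  syn_d <- 0
  nonsyn_d <- 0
  for (iv in seq_len(nrow(coding))) {
    s <- coding$start[iv]; e <- coding$end[iv]; fr <- coding$frame[iv]
    ncodon <- (e - s - fr) %/% 3L
    if (ncodon <= 0L) next
    for (cid in seq_len(ncodon) - 1L) {
      codon_cols <- s + fr + 3L * cid + 0:2
      jpos <- match(codon_cols, rc)
      ing <- vapply(codon_cols, context_base, character(1))
      out <- rep(NA_character_, 3L)
      out[!is.na(jpos)] <- consensus[jpos[!is.na(jpos)]]
      # sites absent from the retained set carry no divergence information;
      # fill them with the ingroup base so only observed differences count
      out[is.na(out)] <- ing[is.na(out)]
      if (any(!(ing %in% VALID_BASES)) || any(!(out %in% VALID_BASES))) next
      if (all(ing == out)) next
      seg_pos <- which(ing != out)
      frac <- codon_path_syn_fraction(ing, out, seg_pos)
      syn_d <- syn_d + sum(frac)
      nonsyn_d <- nonsyn_d + sum(1 - frac)
    }
  }
  Ka <- if (ann$nonsyn_sites > 0) nonsyn_d / ann$nonsyn_sites else NA_real_
  Ks <- if (ann$syn_sites > 0) syn_d / ann$syn_sites else NA_real_
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  list(Ka = Ka, Ks = Ks, ratio = ratio,
       nonsyn_diffs = nonsyn_d, syn_diffs = syn_d,
       nonsyn_sites = ann$nonsyn_sites, syn_sites = ann$syn_sites)
}

#' All diversity and divergence statistics for one gene
#'
#' Bundles S, theta_pi, theta_w, Dxy and (when an annotation is available)
#' the per-category estimators and Ka/Ks into one row-like list.
#'
#' @param f a `filtered_alignment`
#' @param consensus outgroup consensus over retained columns, or NULL
#' @param ann a `site_annotation`, or NULL
#' @param aln optional originating `gene_alignment` (codon context)
#' @return object of class `gene_diversity` (a named list)
#' @export
gene_diversity <- function(f, consensus = NULL, ann = NULL, aln = NULL) {
  n <- nrow(f$matrix)
  res <- list(gene_id = f$gene_id, n = n, L = f$L,
              S = segregating_sites(f),
              theta_pi = theta_pi(f), theta_w = theta_w(f),
              dxy = NA_real_,
              pi_by_category = NULL, thetaw_by_category = NULL,
              Ka = NA_real_, Ks = NA_real_,
              ratio_pia_pis = NA_real_, ratio_ka_ks = NA_real_)
  if (!is.null(consensus)) res$dxy <- dxy(f, consensus)
  if (!is.null(ann)) {
    cd <- category_diversity(f, ann)
    res$pi_by_category <- cd$pi_by_category
    res$thetaw_by_category <- cd$thetaw_by_category
    pia <- cd$pi_by_category["nonsynonymous"]
    pis <- cd$pi_by_category["synonymous"]
    res$ratio_pia_pis <- if (!is.na(pis) && pis > 0) unname(pia / pis) else
      NA_real_
    if (!is.null(consensus)) {
      kk <- ka_ks(f, ann, consensus, aln = aln)
      res$Ka <- kk$Ka; res$Ks <- kk$Ks; res$ratio_ka_ks <- kk$ratio
    }
  }
  class(res) <- "gene_diversity"
  res
}
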