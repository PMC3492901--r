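# codon -> amino acid under the standard nuclear code; NA for untranslatable
translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  unname(aa)
}

# Nei-Gojobori fractional synonymous site count for position k (1..3) of a
# codon: (number of the 3 possible single-nucleotide changes that are
# synonymous) / 3. Changes producing stop codons count as nonsynonymous;
# a stop or untranslatable codon returns NA.
ng_fraction <- function(codon, k) {
  bases <- strsplit(codon, "")[[1]]
  aa0 <- translate_codon(codon)
  if (is.na(aa0) || aa0 == "*") return(NA_real_)
  alts <- setdiff(VALID_BASES, bases[k])
  nsyn <- 0L
  for (b in alts) {
    mut <- bases
    mut[k] <- b
    aa1 <- translate_codon(paste(mut, collapse = ""))
    if (!is.na(aa1) && aa1 != "*" && aa1 == aa0) nsyn <- nsyn + 1L
  }
  nsyn / 3
}

# Pathway enumeration for one codon. major/minor: length-3 base vectors
# (minor == major at non-segregating positions). seg: indices (1..3) of
# the segregating positions. Returns, for each segregating position, the
# fraction of pathway steps at that position that are synonymous, averaged
# over mutational pathways (orderings of the changes). Pathways through
# stop codons are excluded from the average; if every pathway hits a stop
# they are reinstated with stop steps counted as nonsynonymous.
codon_path_syn_fraction <- function(major, minor, seg) {
  perms <- permutations_of(seg)
  for (drop_stops in c(TRUE, FALSE)) {
    syn_sum <- stats::setNames(numeric(length(seg)), seg)
    npaths <- 0L
    for (ord in perms) {
      cur <- major
      path_ok <- TRUE
      steps_syn <- stats::setNames(numeric(length(seg)), seg)
      for (pos in ord) {
        nxt <- cur
        nxt[pos] <- minor[pos]
        aa_from <- translate_codon(paste(cur, collapse = ""))
        aa_to <- translate_codon(paste(nxt, collapse = ""))
        hits_stop <- is.na(aa_from) || is.na(aa_to) ||
          aa_from == "*" || aa_to == "*"
        if (hits_stop && drop_stops) { path_ok <- FALSE; break }
        steps_syn[as.character(pos)] <-
          as.numeric(!hits_stop && aa_from == aa_to)
        cur <- nxt
      }
      if (path_ok) {
        syn_sum <- syn_sum + steps_syn
        npaths <- npaths + 1L
      }
    }
    if (npaths > 0L) return(syn_sum / npaths)
  }
  stats::setNames(numeric(length(seg)), seg)   # unreachable
}

# all permutations of a small vector (<= 3 elements needed here)
permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) {
      out[[length(out) + 1L]] <- c(x[i], rest)
    }
  }
  out
}

#' Classify retained sites as noncoding / synonymous / nonsynonymous
#'
#' Maps each retained site of a filtered alignment to a category from the
#' supplied coding intervals. Sites outside every interval are noncoding.
#' Within codons, a polymorphic site is synonymous only if every
#' segregating allele, substituted into the codon context, leaves the
#' amino acid unchanged (for codons with several segregating positions the
#' mutational pathways are enumerated, excluding paths through stop
#' codons, and the site must be synonymous along all of them). Monomorphic
#' coding positions are apportioned fractionally in the Nei-Gojobori
#' style; their categorical label follows the larger fractional share.
#' Codons whose context cannot be established (a position with no
#' non-missing data, a codon truncated by its interval, or an internal
#' stop in the consensus) have their retained sites flagged
#' `mixed_excluded` and dropped from all category totals.
#'
#' The codon context is the ingroup majority consensus, taken from the
#' original alignment when `aln` is supplied (so codons containing a
#' filtered-out column keep their context) and from the retained columns
#' alone otherwise.
#'
#' @param f a `filtered_alignment`
#' @param coding data.frame with columns `start`, `end` (0-based,
#'   half-open, original alignment coordinates) and `frame` (0/1/2: offset
#'   of the first complete codon from `start`); intervals must not overlap
#' @param aln optional originating `gene_alignment` for codon context
#' @return object of class `site_annotation`: list with `gene_id`,
#'   `coding_intervals`, `site_category` (length-L character vector),
#'   `f_syn` (length-L fractional synonymous site contribution, NA outside
#'   coding), and the totals `syn_sites`, `nonsyn_sites`,
#'   `noncoding_sites`, `silent_sites`, `mixed_excluded`
#' @export
classify_sites <- function(f, coding, aln = NULL) {
  stopifnot(all(c("start", "end", "frame") %in% names(coding)))
  if (nrow(coding) > 1L) {
    o <- order(coding$start)
    coding <- coding[o, ]
    if (any(coding$end[-nrow(coding)] > coding$start[-1L])) {
      stop("coding intervals overlap for gene ", f$gene_id)
    }
  }
  if (any(coding$frame < 0 | coding$frame > 2)) {
    stop("frame must be 0, 1 or 2")
  }
  L <- f$L
  rc <- f$retained_columns            # 0-based original columns
  category <- rep("noncoding", L)
  f_syn <- rep(NA_real_, L)

  context_mat <- if (!is.null(aln)) aln$ingroup else NULL
  # consensus base at an original 0-based column, or N when unknowable
  context_base <- function(col0) {
    if (!is.null(context_mat)) {
      return(ingroup_consensus(context_mat[, col0 + 1L, drop = FALSE]))
    }
    j <- match(col0, rc)
    if (is.na(j)) return("N")
    ingroup_consensus(f$matrix[, j, drop = FALSE])
  }

  for (iv in seq_len(nrow(coding))) {
    s <- coding$start[iv]; e <- coding$end[iv]; fr <- coding$frame[iv]
    in_iv <- which(rc >= s & rc < e)
    if (length(in_iv) == 0L) next
    offset <- rc[in_iv] - s - fr
    codon_id <- ifelse(offset < 0, -1L, offset %/% 3L)
    for (cid in unique(codon_id)) {
      sites <- in_iv[codon_id == cid]
      if (cid < 0L) { category[sites] <- "mixed_excluded"; next }
      codon_cols <- s + fr + 3L * cid + 0:2          # 0-based
      if (any(codon_cols >= e)) { category[sites] <- "mixed_excluded"; next }
      ctx <- vapply(codon_cols, context_base, character(1))
      if (any(!(ctx %in% VALID_BASES))) {
        category[sites] <- "mixed_excluded"; next
      }
      codon <- paste(ctx, collapse = "")
      aa0 <- translate_codon(codon)
      if (is.na(aa0) || aa0 == "*") {              # internal stop in context
        category[sites] <- "mixed_excluded"; next
      }
      # positions within codon (1..3) of the retained sites, and which are
      # segregating in the filtered matrix
      pos_in_codon <- match(rc[sites], codon_cols)
      jcols <- match(rc[sites], rc)
      seg <- vapply(jcols, function(j) {
        length(unique(f$matrix[, j])) == 2L
      }, logical(1))
      # fractional site contributions always from the consensus codon
      f_syn[sites] <- vapply(pos_in_codon, function(k) ng_fraction(codon, k),
                             numeric(1))
      if (!any(seg)) {
        category[sites] <- ifelse(f_syn[sites] > 0.5, "synonymous",
                                  "nonsynonymous")
        next
      }
      major <- ctx
      minor <- ctx
      for (idx in which(seg)) {
        j <- jcols[idx]
        alleles <- unique(f$matrix[, j])
        k <- pos_in_codon[idx]
        maj <- major[k]
        other <- setdiff(alleles, maj)
        if (length(other) == 0L) {   # consensus disagreed with both (tie)
          maj <- alleles[1L]; other <- alleles[2L]
          major[k] <- maj
        }
        minor[k] <- other[1L]
      }
      syn_frac <- codon_path_syn_fraction(major, minor, pos_in_codon[seg])
      for (ii in seq_along(sites)) {
        if (seg[ii]) {
          category[sites[ii]] <-
            if (syn_frac[as.character(pos_in_codon[ii])] == 1) "synonymous" else
              "nonsynonymous"
        } else {
          category[sites[ii]] <- ifelse(f_syn[sites[ii]] > 0.5, "synonymous",
                                        "nonsynonymous")
        }
      }
    }
  }
  f_syn[category %in% c("noncoding", "mixed_excluded")] <- NA_real_
  totals <- count_totals(category, f_syn)
  structure(c(list(gene_id = f$gene_id, coding_intervals = coding,
                   site_category = category, f_syn = f_syn), totals),
            class = "site_annotation")
}

count_totals <- function(category, f_syn) {
  cod <- !(category %in% c("noncoding", "mixed_excluded"))
  syn_sites <- sum(f_syn[cod])
  nonsyn_sites <- sum(1 - f_syn[cod])
  noncoding_sites <- sum(category == "noncoding")
  list(syn_sites = syn_sites,
       nonsyn_sites = nonsyn_sites,
       noncoding_sites = noncoding_sites,
       silent_sites = noncoding_sites + syn_sites,
       mixed_excluded = sum(category == "mixed_excluded"))
}

#' Fractional site counts by category
#'
#' Recomputes the Nei-Gojobori style fractional site totals from an
#' annotation: each coding position contributes its synonymous fraction to
#' `syn_sites` and the complement to `nonsyn_sites`; noncoding positions
#' contribute 1 each to `noncoding_sites`.
#'
#' @param f a `filtered_alignment` (used only for a length check)
#' @param ann a `site_annotation` from [classify_sites()]
#' @return named numeric vector `c(syn_sites, nonsyn_sites,
#'   noncoding_sites)`
#' @export
count_sites <- function(f, ann) {
  stopifnot(length(ann$site_category) == f$L)
  totals <- count_totals(ann$site_category, ann$f_syn)
  c(syn_sites = totals$syn_sites,
    nonsyn_sites = totals$nonsyn_sites,
    noncoding_sites = totals$noncoding_sites)
}

#' @export
print.site_annotation <- function(x, ...) {
  cat(sprintf(
    "<site_annotation> %s: %.2f syn + %.2f nonsyn + %d noncoding sites (%d excluded)\n",
    x$gene_id, x$syn_sites, x$nonsyn_sites, x$noncoding_sites,
    x$mixed_excluded))
  invisible(x)
}
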