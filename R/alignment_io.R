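#' Per-gene haploid alignment with outgroup
#'
#' Container for one gene's aligned haploid ingroup sample plus one or more
#' aligned outgroup rows. All coordinates in this package are 0-based,
#' half-open (alignment column 1 of the FASTA is index 0). The alphabet is
#' A, C, G, T, `-` (gap) and N (missing); any other IUPAC ambiguity code in
#' the ingroup is treated as missing, since haploid megagametophyte
#' sequences should never carry genuine heterozygous ambiguity calls.
#'
#' @param ingroup character matrix (rows = haploid sequences, columns =
#'   alignment positions), rownames = sequence names
#' @param outgroup character matrix with the same number of columns (0 rows
#'   allowed; statistics needing polarization are then unavailable)
#' @param gene_id,species,category identifiers; `category` is `"candidate"`
#'   or `"control"`
#' @param primer_intervals optional list of two half-open 0-based column
#'   intervals `list(fwd = c(start, end), rev = c(start, end))`
#' @return object of class `gene_alignment`
#' @export
gene_alignment <- function(ingroup, outgroup = NULL, gene_id = "gene",
                           species = NA_character_,
                           category = c("candidate", "control"),
                           primer_intervals = NULL) {
  category <- match.arg(category)
  ingroup <- toupper(as.matrix(ingroup))
  if (is.null(outgroup)) {
    outgroup <- matrix(character(0), nrow = 0, ncol = ncol(ingroup))
  }
  outgroup <- toupper(as.matrix(outgroup))
  if (ncol(outgroup) != ncol(ingroup)) {
    stop("outgroup rows must be aligned to the same columns as the ingroup")
  }
  if (nrow(ingroup) < 2L) {
    stop("at least 2 ingroup sequences are required")
  }
  if (anyDuplicated(rownames(ingroup))) {
    warning("identical ingroup sequence names; duplicate-sequence removal ",
            "is assumed to have happened upstream")
  }
  structure(list(
    gene_id = gene_id,
    species = species,
    category = category,
    ingroup = ingroup,
    outgroup = outgroup,
    primer_intervals = primer_intervals,
    masked_columns = integer(0),   # 0-based, filled by mask_primers()
    n = nrow(ingroup)
  ), class = "gene_alignment")
}

#' @export
print.gene_alignment <- function(x, ...) {
  cat(sprintf("<gene_alignment> %s (%s, %s): n = %d, %d outgroup row(s), %d columns\n",
              x$gene_id, x$species, x$category, x$n, nrow(x$outgroup),
              ncol(x$ingroup)))
  invisible(x)
}

#' Read one gene's aligned FASTA
#'
#' Records whose header contains `outgroup_tag` (fixed substring match) are
#' the outgroup; everything else is ingroup. The file must be a true
#' alignment (equal record lengths).
#'
#' @param path FASTA file
#' @param outgroup_tag substring identifying outgroup headers
#' @param gene_id defaults to the file name without extension
#' @param species,category,primer_intervals passed to [gene_alignment()]
#' @return a `gene_alignment`; if no record matches `outgroup_tag` the
#'   alignment is returned with zero outgroup rows and a warning (the gene
#'   is still usable for statistics that do not need polarization)
#' @export
read_gene_fasta <- function(path, outgroup_tag, gene_id = NULL,
                            species = NA_character_, category = "candidate",
                            primer_intervals = NULL) {
  seqs <- Biostrings::readBStringSet(path)
  if (length(unique(Biostrings::width(seqs))) != 1L) {
    stop("records in ", path, " have unequal lengths; not an alignment")
  }
  mat <- do.call(rbind, strsplit(toupper(as.character(seqs)), ""))
  rownames(mat) <- names(seqs)
  is_out <- grepl(outgroup_tag, names(seqs), fixed = TRUE)
  if (!any(is_out)) {
    warning("no record in ", path, " matches outgroup tag '", outgroup_tag,
            "'; polarization and divergence will be unavailable")
  }
  gene_alignment(
    ingroup = mat[!is_out, , drop = FALSE],
    outgroup = mat[is_out, , drop = FALSE],
    gene_id = gene_id %||% sub("\\.[^.]*$", "", basename(path)),
    species = species, category = category,
    primer_intervals = primer_intervals
  )
}

#' Write a gene alignment back to FASTA
#'
#' Inverse of [read_gene_fasta()]: ingroup rows first, then outgroup rows,
#' using the stored row names as headers.
#'
#' @param aln a `gene_alignment`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_gene_fasta <- function(aln, path) {
  mat <- rbind(aln$ingroup, aln$outgroup)
  seqs <- Biostrings::BStringSet(apply(mat, 1L, paste, collapse = ""))
  names(seqs) <- rownames(mat)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Mask columns outside the primer-delimited interval
#'
#' Signal outside the region spanned between the forward and reverse
#' sequencing primers can arise from mispriming; those columns, and the
#' primer-annealing columns themselves, are replaced by N in every row
#' (ingroup and outgroup). Columns strictly between the two primer
#' intervals are untouched. Without `primer_intervals` the alignment is
#' returned unchanged.
#'
#' @param aln a `gene_alignment`
#' @return a `gene_alignment` with `masked_columns` recording the 0-based
#'   masked columns, so that downstream filtering can log them as
#'   `primer_masked` rather than generic missing data
#' @export
mask_primers <- function(aln) {
  pi <- aln$primer_intervals
  if (is.null(pi)) return(aln)
  L <- ncol(aln$ingroup)
  fwd <- pi$fwd; rev <- pi$rev
  ok <- function(iv) length(iv) == 2 && iv[1] >= 0 && iv[2] <= L && iv[1] < iv[2]
  if (!ok(fwd) || !ok(rev) || fwd[2] > rev[1]) {
    stop("primer intervals out of bounds or overlapping for gene ", aln$gene_id)
  }
  # mask [0, fwd_end) and [rev_start, L)  (0-based half-open)
  masked0 <- c(seq_len(fwd[2]) - 1L, seq.int(rev[1], L - 1L))
  cols <- masked0 + 1L
  aln$ingroup[, cols] <- "N"
  if (nrow(aln$outgroup) > 0L) aln$outgroup[, cols] <- "N"
  aln$masked_columns <- sort(unique(c(aln$masked_columns, masked0)))
  aln
}

VALID_BASES <- c("A", "C", "G", "T")

#' Filter alignment columns for the infinite-sites analyses
#'
#' Drops every column with missing data (N or any non-ACGT, non-gap
#' character) or an alignment gap in any ingroup row, and every column with
#' more than two distinct ingroup nucleotides (an infinite-sites
#' violation). Outgroup characters never trigger removal: outgroup gaps or
#' Ns only make that site unusable for polarization and divergence. The
#' retained matrix is complete and every column is at most biallelic, so
#' all downstream statistics operate on clean data.
#'
#' @param aln a `gene_alignment`
#' @return object of class `filtered_alignment`: list with `gene_id`,
#'   `matrix` (retained ingroup columns), `outgroup` (outgroup rows at the
#'   retained columns), `retained_columns` (0-based original indices), `L`,
#'   and `removal_log` (data.frame `column` 0-based, `reason` in
#'   `primer_masked`, `indel`, `missing`, `infinite_sites_violation`).
#'   `L = 0` flags an empty alignment whose statistics are undefined.
#' @export
filter_sites <- function(aln) {
  mat <- aln$ingroup
  L0 <- ncol(mat)
  masked <- aln$masked_columns
  reason <- character(0)
  bad <- integer(0)
  for (j in seq_len(L0)) {
    col <- mat[, j]
    r <- NA_character_
    if ((j - 1L) %in% masked) {
      r <- "primer_masked"
    } else if (any(col == "-")) {
      r <- "indel"
    } else if (any(!(col %in% VALID_BASES))) {
      r <- "missing"
    } else if (length(unique(col)) > 2L) {
      r <- "infinite_sites_violation"
    }
    if (!is.na(r)) {
      bad <- c(bad, j)
      reason <- c(reason, r)
    }
  }
  keep <- setdiff(seq_len(L0), bad)
  structure(list(
    gene_id = aln$gene_id,
    matrix = mat[, keep, drop = FALSE],
    outgroup = aln$outgroup[, keep, drop = FALSE],
    retained_columns = keep - 1L,
    L = length(keep),
    removal_log = data.frame(column = bad - 1L, reason = reason,
                             stringsAsFactors = FALSE)
  ), class = "filtered_alignment")
}

#' @export
print.filtered_alignment <- function(x, ...) {
  cat(sprintf("<filtered_alignment> %s: n = %d, L = %d retained of %d, %d removed\n",
              x$gene_id, nrow(x$matrix), x$L,
              x$L + nrow(x$removal_log), nrow(x$removal_log)))
  invisible(x)
}

#' Majority-rules outgroup consensus
#'
#' Per column, the strict-majority nucleotide among non-gap, non-N outgroup
#' characters; ties and all-missing columns yield N, making the site
#' unusable for divergence and polarization there.
#'
#' @param aln a `gene_alignment` (uses all original columns) or a
#'   `filtered_alignment` (uses retained columns)
#' @return character vector of consensus characters (A/C/G/T/N)
#' @export
outgroup_consensus <- function(aln) {
  out <- if (inherits(aln, "filtered_alignment")) aln$outgroup else aln$outgroup
  if (nrow(out) == 0L) stop("no outgroup rows for gene ", aln$gene_id)
  apply(out, 2L, function(col) {
    col <- col[col %in% VALID_BASES]
    if (length(col) == 0L) return("N")
    tab <- table(col)
    top <- tab[tab == max(tab)]
    if (length(top) > 1L) "N" else names(top)
  })
}

# accept either a single string or a character vector of length L
as_char_vector <- function(x, L) {
  if (length(x) == 1L && nchar(x) == L) x <- strsplit(x, "")[[1]]
  stopifnot(length(x) == L || L == 0L)
  x <- toupper(x)
  x[!(x %in% VALID_BASES)] <- NA_character_
  x
}

# majority consensus of ingroup rows at each column (ties broken to the
# alphabetically first top base; all-missing -> N)
ingroup_consensus <- function(mat) {
  apply(mat, 2L, function(col) {
    col <- col[col %in% VALID_BASES]
    if (length(col) == 0L) return("N")
    tab <- sort(table(col), decreasing = TRUE)
    names(tab)[1L]
  })
}
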