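#' Simulate one standard-neutral-model coalescent replicate
#'
#' Hudson-style neutral coalescent for a sample of `n` haploid sequences
#' with infinite-sites mutation. Time is measured in units of 2N
#' generations: while k lineages remain, the waiting time to the next
#' coalescence is exponential with rate k(k-1)/2 and a uniformly random
#' pair merges. Mutations are then dropped on the genealogy as a Poisson
#' process with rate `theta_locus / 2` per unit branch length, which gives
#' the classical expectation E[S] = theta_locus * a1 (so `theta_locus`
#' matches the `-t` argument of Hudson's `ms`, 4N*mu per locus).
#'
#' Uses the current RNG state; seed outside (e.g. via [derive_seed()]).
#'
#' @param n sample size (>= 2)
#' @param theta_locus population mutation rate for the whole locus (> 0)
#' @return an object of class `coal_replicate`: a list with `n`,
#'   `times` (inter-coalescence waiting times, 2N units), `tmrca`,
#'   `total_branch_length` (2N units), `S`, `matrix` (n x S 0/1 matrix,
#'   1 = derived), `counts` (derived-allele count per column) and
#'   `positions` (relative positions in \[0,1), sorted).
#' @seealso [null_distribution()], [replicate_stats()]
#' @export
simulate_replicate <- function(n, theta_locus) {
  stopifnot(n >= 2, theta_locus > 0)
  kk <- n:2
  times <- stats::rexp(n - 1L, rate = kk * (kk - 1) / 2)
  build_replicate_from_tree(n, times, theta_locus)
}

# Shared machinery: given per-interval waiting times (intervals with n..2
# lineages), random topology, drop Poisson mutations. Returns coal_replicate.
build_replicate_from_tree <- function(n, times, theta_locus) {
  # lineage membership while merging; segments collect (carrier set, length)
  lineages <- as.list(seq_len(n))
  seg_members <- vector("list", n * (n + 1L) / 2L - 1L)
  seg_len <- numeric(length(seg_members))
  p <- 0L
  for (j in seq_len(n - 1L)) {
    k <- length(lineages)
    for (l in seq_len(k)) {
      p <- p + 1L
      seg_members[[p]] <- lineages[[l]]
      seg_len[p] <- times[j]
    }
    pair <- sample.int(k, 2L)
    merged <- c(lineages[[pair[1L]]], lineages[[pair[2L]]])
    lineages[[pair[1L]]] <- merged
    lineages[[pair[2L]]] <- NULL
  }
  total_len <- sum(seg_len)
  S <- stats::rpois(1L, theta_locus / 2 * total_len)
  mat <- matrix(0L, nrow = n, ncol = S)
  if (S > 0L) {
    hit <- sample.int(length(seg_len), S, replace = TRUE, prob = seg_len)
    for (s in seq_len(S)) mat[seg_members[[hit[s]]], s] <- 1L
  }
  structure(list(
    n = n,
    times = times,
    tmrca = sum(times),
    total_branch_length = total_len,
    S = S,
    matrix = mat,
    counts = if (S > 0L) colSums(mat) else integer(0),
    positions = sort(stats::runif(S))
  ), class = "coal_replicate")
}

#' Neutrality statistics for one simulated replicate
#'
#' Computes Tajima's D, Fay & Wu's normalized H (with perfect polarization:
#' the simulator's 0 state is ancestral by construction), Ewens-Watterson F
#' and Kelly's ZnS on a 0/1 replicate matrix. Statistics undefined for the
#' replicate (S = 0 for D/H, no polarizable sites, S < 2 for ZnS) are NA.
#'
#' @param rep a `coal_replicate`
#' @return named numeric vector `c(D, H, F, Zns)`
#' @export
replicate_stats <- function(rep) {
  n <- rep$n
  cnt <- rep$counts
  S <- length(cnt)
  FF <- haplotype_homozygosity_01(rep$matrix)
  if (S == 0L) {
    return(c(D = NA_real_, H = NA_real_, F = FF, Zns = NA_real_))
  }
  npairs <- n * (n - 1) / 2
  pi_locus <- sum(cnt * (n - cnt)) / npairs
  D <- tajima_d(S, pi_locus, n)
  H <- fw_h_from_counts(cnt, n)
  Zns <- if (S >= 2L) zns_from_01(rep$matrix) else NA_real_
  c(D = D, H = H, F = FF, Zns = Zns)
}

# haplotype homozygosity sum(p_k^2) for a 0/1 matrix (rows = sequences)
haplotype_homozygosity_01 <- function(mat) {
  n <- nrow(mat)
  key <- if (ncol(mat) == 0L) rep("", n) else
    apply(mat, 1L, paste, collapse = "")
  sum((table(key) / n)^2)
}

# mean pairwise r^2 over columns of a 0/1 matrix (>= 2 columns)
zns_from_01 <- function(mat) {
  n <- nrow(mat)
  p <- colMeans(mat)
  keep <- p > 0 & p < 1
  mat <- mat[, keep, drop = FALSE]
  p <- p[keep]
  S <- ncol(mat)
  if (S < 2L) return(NA_real_)
  p11 <- crossprod(mat) / n
  Dmat <- p11 - tcrossprod(p)
  denom <- tcrossprod(p * (1 - p))
  r2 <- Dmat^2 / denom
  ut <- upper.tri(r2)
  mean(r2[ut])
}

#' Null distribution of a neutrality statistic under the SNM
#'
#' Simulates `reps` neutral coalescent replicates at (`n`, `theta_locus`)
#' and evaluates a statistic on each. Replicates on which the statistic is
#' undefined (e.g. S = 0 for Tajima's D) are recorded as NA and excluded
#' from `values`. Fay & Wu's H uses the simulator's true ancestral state.
#'
#' @param stat one of `"D"`, `"H"`, `"F"`, `"Zns"`, or a function taking a
#'   `coal_replicate` and returning a scalar
#' @param n sample size
#' @param theta_locus locus mutation rate (4N mu)
#' @param reps number of replicates (>= 1)
#' @param seed integer seed; the run is reproducible given the seed
#' @return an object of class `null_distribution`: list with
#'   `statistic_name`, `n`, `theta_locus`, `reps`, `values` (sorted,
#'   NA-dropped), `na_count`, `seed`
#' @export
null_distribution <- function(stat, n, theta_locus, reps, seed) {
  stopifnot(reps >= 1)
  statistic_name <- if (is.character(stat)) stat else "custom"
  statfun <- if (is.function(stat)) stat else {
    stopifnot(stat %in% c("D", "H", "F", "Zns"))
    function(rep) unname(replicate_stats(rep)[stat])
  }
  set.seed(seed)
  vals <- vapply(seq_len(reps), function(i) {
    statfun(simulate_replicate(n, theta_locus))
  }, numeric(1))
  structure(list(
    statistic_name = statistic_name,
    n = n,
    theta_locus = theta_locus,
    reps = reps,
    values = sort(vals[!is.na(vals)]),
    na_count = sum(is.na(vals)),
    seed = seed
  ), class = "null_distribution")
}

# matrix of (D, H, F, Zns) over reps neutral replicates; rows = replicates
null_stat_matrix <- function(n, theta_locus, reps, seed,
                             generator = simulate_replicate) {
  set.seed(seed)
  out <- matrix(NA_real_, nrow = reps, ncol = 4L,
                dimnames = list(NULL, c("D", "H", "F", "Zns")))
  for (i in seq_len(reps)) {
    out[i, ] <- replicate_stats(generator(n, theta_locus))
  }
  out
}

#' Empirical P-value against a simulated null
#'
#' Lower tail: `(#\{v <= observed\} + 1) / (usable + 1)`; upper tail
#' symmetric. The +1/+1 estimator never returns 0, so an observation beyond
#' all `reps` simulated values reports `1/(reps+1)` (the familiar
#' "P < 0.0001" of a 10,000-replicate run). NA simulated values must
#' already be excluded.
#'
#' @param observed observed statistic (NA gives NA)
#' @param null a `null_distribution` or a numeric vector of simulated values
#' @param tail `"lower"` or `"upper"`
#' @return P-value in (0, 1]
#' @export
empirical_pvalue <- function(observed, null, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  if (is.na(observed)) return(NA_real_)
  vals <- if (inherits(null, "null_distribution")) null$values else
    null[!is.na(null)]
  usable <- length(vals)
  if (usable < 1L) return(NA_real_)
  hits <- if (tail == "lower") sum(vals <= observed) else sum(vals >= observed)
  (hits + 1) / (usable + 1)
}

#' Write replicates in ms-like text form
#'
#' Emits `segsites:`/`positions:`/haplotype lines for a list of replicates,
#' for eyeballing or cross-validation against external simulators.
#'
#' @param reps list of `coal_replicate` objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_ms <- function(reps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (r in reps) {
    writeLines("//", con)
    writeLines(paste("segsites:", r$S), con)
    if (r$S > 0L) {
      writeLines(paste("positions:",
                       paste(formatC(r$positions, digits = 5, format = "f"),
                             collapse = " ")), con)
      writeLines(apply(r$matrix, 1L, paste, collapse = ""), con)
    }
  }
  invisible(path)
}
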