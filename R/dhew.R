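# Joint exceedance level of one (D, H, F) triple against a reference null:
# q = max(P_D, P_H, 1 - P_EW), with P_D and P_H lower-tail and P_EW
# lower-tail (so 1 - P_EW measures homozygosity excess, the
# sweep-sensitive direction). A gene rejects at per-component level p'
# iff q <= p'.
dhew_exceedance <- function(triples, ref) {
  refD <- sort(ref[!is.na(ref[, "D"]), "D"])
  refH <- sort(ref[!is.na(ref[, "H"]), "H"])
  refF <- sort(ref[!is.na(ref[, "F"]), "F"])
  apply(triples, 1L, function(x) {
    pD <- empirical_pvalue(x[["D"]], refD, "lower")
    pH <- empirical_pvalue(x[["H"]], refH, "lower")
    pEW <- empirical_pvalue(x[["F"]], refF, "lower")
    if (anyNA(c(pD, pH, pEW))) return(NA_real_)
    max(pD, pH, 1 - pEW)
  })
}

#' Calibrate the DHEW per-component significance level P*
#'
#' The compound DHEW test rejects neutrality only when Tajima's D, Fay &
#' Wu's normalized H and the Ewens-Watterson test are all individually
#' significant at a common per-component level P*. Because the three
#' statistics are correlated, P* must be calibrated by simulation so that
#' the joint rejection probability under the standard neutral model equals
#' the target multidimensional level `a`: `reps` neutral replicates are
#' simulated at the gene's (n, theta_locus) (conditioning on the observed
#' per-gene diversity), each replicate's three one-sided component
#' P-values are computed against an independently simulated reference
#' null of the same size, and P* is the largest per-component threshold at
#' which the fraction of replicates with all three component P-values
#' below it stays at or below `a`. P* is floored at
#' max(a, 1/(reps + 1)): the joint probability of three events can never
#' be smaller than any single event's probability, and levels below the
#' simulation resolution are not estimable.
#'
#' @param n sample size
#' @param theta_locus locus mutation rate, normally the gene's observed
#'   theta_pi per site times L
#' @param a target multidimensional level (the study default is 0.0001)
#' @param reps calibration replicates (study default 50,000; `a < 1/reps`
#'   triggers a resolution warning)
#' @param seed integer seed; calibration and reference sets use
#'   independent derived substreams
#' @param generator replicate generator, [simulate_replicate()] by default
#' @return object of class `dhew_calibration`: list with `P_star`, `a`,
#'   `n`, `theta_locus`, `reps`, `seed` and `ref` (the reference null
#'   triples, reusable for testing genes at the same (n, theta))
#' @export
calibrate_pstar <- function(n, theta_locus, a = 1e-4, reps = 50000L,
                            seed = 1L, generator = simulate_replicate) {
  stopifnot(a > 0, a <= 1, reps >= 1)
  if (a < 1 / reps) {
    warning("a = ", a, " is below the resolution of ", reps,
            " replicates; P* is floored at 1/(reps+1)")
  }
  ref <- null_stat_matrix(n, theta_locus, reps,
                          seed = derive_seed(seed, "dhew_ref"),
                          generator = generator)
  cal <- null_stat_matrix(n, theta_locus, reps,
                          seed = derive_seed(seed, "dhew_cal"),
                          generator = generator)
  q <- dhew_exceedance(cal, ref)
  q <- q[!is.na(q)]
  usable <- length(q)
  floor_p <- 1 / (reps + 1)
  if (a >= 1 || usable == 0L) {
    p_star <- 1
  } else {
    k <- floor(a * usable)
    qs <- sort(q)
    if (k >= usable) {
      p_star <- 1
    } else if (k < 1L) {
      p_star <- floor_p
    } else {
      # largest observed level whose empirical joint rejection stays <= a
      cand <- qs[k]
      while (sum(q <= cand) > k && cand > min(qs)) {
        below <- qs[qs < cand]
        if (length(below) == 0L) { cand <- floor_p; break }
        cand <- max(below)
      }
      p_star <- if (sum(q <= cand) > k) floor_p else cand
    }
  }
  p_star <- min(1, max(p_star, a, floor_p))
  structure(list(P_star = p_star, a = a, n = n, theta_locus = theta_locus,
                 reps = reps, seed = seed, ref = ref),
            class = "dhew_calibration")
}

#' @export
print.dhew_calibration <- function(x, ...) {
  cat(sprintf("<dhew_calibration> n = %d, theta = %.4g, a = %g, reps = %d: P* = %.4g\n",
              x$n, x$theta_locus, x$a, x$reps, x$P_star))
  invisible(x)
}

#' Apply the compound DHEW outlier decision to one gene
#'
#' A gene is an outlier when all three component tests are significant at
#' the calibrated level: P_D <= P*, P_H <= P* and 1 - P_EW <= P* (P_EW is
#' the lower-tail homozygosity P-value, so its complement measures
#' homozygosity excess). Genes with a single SNP are excluded outright to
#' avoid false positives driven by minimal diversity, and a gene with any
#' unavailable component (e.g. no polarizable site for H) is excluded with
#' a reason.
#'
#' @param gene_stats list or one-row data.frame with `gene_id`, `S`,
#'   `P_D`, `P_H`, `P_EW` (lower-tail)
#' @param P_star calibrated per-component level (a `dhew_calibration` or a
#'   number)
#' @return object of class `dhew_result`: list with `gene_id`, `S`,
#'   `P_star`, `component_P`, `outlier` (NA when excluded), `excluded`,
#'   `reason`
#' @export
dhew_test <- function(gene_stats, P_star) {
  if (inherits(P_star, "dhew_calibration")) P_star <- P_star$P_star
  g <- gene_stats
  comp <- c(P_D = g$P_D, P_H = g$P_H, P_EW = g$P_EW)
  excluded <- FALSE
  reason <- NA_character_
  outlier <- NA
  if (is.na(g$S) || g$S <= 1L) {
    excluded <- TRUE
    reason <- "single_SNP"
  } else if (anyNA(comp)) {
    excluded <- TRUE
    reason <- "component_unavailable"
  } else {
    outlier <- (comp[["P_D"]] <= P_star) &&
      (comp[["P_H"]] <= P_star) &&
      (1 - comp[["P_EW"]] <= P_star)
  }
  structure(list(gene_id = g$gene_id, S = g$S, P_star = P_star,
                 component_P = comp, outlier = outlier,
                 excluded = excluded, reason = reason),
            class = "dhew_result")
}
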