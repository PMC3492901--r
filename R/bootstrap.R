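#' Across-locus bootstrap mean with percentile confidence interval
#'
#' Resamples loci with replacement, takes the mean per replicate, and
#' returns the percentile interval at the requested level (via the `boot`
#' package). NA loci are dropped with a count. Degenerate inputs (a single
#' locus, or zero variance) collapse the interval onto the point estimate.
#'
#' @param values per-locus statistic values
#' @param reps bootstrap replicates (study default 10,000)
#' @param level confidence level (default 0.95)
#' @param seed integer seed; identical seeds give identical intervals
#' @param statistic_name,species labels carried into the summary
#' @return object of class `bootstrap_summary`: list with `species`,
#'   `statistic_name`, `n_loci`, `n_dropped`, `mean`, `ci_low`, `ci_high`,
#'   `reps`, `level`, `seed`
#' @export
bootstrap_mean_ci <- function(values, reps = 10000L, level = 0.95, seed = 1L,
                              statistic_name = "statistic",
                              species = NA_character_) {
  stopifnot(reps >= 1)
  n_dropped <- sum(is.na(values))
  values <- values[!is.na(values)]
  out <- list(species = species, statistic_name = statistic_name,
              n_loci = length(values), n_dropped = n_dropped,
              mean = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
              reps = reps, level = level, seed = seed)
  class(out) <- "bootstrap_summary"
  if (length(values) == 0L) return(out)
  out$mean <- mean(values)
  if (length(values) == 1L || stats::var(values) == 0) {
    out$ci_low <- out$mean
    out$ci_high <- out$mean
    return(out)
  }
  set.seed(seed)
  bt <- boot::boot(values, function(d, i) mean(d[i]), R = reps)
  ci <- boot::boot.ci(bt, conf = level, type = "perc")
  out$ci_low <- ci$percent[4L]
  out$ci_high <- ci$percent[5L]
  out
}

#' @export
print.bootstrap_summary <- function(x, ...) {
  cat(sprintf("<bootstrap_summary> %s %s: mean = %.4g [%.4g, %.4g] (%d loci, %d reps)\n",
              x$species, x$statistic_name, x$mean, x$ci_low, x$ci_high,
              x$n_loci, x$reps))
  invisible(x)
}

#' Compare two species means by bootstrap CI overlap
#'
#' The difference is called significant iff the two closed confidence
#' intervals do not overlap; touching endpoints count as overlap
#' (conservative).
#'
#' @param a,b `bootstrap_summary` objects for the same statistic
#' @return `"significant"`, `"not_significant"`, or `"not_comparable"`
#'   when either interval is NA
#' @export
compare_species <- function(a, b) {
  if (!identical(a$statistic_name, b$statistic_name)) {
    stop("summaries compare different statistics: ",
         a$statistic_name, " vs ", b$statistic_name)
  }
  if (anyNA(c(a$ci_low, a$ci_high, b$ci_low, b$ci_high))) {
    return("not_comparable")
  }
  if (a$ci_high < b$ci_low || b$ci_high < a$ci_low) "significant" else
    "not_significant"
}
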