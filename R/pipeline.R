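#' Configuration for a full study run
#'
#' @param manifest path to a manifest TSV (`gene_id`, `species`,
#'   `category`, `file`, ...; `file` relative to the manifest's directory)
#' @param out_dir output directory for the result tables
#' @param annotations optional path to an annotation TSV (`gene_id`,
#'   `start`, `end`, `frame`; 0-based half-open)
#' @param primers optional path to a primer TSV (`gene_id`, `fwd_start`,
#'   `fwd_end`, `rev_start`, `rev_end`; 0-based half-open)
#' @param outgroup_tag substring identifying outgroup FASTA headers
#' @param seed master seed; every stochastic step derives its own
#'   substream from it
#' @param reps_single replicates for the single-statistic null
#'   distributions (study default 10,000)
#' @param reps_dhew replicates for the DHEW P* calibration (study default
#'   50,000)
#' @param a target multidimensional DHEW level (study default 0.0001)
#' @param bootstrap_reps across-locus bootstrap replicates (study default
#'   10,000)
#' @param ci_level bootstrap confidence level
#' @param include_monomorphic include monomorphic genes (statistics 0) in
#'   the species means, rather than dropping them
#' @return a `run_config` list
#' @export
run_config <- function(manifest, out_dir, annotations = NULL, primers = NULL,
                       outgroup_tag = "Ptaeda", seed = 1L,
                       reps_single = 10000L, reps_dhew = 50000L, a = 1e-4,
                       bootstrap_reps = 10000L, ci_level = 0.95,
                       include_monomorphic = TRUE) {
  stopifnot(file.exists(manifest), reps_single >= 1, reps_dhew >= 1,
            a > 0, a < 1, bootstrap_reps >= 1,
            ci_level > 0, ci_level < 1)
  structure(list(manifest = manifest, out_dir = out_dir,
                 annotations = annotations, primers = primers,
                 outgroup_tag = outgroup_tag, seed = as.integer(seed),
                 reps_single = as.integer(reps_single),
                 reps_dhew = as.integer(reps_dhew), a = a,
                 bootstrap_reps = as.integer(bootstrap_reps),
                 ci_level = ci_level,
                 include_monomorphic = include_monomorphic),
            class = "run_config")
}

# analyse one gene; returns list(diversity=, neutrality=, outlier=, log=)
process_gene <- function(row, cfg, coding = NULL, primer = NULL) {
  gene_id <- row$gene_id
  gseed <- derive_seed(cfg$seed, gene_id)
  fa <- file.path(dirname(cfg$manifest), row$file)
  primer_intervals <- NULL
  if (!is.null(primer) && nrow(primer) == 1L) {
    primer_intervals <- list(fwd = c(primer$fwd_start, primer$fwd_end),
                             rev = c(primer$rev_start, primer$rev_end))
  }
  aln <- read_gene_fasta(fa, cfg$outgroup_tag, gene_id = gene_id,
                         species = row$species, category = row$category,
                         primer_intervals = primer_intervals)
  aln <- mask_primers(aln)
  f <- filter_sites(aln)
  consensus <- if (nrow(aln$outgroup) > 0L && f$L > 0L)
    outgroup_consensus(f) else NULL
  ann <- NULL
  if (!is.null(coding) && nrow(coding) > 0L && f$L > 0L) {
    ann <- classify_sites(f, coding, aln = aln)
  }
  gd <- if (f$L > 0L) gene_diversity(f, consensus, ann, aln = aln) else NULL

  pick <- function(v, nm) {
    if (is.null(v) || is.null(v[[nm]]) || length(v[[nm]]) == 0) NA_real_ else
      as.numeric(v[[nm]])
  }
  pcat <- function(nm) {
    if (is.null(gd) || is.null(gd$pi_by_category)) NA_real_ else
      unname(gd$pi_by_category[nm])
  }
  tcat <- function(nm) {
    if (is.null(gd) || is.null(gd$thetaw_by_category)) NA_real_ else
      unname(gd$thetaw_by_category[nm])
  }
  div_row <- data.frame(
    gene_id = gene_id, species = row$species, category = row$category,
    n = aln$n, L = f$L, S = if (is.null(gd)) NA_integer_ else gd$S,
    theta_pi = pick(gd, "theta_pi"), theta_w = pick(gd, "theta_w"),
    dxy = pick(gd, "dxy"),
    pi_noncoding = pcat("noncoding"), pi_syn = pcat("synonymous"),
    pi_nonsyn = pcat("nonsynonymous"), pi_silent = pcat("silent"),
    thetaw_noncoding = tcat("noncoding"), thetaw_syn = tcat("synonymous"),
    thetaw_nonsyn = tcat("nonsynonymous"), thetaw_silent = tcat("silent"),
    Ka = pick(gd, "Ka"), Ks = pick(gd, "Ks"),
    ratio_pia_pis = pick(gd, "ratio_pia_pis"),
    ratio_ka_ks = pick(gd, "ratio_ka_ks"))

  S <- div_row$S
  nstats <- if (f$L > 0L) neutrality_stats(f, consensus) else NULL
  P <- c(P_D = NA_real_, P_H = NA_real_, P_EW = NA_real_, P_Zns = NA_real_)
  theta_locus <- if (f$L > 0L && !is.na(div_row$theta_pi))
    div_row$theta_pi * f$L else 0
  if (!is.null(nstats) && !is.na(S) && S >= 1L && theta_locus > 0) {
    nulls <- null_stat_matrix(aln$n, theta_locus, cfg$reps_single,
                              seed = derive_seed(cfg$seed,
                                                 paste0(gene_id, "/null")))
    P["P_D"] <- empirical_pvalue(nstats$D, nulls[, "D"], "lower")
    P["P_H"] <- empirical_pvalue(nstats$H, nulls[, "H"], "lower")
    P["P_EW"] <- empirical_pvalue(nstats$F, nulls[, "F"], "lower")
    P["P_Zns"] <- empirical_pvalue(nstats$Zns, nulls[, "Zns"], "lower")
  }
  neut_row <- data.frame(
    gene_id = gene_id, S = S,
    D = pick(nstats, "D"), H = pick(nstats, "H"),
    F = pick(nstats, "F"), Zns = pick(nstats, "Zns"),
    P_D = P[["P_D"]], P_H = P[["P_H"]], P_EW = P[["P_EW"]],
    P_Zns = P[["P_Zns"]])

  if (!is.na(S) && S >= 2L &&
      !anyNA(c(P[["P_D"]], P[["P_H"]], P[["P_EW"]]))) {
    cal <- calibrate_pstar(aln$n, theta_locus, a = cfg$a,
                           reps = cfg$reps_dhew,
                           seed = derive_seed(cfg$seed,
                                              paste0(gene_id, "/dhew")))
    dh <- dhew_test(list(gene_id = gene_id, S = S, P_D = P[["P_D"]],
                         P_H = P[["P_H"]], P_EW = P[["P_EW"]]), cal)
  } else {
    dh <- dhew_test(list(gene_id = gene_id, S = S, P_D = P[["P_D"]],
                         P_H = P[["P_H"]], P_EW = P[["P_EW"]]), NA_real_)
  }
  out_row <- data.frame(
    gene_id = gene_id, species = row$species, category = row$category,
    S = S, P_D = P[["P_D"]], P_H = P[["P_H"]], P_EW = P[["P_EW"]],
    P_Zns = P[["P_Zns"]], P_star = dh$P_star,
    outlier = dh$outlier, excluded = dh$excluded, reason = dh$reason)

  log_row <- data.frame(gene_id = gene_id, n = aln$n, L = f$L, S = S,
                        seed = gseed, status = "ok", message = "")
  list(diversity = div_row, neutrality = neut_row, outlier = out_row,
       log = log_row)
}

#' Run the full analysis over a study manifest
#'
#' Orchestrates read, primer masking, site filtering, annotation,
#' diversity/divergence estimation, the four neutrality tests against
#' per-gene coalescent nulls (conditioned on the gene's observed
#' theta_pi), the DHEW outlier decision with per-gene calibrated P*, and
#' species x category bootstrap summaries. Per-gene failures are logged
#' and skipped; the run aborts only on manifest/config errors. Identical
#' seed and config give byte-identical output tables.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a list of the five tables; written to
#'   `cfg$out_dir` as `diversity.tsv`, `neutrality.tsv`, `outliers.tsv`,
#'   `species_summary.tsv` and `run_log.tsv` (plus `run_info.tsv` with
#'   seed and versions)
#' @export
run_study <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  manifest <- utils::read.delim(cfg$manifest, stringsAsFactors = FALSE)
  stopifnot(all(c("gene_id", "species", "category", "file") %in%
                  names(manifest)))
  annos <- if (!is.null(cfg$annotations))
    utils::read.delim(cfg$annotations, stringsAsFactors = FALSE) else NULL
  primers <- if (!is.null(cfg$primers))
    utils::read.delim(cfg$primers, stringsAsFactors = FALSE) else NULL

  divs <- list(); neuts <- list(); outs <- list(); logs <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    coding <- if (!is.null(annos)) annos[annos$gene_id == row$gene_id, ] else
      NULL
    primer <- if (!is.null(primers))
      primers[primers$gene_id == row$gene_id, ] else NULL
    res <- tryCatch(
      process_gene(row, cfg, coding = coding, primer = primer),
      error = function(e) {
        list(log = data.frame(gene_id = row$gene_id, n = NA_integer_,
                              L = NA_integer_, S = NA_integer_,
                              seed = derive_seed(cfg$seed, row$gene_id),
                              status = "skipped",
                              message = conditionMessage(e)))
      })
    if (!is.null(res$diversity)) {
      divs[[row$gene_id]] <- res$diversity
      neuts[[row$gene_id]] <- res$neutrality
      outs[[row$gene_id]] <- res$outlier
    }
    logs[[row$gene_id]] <- res$log
  }
  diversity <- do.call(rbind, divs)
  neutrality <- do.call(rbind, neuts)
  outliers <- do.call(rbind, outs)
  run_log <- do.call(rbind, logs)
  summary <- species_summary(diversity, cfg)

  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  write_tsv(diversity, file.path(cfg$out_dir, "diversity.tsv"))
  write_tsv(neutrality, file.path(cfg$out_dir, "neutrality.tsv"))
  write_tsv(outliers, file.path(cfg$out_dir, "outliers.tsv"))
  write_tsv(summary, file.path(cfg$out_dir, "species_summary.tsv"))
  write_tsv(run_log, file.path(cfg$out_dir, "run_log.tsv"))
  write_tsv(data.frame(
    key = c("seed", "reps_single", "reps_dhew", "a", "bootstrap_reps",
            "ci_level", "package_version", "r_version"),
    value = c(cfg$seed, cfg$reps_single, cfg$reps_dhew, cfg$a,
              cfg$bootstrap_reps, cfg$ci_level,
              as.character(utils::packageVersion("dhewscan")),
              paste(R.version$major, R.version$minor, sep = "."))),
    file.path(cfg$out_dir, "run_info.tsv"))
  invisible(list(diversity = diversity, neutrality = neutrality,
                 outliers = outliers, species_summary = summary,
                 run_log = run_log))
}

# species x category bootstrap summary table
species_summary <- function(diversity, cfg) {
  if (is.null(diversity) || nrow(diversity) == 0L) {
    return(data.frame())
  }
  rows <- list()
  for (sp in sort(unique(diversity$species))) {
    for (cat in sort(unique(diversity$category))) {
      d <- diversity[diversity$species == sp & diversity$category == cat, ]
      if (nrow(d) == 0L) next
      poly <- sum(!is.na(d$S) & d$S > 0)
      base <- data.frame(species = sp, category = cat, n_genes = nrow(d),
                         percent_polymorphic = percent(poly, nrow(d), 2))
      for (stat in c("S", "theta_pi", "theta_w", "dxy")) {
        vals <- d[[stat]]
        if (!cfg$include_monomorphic) vals <- vals[!is.na(d$S) & d$S > 0]
        bs <- bootstrap_mean_ci(
          vals, reps = cfg$bootstrap_reps, level = cfg$ci_level,
          seed = derive_seed(cfg$seed, paste("boot", sp, cat, stat)),
          statistic_name = stat, species = sp)
        base[[paste0(stat, "_mean")]] <- bs$mean
        base[[paste0(stat, "_sd")]] <- if (bs$n_loci > 1)
          stats::sd(vals, na.rm = TRUE) else NA_real_
        base[[paste0(stat, "_ci_low")]] <- bs$ci_low
        base[[paste0(stat, "_ci_high")]] <- bs$ci_high
      }
      rows[[paste(sp, cat)]] <- base
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Outlier proportions per species and gene category
#'
#' Percentage of outlier genes (half-up, 2 decimals). Either give two
#' counts, or an outlier table (as produced by [run_study()]) whose
#' non-excluded genes are aggregated by species and category.
#'
#' @param outliers number of outlier genes, or a data.frame with columns
#'   `species`, `category`, `outlier`
#' @param total total number of genes (scalar; only with count input)
#' @return a percentage, or a data.frame `species`, `category`, `n_genes`,
#'   `n_outliers`, `percent_outliers`
#' @examples
#' summarize_outliers(7, 171)  # 4.09
#' summarize_outliers(3, 190)  # 1.58
#' @export
summarize_outliers <- function(outliers, total = NULL) {
  if (is.numeric(outliers)) {
    stopifnot(!is.null(total))
    return(percent(outliers, total, 2))
  }
  stopifnot(is.data.frame(outliers))
  rows <- list()
  for (sp in sort(unique(outliers$species))) {
    for (cat in sort(unique(outliers$category))) {
      d <- outliers[outliers$species == sp & outliers$category == cat, ]
      if (nrow(d) == 0L) next
      k <- sum(!is.na(d$outlier) & d$outlier)
      rows[[paste(sp, cat)]] <- data.frame(
        species = sp, category = cat, n_genes = nrow(d), n_outliers = k,
        percent_outliers = percent(k, nrow(d), 2))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
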