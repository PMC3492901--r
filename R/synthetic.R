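#' Specification for one synthetic gene
#'
#' Defaults describe a typical amplicon of the study design this generator
#' emulates: a few haploid megagametophyte sequences per gene (3-12),
#' ~380-400 bp amplicons, per-site diversity around 0.001-0.01, an
#' outgroup at 0.01-0.09 substitutions/site, mixed coding/noncoding
#' structure, and low rates of injected data defects (missing bases, indel
#' columns, triallelic columns) to exercise the site filters.
#'
#' @param gene_id,species,category identifiers
#' @param n haploid sample size (>= 2; >= 3 needed for triallelic defects)
#' @param L alignment length in bp
#' @param theta_site per-site population mutation rate
#' @param outgroup_divergence substitution rate on the outgroup branch
#'   from the ingroup root (substitutions/site); the realized ingroup-
#'   outgroup Dxy exceeds this by roughly `theta_site * (1 - 1/n)` of
#'   within-ingroup coalescent depth
#' @param coding_fraction fraction of the amplicon covered by a single
#'   central coding interval (trimmed to whole codons)
#' @param frame reading-frame offset of that interval
#' @param defect_rates named numeric vector with per-column injection
#'   rates `missing_col`, `indel_col`, `triallelic_col` (each in \[0,1\])
#' @param scenario `"neutral"` (standard coalescent) or `"star_sweep"`
#'   (near-star post-sweep caricature; see [generate_gene()])
#' @param seed integer seed
#' @return object of class `synthetic_gene_spec`
#' @export
synthetic_gene_spec <- function(gene_id = "gene1", species = "speciesA",
                                category = "candidate",
                                n = 6L, L = 400L, theta_site = 0.005,
                                outgroup_divergence = 0.05,
                                coding_fraction = 0.6, frame = 0L,
                                defect_rates = c(missing_col = 0,
                                                 indel_col = 0,
                                                 triallelic_col = 0),
                                scenario = c("neutral", "star_sweep"),
                                seed = 1L) {
  scenario <- match.arg(scenario)
  stopifnot(n >= 2, L >= 30, theta_site > 0, outgroup_divergence >= 0,
            coding_fraction >= 0, coding_fraction <= 1,
            all(defect_rates >= 0), all(defect_rates <= 1))
  for (nm in c("missing_col", "indel_col", "triallelic_col")) {
    if (!nm %in% names(defect_rates)) defect_rates[nm] <- 0
  }
  structure(list(gene_id = gene_id, species = species, category = category,
                 n = as.integer(n), L = as.integer(L),
                 theta_site = theta_site,
                 outgroup_divergence = outgroup_divergence,
                 coding_fraction = coding_fraction, frame = as.integer(frame),
                 defect_rates = defect_rates, scenario = scenario,
                 seed = as.integer(seed)),
            class = "synthetic_gene_spec")
}

# Near-star sweep caricature: n-1 lineages coalesce at t_tip (2N units),
# the resulting clade joins the one escaped lineage at t_tip + t_int. The
# long internal branch puts derived alleles at frequency n-1 (strongly
# negative H), the near-identical clade haplotypes push F up, and the
# escape/tip singletons keep Tajima's D negative -- the joint DHEW
# signature. A literal star genealogy produces only singletons and has
# none of the F or H signal.
star_sweep_replicate <- function(n, theta_locus, t_tip = 0.05, t_int = 1.0) {
  stopifnot(n >= 3)
  seg_members <- c(as.list(seq_len(n - 1L)),      # clade tips
                   list(n),                       # escaped lineage
                   list(seq_len(n - 1L)))         # internal clade branch
  seg_len <- c(rep(t_tip, n - 1L), t_tip + t_int, t_int)
  total_len <- sum(seg_len)
  S <- stats::rpois(1L, theta_locus / 2 * total_len)
  mat <- matrix(0L, nrow = n, ncol = S)
  if (S > 0L) {
    hit <- sample.int(length(seg_len), S, replace = TRUE, prob = seg_len)
    for (s in seq_len(S)) mat[seg_members[[hit[s]]], s] <- 1L
  }
  structure(list(n = n, times = c(t_tip, t_int), tmrca = t_tip + t_int,
                 total_branch_length = total_len, S = S, matrix = mat,
                 counts = if (S > 0L) colSums(mat) else integer(0),
                 positions = sort(stats::runif(S))),
            class = "coal_replicate")
}

BASES <- c("A", "C", "G", "T")

#' Generate one synthetic gene alignment with truth record
#'
#' Draws a coalescent genealogy (standard neutral, or the near-star sweep
#' caricature for `scenario = "star_sweep"`), maps its infinite-sites
#' mutations onto distinct columns of a uniform random base sequence
#' (Jukes-Cantor: the derived base is uniform over the three others), adds
#' an outgroup sequence derived from the ingroup root by Poisson
#' substitutions, and injects column defects at the configured rates into
#' previously monomorphic columns (disjointly, so the truth record maps
#' one-to-one onto filter removals).
#'
#' @param spec a [synthetic_gene_spec()]
#' @return list with `aln` (a `gene_alignment`), `coding` (annotation
#'   data.frame `gene_id`, `start`, `end`, `frame`, 0-based half-open) and
#'   `truth` (list: `theta_site`, `S_true`, `variant_columns` (0-based),
#'   `derived_base`, `ancestral_base`, `derived_count`, per-type injected
#'   defect columns, `scenario`)
#' @export
generate_gene <- function(spec) {
  set.seed(spec$seed)
  n <- spec$n; L <- spec$L
  theta_locus <- spec$theta_site * L
  rep <- if (spec$scenario == "star_sweep") {
    star_sweep_replicate(n, theta_locus)
  } else {
    simulate_replicate(n, theta_locus)
  }
  S <- min(rep$S, L %/% 2L)    # truncate pathological draws, keep defects room
  pos <- sort(sample.int(L, S))
  anc <- sample(BASES, L, replace = TRUE)
  mat <- matrix(rep(anc, each = n), nrow = n)
  derived_base <- character(S)
  for (s in seq_len(S)) {
    db <- sample(setdiff(BASES, anc[pos[s]]), 1L)
    derived_base[s] <- db
    mat[rep$matrix[, s] == 1L, pos[s]] <- db
  }
  og <- anc
  K <- min(stats::rpois(1L, spec$outgroup_divergence * L), L)
  og_pos <- if (K > 0L) sort(sample.int(L, K)) else integer(0)
  for (p in og_pos) og[p] <- sample(setdiff(BASES, og[p]), 1L)

  # defect injection into monomorphic, not-yet-defective columns
  pool <- setdiff(seq_len(L), pos)
  draw_cols <- function(rate) {
    k <- min(stats::rbinom(1L, L, rate), length(pool))
    if (k == 0L) return(integer(0))
    cols <- sample(pool, k)
    pool <<- setdiff(pool, cols)
    sort(cols)
  }
  miss_cols <- draw_cols(spec$defect_rates[["missing_col"]])
  indel_cols <- draw_cols(spec$defect_rates[["indel_col"]])
  tri_cols <- if (n >= 3L) draw_cols(spec$defect_rates[["triallelic_col"]]) else
    integer(0)
  for (p in miss_cols) mat[sample.int(n, 1L), p] <- "N"
  for (p in indel_cols) mat[sample.int(n, 1L), p] <- "-"
  for (p in tri_cols) {
    others <- setdiff(BASES, mat[1L, p])
    mat[1L, p] <- others[1L]
    mat[2L, p] <- others[2L]
  }

  rownames(mat) <- sprintf("%s|%s|h%02d", spec$species, spec$gene_id,
                           seq_len(n))
  out <- matrix(og, nrow = 1L,
                dimnames = list(sprintf("Ptaeda|%s", spec$gene_id), NULL))
  aln <- gene_alignment(mat, out, gene_id = spec$gene_id,
                        species = spec$species, category = spec$category)

  coding_len <- (floor(L * spec$coding_fraction) %/% 3L) * 3L
  coding <- if (coding_len >= 3L) {
    start <- (L - coding_len) %/% 2L
    data.frame(gene_id = spec$gene_id, start = start,
               end = start + coding_len, frame = spec$frame)
  } else {
    data.frame(gene_id = character(0), start = integer(0), end = integer(0),
               frame = integer(0))
  }
  truth <- list(gene_id = spec$gene_id, theta_site = spec$theta_site,
                outgroup_divergence = spec$outgroup_divergence,
                S_true = S, variant_columns = pos - 1L,
                ancestral_base = anc[pos], derived_base = derived_base,
                derived_count = if (S > 0L) colSums(rep$matrix[, seq_len(S), drop = FALSE]) else integer(0),
                missing_cols = miss_cols - 1L,
                indel_cols = indel_cols - 1L,
                triallelic_cols = tri_cols - 1L,
                outgroup_sub_cols = og_pos - 1L,
                scenario = spec$scenario)
  list(aln = aln, coding = coding, truth = truth)
}

#' Generate a reproducible multi-species synthetic study
#'
#' Emulates the layout of a multi-species candidate-gene resequencing
#' study: for each species and gene category, per-gene parameters are
#' drawn uniformly from the configured ranges and the gene is written as
#' an aligned FASTA (ingroup plus one `Ptaeda`-tagged outgroup row),
#' together with an annotation table, a manifest and a truth table. The
#' whole tree is a deterministic function of the master seed.
#'
#' @param config list with elements `species` (character vector),
#'   `genes_per_category` (named c(candidate=, control=)), `n_range`,
#'   `L_range`, `theta_range`, `div_range`, `coding_fraction`,
#'   `defect_rates`, `sweep_fraction` (fraction of candidate genes
#'   simulated under the sweep caricature, default 0) and `seed`; missing
#'   elements fall back to study-shaped defaults
#' @param out_dir output directory (created); FASTA files under `fasta/`,
#'   plus `manifest.tsv`, `annotations.tsv`, `truth.tsv`
#' @return the manifest data.frame, invisibly
#' @export
generate_study <- function(config, out_dir) {
  cfg <- utils::modifyList(list(
    species = c("Aalba", "Ldecidua", "Pcembra", "Pmugo"),
    genes_per_category = c(candidate = 10L, control = 6L),
    n_range = c(3L, 12L), L_range = c(380L, 401L),
    theta_range = c(0.001, 0.01), div_range = c(0.01, 0.09),
    coding_fraction = 0.6,
    defect_rates = c(missing_col = 0.02, indel_col = 0.01,
                     triallelic_col = 0.01),
    sweep_fraction = 0, seed = 1L
  ), config)
  dir.create(file.path(out_dir, "fasta"), recursive = TRUE,
             showWarnings = FALSE)
  manifest <- list(); annos <- list(); truths <- list()
  for (sp in cfg$species) {
    for (cat in names(cfg$genes_per_category)) {
      for (g in seq_len(cfg$genes_per_category[[cat]])) {
        gene_id <- sprintf("%s_%s_%03d", sp, substr(cat, 1, 4), g)
        gseed <- derive_seed(cfg$seed, gene_id)
        set.seed(gseed)
        scenario <- if (cat == "candidate" &&
                        stats::runif(1) < cfg$sweep_fraction) "star_sweep" else
          "neutral"
        spec <- synthetic_gene_spec(
          gene_id = gene_id, species = sp, category = cat,
          n = sample(seq.int(cfg$n_range[1], cfg$n_range[2]), 1L),
          L = sample(seq.int(cfg$L_range[1], cfg$L_range[2]), 1L),
          theta_site = stats::runif(1, cfg$theta_range[1], cfg$theta_range[2]),
          outgroup_divergence = stats::runif(1, cfg$div_range[1],
                                             cfg$div_range[2]),
          coding_fraction = cfg$coding_fraction,
          defect_rates = cfg$defect_rates,
          scenario = scenario,
          seed = derive_seed(gseed, "gene")
        )
        gen <- generate_gene(spec)
        fa <- file.path(out_dir, "fasta", paste0(gene_id, ".fa"))
        write_gene_fasta(gen$aln, fa)
        manifest[[gene_id]] <- data.frame(
          gene_id = gene_id, species = sp, category = cat,
          file = file.path("fasta", paste0(gene_id, ".fa")),
          n = spec$n, seed = spec$seed)
        annos[[gene_id]] <- gen$coding
        tr <- gen$truth
        truths[[gene_id]] <- data.frame(
          gene_id = gene_id, species = sp, category = cat,
          scenario = tr$scenario, n = spec$n, L = spec$L,
          theta_site = tr$theta_site,
          outgroup_divergence = tr$outgroup_divergence, S_true = tr$S_true,
          variant_columns = paste(tr$variant_columns, collapse = ","),
          missing_cols = paste(tr$missing_cols, collapse = ","),
          indel_cols = paste(tr$indel_cols, collapse = ","),
          triallelic_cols = paste(tr$triallelic_cols, collapse = ","))
      }
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  write_tsv(manifest, file.path(out_dir, "manifest.tsv"))
  write_tsv(do.call(rbind, annos), file.path(out_dir, "annotations.tsv"))
  write_tsv(do.call(rbind, truths), file.path(out_dir, "truth.tsv"))
  invisible(manifest)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
}
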