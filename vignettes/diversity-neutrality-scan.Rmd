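---
title: "Candidate-gene diversity and the DHEW neutrality scan: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Candidate-gene diversity and the DHEW neutrality scan: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dhewscan)
```

## The problem

Candidate-gene resequencing studies in conifers sequence a few hundred
amplicons (roughly 300-450 bp each) across a small sample of haploid
megagametophytes — one meiotic product per tree, so the data are phased by
construction and carry no heterozygous base calls. For each gene one asks:
how much nucleotide variation is there, how divergent is the species from
an outgroup, and does the pattern of variation depart from the standard
neutral model (SNM) in the direction expected after a selective sweep?
`dhewscan` implements that whole per-gene analysis: site filtering,
diversity and divergence estimation with synonymous/nonsynonymous
partitioning, four neutrality statistics with coalescent-simulated null
distributions, the compound DHEW outlier test, and across-locus bootstrap
comparisons of species means.

## Site filtering

All statistics operate on a filtered site matrix (`filter_sites()`). A
column is removed when any ingroup row carries a gap, an N or any other
ambiguity code (ambiguities are treated as missing, not as errors, because
haploid tissue cannot produce genuine heterozygous calls), or when the
ingroup carries more than two alleles — a violation of the infinite-sites
mutation model that underlies every estimator used here. Outgroup
characters never remove a column: an unresolved outgroup only makes that
site unusable for polarization and divergence. Primer-annealing flanks can
be masked beforehand (`mask_primers()`); masked columns are logged under
their own reason so the removal log partitions the original columns
exactly. Filtering is idempotent, and every retained column is complete
and at most biallelic, which is what makes the downstream haplotype-based
statistics (Ewens-Watterson F, Kelly's ZnS) well defined without any
missing-data policy.

Coordinates are 0-based and half-open everywhere (alignment column 1 is
index 0), including the primer and annotation interval files.

## Diversity and divergence

For a sample of $n$ sequences and $L$ retained sites with $S$ segregating
sites:

* $\theta_\pi$ — mean pairwise difference, $\sum_{i<j} d_{ij} / \binom{n}{2}$,
  per site. The unbiased pairwise-average form is used, matching the
  definition "average pairwise difference between sequences".
* $\theta_W = S / (a_1 L)$ with $a_1 = \sum_{i=1}^{n-1} 1/i$.
* $D_{xy}$ — divergence to the outgroup, computed row-by-row against a
  majority-rules outgroup consensus and averaged over ingroup rows (this
  uses all sampled sequences rather than reducing the ingroup to a second
  consensus). Columns where the consensus is N (tie or missing) are
  excluded and the denominator renormalized to the usable sites; whether
  such sites should instead count toward the denominator is not decidable
  from first principles, and the renormalizing choice keeps $D_{xy}$
  unbiased per usable site.

Coding positions are classified from user-supplied coding intervals with
frame (`classify_sites()`); no homology search is performed. A polymorphic
coding site is synonymous only if every segregating allele leaves the
amino acid unchanged in its codon context (the ingroup majority
consensus). Codons carrying several segregating sites are resolved by
enumerating mutational pathways — two orderings for two sites, six for
three — excluding pathways through stop codons; a site is labelled
synonymous only when every pathway step at that site is synonymous.
Monomorphic coding positions are apportioned fractionally in the
Nei-Gojobori style: position $k$ of a codon contributes (number of
synonymous single-base changes)/3 to the synonymous site count and the
complement to the nonsynonymous count, with changes to stop codons counted
as nonsynonymous. Codons with unknowable context (no data at a position,
truncation by the interval edge, or an internal stop in the consensus) are
flagged `mixed_excluded` and dropped from all category totals. This
counting is deliberately the classical Nei-Gojobori (1986) scheme; tools
built on the Comeron counting can differ in the second decimal of site
totals, which is accepted.

Per-category diversity divides the pairwise differences at a category's
polymorphic sites by the category's fractional site count; `silent` pools
noncoding and synonymous sites. $K_a$ and $K_s$ count
ingroup-consensus-versus-outgroup-consensus coding differences with the
same pathway averaging, divided by the fractional nonsynonymous and
synonymous site totals. Ratios with zero denominators are NA, and the raw
numerators and denominators are returned alongside, because small
synonymous denominators make $K_a/K_s$ spectacularly unstable on single
amplicons. No multiple-hit correction is applied to any divergence; at the
divergences this design targets (up to ~0.09 substitutions/site)
saturation is negligible.

## Neutrality statistics

* **Tajima's D** — $(\theta_{\pi,\mathrm{locus}} - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}$
  with the 1989 variance constants. Undefined at $S = 0$.
* **Fay & Wu's normalized H** — computed on the unfolded spectrum after
  polarization against the outgroup consensus: a segregating site is
  polarizable when the consensus matches one ingroup allele; consensus N
  or a third allele sends the site to the unpolarized pool. The numerator
  is $\theta_\pi - \theta_L$ with
  $\theta_L = \frac{1}{n-1}\sum_i i\,S_i$, both restricted to polarizable
  sites, normalized by the Zeng et al. (2006) variance with
  $\hat\theta = S/a_1$ and $\hat{\theta^2} = S(S-1)/(a_1^2 + a_2)$.
* **Ewens-Watterson F** — haplotype homozygosity $\sum_k p_k^2$ over the
  distinct rows of the filtered matrix; $F \in [1/n, 1]$.
* **Kelly's ZnS** — mean $r^2$ over all pairs of segregating sites.

Empirical P-values come from neutral coalescent simulation at the gene's
own $(n, \theta)$. All four are reported lower-tail,
$P = (\#\{x_{\mathrm{sim}} \le x_{\mathrm{obs}}\} + 1)/(R + 1)$: a
sweep-like gene therefore shows small $P_D$ and $P_H$ but $P_{EW}$ *near
1*, since excess homozygosity sits in F's upper tail. The +1/+1 estimator
never returns 0; an observation beyond all 10,000 replicates reports
1/10,001, the "< 0.0001" of a full-scale run.

## The coalescent null

`simulate_replicate()` implements the standard neutral coalescent: with
$k$ lineages the waiting time to the next merger is exponential with rate
$k(k-1)/2$ in units of $2N$ generations, a uniformly random pair merges,
and mutations fall on the genealogy as a Poisson process of rate
$\theta_{\mathrm{locus}}/2$ per unit branch length under infinite sites
(every mutation a new column). This gives $E[S] = \theta_{\mathrm{locus}} a_1$,
so $\theta_{\mathrm{locus}}$ has exactly the meaning of `ms -t` (that is,
$4N\mu$ per locus). Nulls contain no recombination, which is conservative
for ZnS.

Nulls are conditioned on the observed diversity by setting
$\theta_{\mathrm{locus}} = \hat\theta_\pi \times L$ for each gene — the
closest literal reading of simulating "conditional on the SNM and the
observed $\theta_\pi$" — rather than fixing $S$. H is evaluated on
simulated replicates with perfect polarization (the simulator's 0 state is
ancestral by construction), so the null ignores polarization error; the
misdirection rate from outgroup substitutions is about one third of the
outgroup divergence per polymorphic site, negligible against the
simulation noise at 10,000 replicates but worth remembering at high
divergence.

Every stochastic step derives its seed from the run's master seed and a
string key (`derive_seed()`), so a whole run is byte-reproducible and any
single gene can be replayed in isolation. The derivation ends in three
Lehmer-multiplier steps because near-identical keys otherwise produce
nearly consecutive seeds, and Mersenne-Twister started from consecutive
seeds yields correlated first draws.

## The DHEW compound test

The compound test rejects neutrality only when Tajima's D, normalized H
and the Ewens-Watterson test are *jointly* significant: $P_D \le P^*$,
$P_H \le P^*$ and $1 - P_{EW} \le P^*$, the all-components construction of
Zeng et al. (2007), with the EW component pointed at homozygosity excess
(the sweep-sensitive direction). Because the three statistics are
correlated, the per-component level $P^*$ giving a joint type-I error $a$
must be found by simulation (`calibrate_pstar()`): simulate a calibration
set of replicates at the gene's $(n, \theta)$, compute each replicate's
three component P-values against an *independently seeded* reference set
of the same size (independence avoids the optimism of self-ranking), form
the joint exceedance $q = \max(P_D, P_H, 1 - P_{EW})$, and take the
largest threshold whose empirical rejection fraction stays at or below
$a$. $P^*$ is floored at $\max(a,\ 1/(\mathrm{reps}+1))$: the joint
probability of three events can never be below a single event's
probability, and levels beneath the simulation resolution are not
estimable (a target $a < 1/\mathrm{reps}$ warns). Genes with one SNP are
excluded outright — at $S \le 1$ the statistics are degenerate and the
test produces false positives — as is any gene with an unavailable
component.

Study-scale defaults are $a = 10^{-4}$ with 50,000 calibration
replicates and 10,000 single-statistic replicates; those sit at the
resolution floor by design. The package's own verification runs the same
machinery at desk scale — $a = 0.05$, 4,000 calibration replicates, 2,000
fresh test genes — where the binomial error of the realized type-I rate is
small enough to be informative.

## Across-locus bootstrap

Species means of $S$, $\theta_\pi$, $\theta_W$ and $D_{xy}$ get percentile
bootstrap intervals from resampling loci with replacement (10,000
replicates by default, via the `boot` package). Percentile intervals are
the simplest method consistent with comparing "95% bootstrap confidence
intervals", and two species are called different only when the closed
intervals fail to overlap — touching endpoints count as overlap, the
conservative reading. Monomorphic genes enter the means as zeros by
default (total gene counts, not polymorphic counts, are the natural
denominators), with a flag to drop them instead.

## The synthetic study generator

`generate_gene()` and `generate_study()` produce study-shaped inputs:
3-12 haploid sequences, 380-401 bp, per-site $\theta$ 0.001-0.01, an
outgroup at 0.01-0.09 substitutions/site, 60% coding, and injected
missing/indel/triallelic columns at low rates to exercise the filters.
Base composition is uniform and mutation is Jukes-Cantor (uniform target
base), the simplest model consistent with infinite-sites statistics.
`outgroup_divergence` parameterizes the outgroup branch from the ingroup
root, so realized $D_{xy}$ runs about $\theta_{\mathrm{site}}(1 - 1/n)$
higher (the within-ingroup coalescent depth). Outgroup substitutions may
land on polymorphic columns, deliberately exercising the unpolarizable and
misdirected-polarization paths. Defects are injected into distinct,
previously monomorphic columns so the truth record maps one-to-one onto
the filter's removal log.

The sweep scenario is a near-star genealogy: $n-1$ tips coalesce almost
immediately (tip length 0.05 in $2N$ units) and join the one escaped
lineage at depth 1.05. A *literal* star tree was considered and rejected:
it produces only singletons, which drives Tajima's D down but leaves every
haplotype distinct (F minimal) and the H numerator positive — a population
expansion caricature, not a sweep, and one the DHEW test is built *not* to
reject. The near-star version puts many derived alleles at frequency
$n-1$ (H strongly negative), leaves the clade nearly haplotype-identical
(F high) and keeps singletons on the long escape branch (D negative),
which is the joint signature the compound test targets; at $n = 12$,
$\theta = 5$ it is rejected in about 90% of runs at $a = 0.05$.

What passing tests on this generator do *not* show: robustness to
demography (no growth, bottlenecks or structure are simulated — the null
and the generator are both SNM), to recombination, to base-composition
bias, to alignment error, or to real primer/paralog artifacts. The
generator validates the estimators and the decision machinery, not the
biological interpretation of outliers.

## Numerical choices and degenerate inputs

* Percentages round half-up (`percent()`), not banker's rounding.
* Outgroup consensus ties give N; ingroup consensus ties break to the
  alphabetically first base (deterministic, documented).
* Genes with $n < 2$ or $L = 0$ are reported with NA statistics, never
  silently dropped; $S = 0$ gives $\theta_\pi = \theta_W = 0$ but NA
  neutrality tests.
* Constant or single-locus bootstrap inputs collapse the interval onto
  the point estimate.
* Oracle comparisons in the test suite use tolerance $10^{-9}$ on the
  worked 4x10 matrix; fractional site-count identities hold to $10^{-9}$.
* The SFS check uses per-class z-tests with across-replicate standard
  errors (Bonferroni at 0.01) rather than a pooled chi-square: sites
  within a replicate share one genealogy, so pooled counts are
  overdispersed and a multinomial chi-square rejects even an exact
  simulator.

## Verification scale

The shipped tests and the acceptance script run at sizes chosen to make
each check statistically meaningful at desk scale: 500 synthetic genes
($n = 12$, $L = 400$, $\theta = 0.005$) for estimator recovery within 5%;
5,000 replicates for neutral centering of D and H; 20,000 replicates for
the $E[S] = \theta a_1$ closed form within 2% and the SFS and
branch-length expectations; DHEW calibration at $a = 0.05$ with 4,000
calibration replicates against 2,000 fresh genes (99% binomial band);
1,000 outer datasets for 95% bootstrap coverage in [0.93, 0.97]; and a
two-species synthetic study run twice for byte-identical outputs. The
`analysis/` scripts run the same pipeline end-to-end at 52 genes with
1,000-replicate nulls; scaling to full-study settings is a matter of the
three replicate-count arguments in `run_config()`.

## Known limitations

* The null model is the SNM only; demographic robustness is an argued
  property of the DHEW construction, not something this package tests.
* Minus-strand coding intervals are not supported (amplicons are
  EST-oriented by design).
* The infinite-sites filter discards genuinely multi-allelic biology along
  with artifacts; at conifer diversity levels this is a per-mille effect.
* $K_a/K_s$ on single amplicons is noisy by nature; treat per-gene ratios
  as screening values and rely on the reported raw counts.
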