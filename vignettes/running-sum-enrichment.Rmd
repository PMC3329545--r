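---
title: "Running-sum gene set enrichment for paired body-fluid profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Running-sum gene set enrichment for paired body-fluid profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fluidgsea)
library(dplyr)
set.seed(1)
```

## The analysis problem

fluidgsea analyses paired two-colour expression profiles: a single
hybridisation compares two fluids from the same subject, with one fluid
labelled Cy5 (here, pleural) and the other Cy3 (ascitic). After upstream
normalisation, each probe carries a log-ratio

$$r = \log_2 \frac{\text{Cy5 signal}}{\text{Cy3 signal}},$$

positive when the gene is more abundant in the pleural fluid. There is
one such profile per sample-pair and no replication across subjects, so
the question is not "which genes are significant across a cohort" but
"which *functional gene sets* are coherently shifted within each
sample-pair, and how do those shifts compare across sample-pairs". That
motivates a rank-based enrichment statistic applied per sample, followed
by cross-sample collation.

## The enrichment statistic

All genes are sorted by decreasing log-ratio into a list
$L = \{g_1, \dots, g_N\}$. For a gene set $S$ with $N_S$ members present
in the list, define the running sum over ranks $1 \le i \le N$:

$$f(i) = \frac{\#\{\text{members with rank} \le i\}}{N_S}
       - \frac{\#\{\text{non-members with rank} \le i\}}{N - N_S}.$$

$f$ is a walk that steps up by $1/N_S$ at each member and down by
$1/(N-N_S)$ at each non-member. The enrichment score is its maximum,
$ES(S) = \max_i f(i)$ — the unweighted Kolmogorov–Smirnov-type
statistic. Since $f(N) = 0$, the score always lies in $[0, 1]$ and
equals 1 exactly when the members fill the top $N_S$ ranks. Enrichment
of *down*-regulated genes is measured by the same statistic on the exact
reversal of $L$.

Two properties shape the implementation:

* **Rank dependence only.** $ES$ depends on the member rank positions,
  never on the score magnitudes, so it is invariant under any strictly
  monotone transform of the log-ratios. Internally the score is computed
  in $O(N_S)$ from the sorted member positions $p_1 < \dots < p_{N_S}$
  as $\max_j \, [\, j/N_S - (p_j - j)/(N - N_S) \,]$, because $f$ only
  increases at member positions. The test suite checks this closed form
  against a brute-force evaluation of $f$ at every position.
* **A position-sampling null.** Permuting gene labels uniformly is
  equivalent to placing the $N_S$ members on a uniform random
  $N_S$-subset of rank positions. The permutation p-value is the
  fraction of `n_perm` such draws (default 10,000) whose score
  *strictly* exceeds the observed one. No pseudo-count is added, so
  $p = 0$ is a legal output for a set that beats every permutation; an
  add-one `smooth` option exists for users who prefer the conservative
  estimator. For small lists `exhaustive_null()` enumerates the exact
  null over all $\binom{N}{N_S}$ subsets and anchors the Monte-Carlo
  machinery in the tests.

Because the null depends only on $(N, N_S)$, `rank_gene_sets()` shares
one batch of `n_perm` draws across all sets of equal size by default —
statistically identical to per-set nulls (a test verifies agreement
within Monte-Carlo error) and much faster on collections with thousands
of sets.

## From probes to a ranked list

Arrays measure tens of thousands of probes but the statistic ranks
*genes*, so replicate probes are collapsed per symbol. The collapse
summary is the median by default (robust to a single aberrant probe);
`method = "mean"` is available because deposited gene-level tables may
have used either rule. Per gene, a two-sided one-sample Student's t-test
of the probe log-ratios against zero gives a differential-expression
p-value wherever at least two probes with non-zero spread exist; genes
below `alpha = 0.01` are *flagged* for reporting, but the ranked list
always contains all genes — filtering before ranking would change the
statistic's null.

Ties in log-ratio are broken by stable input order. This is
deterministic and injects no randomness that could bias the permutation
test; with continuous log-ratios ties are rare anyway.

## Gene-set collections

`read_gmt()` parses the standard tab-separated GMT carrier and
`read_gaf()` builds one set per GO identifier from a GAF 2.x annotation
file, using the object-symbol column and excluding NOT-qualified rows.
GO sets are built from **direct annotations only**: propagating
memberships up the ontology graph requires an OBO graph, and the
analysis this package implements used flat category memberships. A
`propagate` hook accepts a user-supplied closure should pre-propagated
analysis be wanted. Identifiers are matched case-sensitively after
whitespace trimming.

Before scoring, `restrict_to_universe()` intersects every set with the
measured genes — $N_S$ must count measured members for $f$ to be well
defined — and drops sets of intersected size below `min_size` (default
3, below which the score grid is too coarse to be informative), above
`max_size`, or equal to the universe size (degenerate). Collection sizes
are therefore data-driven and reported, never assumed.

## A worked example

```{r study}
study <- generate_study(synthetic_config(seed = 1))
genes <- collapse_probes(study$samples[["FC-r"]])
ranked <- rank_genes(genes)
restricted <- restrict_to_universe(study$collection, ranked$gene)
res <- rank_gene_sets(restricted, ranked, n_perm = 1000, seed = 2)
tidy(res) |> filter(direction == "up") |> head(5)
glance(res)
```

```{r mountain, fig.width = 6, fig.height = 3.5}
plot_running_sum(ranked, collection_sets(restricted)[["IMMUNE_1"]],
                 "IMMUNE_1 (planted up)")
```

## The synthetic study design

`generate_study()` emulates a four-sample paired-fluid design so the
whole pipeline is testable without any download:

* four sample-pairs named `Ind-A`, `Ind-B`, `FC-r`, `NFC-r` — an index
  case after and before treatment, a second chylothorax case, and a
  non-chylothorax hydrops control;
* three planted "immune-analogue" sets shifted **up** in `Ind-A`,
  `Ind-B` and `FC-r` and left null in `NFC-r`;
* one "lymphangiogenesis-analogue" set shifted **down** in the untreated
  chylothorax samples (`Ind-B`, `FC-r`) and **up** in `Ind-A` and
  `NFC-r`;
* a focal gene, deliberately excluded from that set's membership (the
  pathway of interest in the motivating study did not contain its focal
  gene), whose true shift follows the set's direction in every sample.

Each gene's true log-ratio is $\mathcal N(0, \sigma_g^2)$, plus
$\pm\delta\sigma_g$ when planted; each of `probes_per_gene` probes adds
$\mathcal N(0, \sigma_p^2)$ replicate noise. Defaults: 2,000 genes
(a desk-scale stand-in for a ~60K-probe array; the statistic is
rank-based, so behaviour transfers across list lengths), 3 probes per
gene, $\sigma_g = 1$, $\sigma_p = 0.2$, $\delta = 2$, 50 sets of sizes
10–60 with the planted sets of size 30, disjoint by default so rank
assertions are clean (real GO sets overlap; an overlap mode is the
natural extension and random background sets may already overlap the
planted ones). Emitted log-ratios are rounded to 6 decimals so a fixed
seed reproduces byte-identical files across platforms.

Gaussian noise on log-ratios is the standard two-colour model, but the
generator deliberately omits dye bias, intensity-dependent variance,
spatial artifacts and correlated probe failure. Passing recovery tests
therefore shows the statistic behaves as designed under its own model,
not that any particular biological dataset will reproduce.

## Cross-sample reporting

`cross_sample_table()` collates per-sample results into rows for sets
ranked in the top `top_k` (default 20) of a direction in at least
`min_samples` (default 2) samples. The published table this layout
mirrors never stated its inclusion rule; these defaults reconstruct it —
every printed rank there is ≤ 20 and every row has ≥ 2 populated cells —
and both knobs are configuration, with the caveat documented here.
`focus_report()` gives the per-sample view of one pathway (the direction
with the larger of the two enrichment scores — a tie resolves to "up"
and is flagged) next to a focal gene's log-ratio and t-test p-value,
with a concordance flag that is true when the gene's sign matches the
pathway's direction.

Ranks within a direction follow **ES descending** by default; ranking by
p-value ascending (`rank_by = "p"`) is provided because printed ranks in
the motivating tables cannot distinguish the two conventions. Tied
scores share the smallest rank.

## Numerical and design choices

* Strictly-greater comparison in the p-value, matching the definition
  "fraction of permutations with *higher* score"; published tables in
  this style print `0.0000e+00` entries, which only an unsmoothed
  estimator produces.
* All randomness flows from one seed per run; the pipeline derives
  per-stage, per-sample substream seeds deterministically, so outputs
  are byte-identical across reruns.
* Degenerate sets ($N_S = 0$ or $N_S = N$ after intersection) are
  refused with an explicit error rather than returning a meaningless
  score; `restrict_to_universe()` removes them up front.
* Probes with missing symbols or non-finite log-ratios are dropped with
  counted warnings so data cleaning is auditable in logs.
* The per-gene t-test operates on replicate probes. Whether the original
  analysis tested replicate probes or a scanner error model is not
  documented; the replicate-probe test is the reproducible choice from
  the data this package consumes.

## Problem sizes used in the checks

The packaged tests and the acceptance script run entirely on synthetic
data: score-oracle and symmetry checks on 1,000 random instances with
$N \le 50$; the exact null at $N = 5$, $N_S = 2$ against 10,000
Monte-Carlo permutations; null calibration on a 220-set, 1,000-gene
all-null study at 400 permutations; planted-set recovery over 50
replicate seeds at $\delta = 2$, set size 30, 2,000 genes and 2,000
permutations; and the full four-sample study at 1,000 permutations.
These sizes make the whole battery run in a few minutes on one core
while keeping every Monte-Carlo tolerance comfortable.

## Limitations

* The statistic is the classic unweighted running sum; the later
  score-weighted variant, phenotype-label permutation, leading-edge
  extraction and cross-set FDR are out of scope.
* GO sets come from direct annotations without ontology propagation
  (see above), so GO term sizes will differ from propagated pipelines.
* With permutation p-values reported per set, multiple-testing control
  across a collection is the user's responsibility; ranks within a
  direction are the primary reporting device.
* Reproducing published numbers from a deposited accession additionally
  requires that accession's processed tables and the era's collection
  versions; `read_series_matrix()` provides the entry point but no
  downloading.
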