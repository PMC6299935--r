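---
title: "Methods and design of exprkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design of exprkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exprkit)
```

exprkit turns a gene-level expression matrix into biological readouts —
quality flags, clusters, differentially expressed gene (DEG) lists, enriched
gene sets, pathway activity profiles and enriched promoter motifs — as a
scriptable library rather than an interactive application. This vignette
explains each method, its assumptions and tunables, the choices made where
the design was genuinely open, and what the simulation-based tests do and do
not establish.

## Pre-processing

Raw RNA-seq counts are filtered, normalised and variance-stabilised before
any exploratory or inferential step.

**Low-expression filter.** A gene is kept when its counts-per-million
(CPM, the count divided by the library total times $10^6$) reaches
`cpm_threshold` in at least `min_samples` samples. Defaults are 0.5 CPM in
at least one sample: permissive enough to retain genes expressed in a
single condition, strict enough to drop the near-zero rows that only add
multiple-testing burden. Filtering happens on the counts scale, after any
identifier conversion and duplicate collapsing, so the filter sees the
final gene universe.

**Started-log transform.** Counts are mapped to $\log_2(\mathrm{CPM} + c)$
with pseudocount $c = 4$ by default. The pseudocount bounds the variance of
low counts (a gene moving from 0 to 1 CPM moves only
$\log_2 5 - \log_2 4 \approx 0.32$) while high expressors sit essentially on
the log2-CPM scale. This is a deliberate, simple variance stabiliser; model
based transforms (rlog/VST-style shrinkage) are intentionally out of scope,
and externally transformed matrices can be supplied directly.

**Skew guard.** Feeding raw counts into correlation- or variance-based
analyses is a common mistake. `detect_skew()` computes the sample skewness
(third standardised moment) of all pooled values; when it exceeds 2 on
non-negative data the pipeline enforces the log transform even if the user
asked for none. The threshold of 2 is a heuristic chosen once: pooled
log-scale expression is roughly symmetric (|skewness| typically < 1) while
pooled raw counts, whose gene means span orders of magnitude, land far
above 2. Constant matrices are defined to have skewness 0.

**Library-size QC.** Systematically different sequencing depth between
sample groups confounds any downstream contrast. `library_size_anova()`
runs a one-way ANOVA of per-sample total counts across the levels of a
design factor and raises a warning below `anova_alpha` = 0.05. Each level
needs at least two samples for a finite F statistic.

## Identifier conversion and species detection

Uploaded matrices arrive with symbols, RefSeq, versioned Ensembl ids, and
so on. Matching against a user-supplied mapping table (TSV: source id,
canonical id, species, id type) is case-insensitive and version-tolerant: a
normalised key lower-cases the id and strips a trailing `.<digits>`.
`detect_species()` ranks species by the number of distinct matched query
ids, ties broken alphabetically (no rule is obviously better; alphabetical
is deterministic). During conversion, a source id mapping to several
canonical ids contributes one row per target, and rows sharing a canonical
id are collapsed to the one with the largest across-sample standard
deviation (sample, $n-1$ denominator), ties broken by input order —
duplicate rows are usually probes or transcript variants, and the most
variable one carries the most analysable signal. Unmatched ids are kept
verbatim by default so that enrichment against a user GMT in the same
namespace still works.

## Exploratory analysis

All EDA operates on the transformed matrix, usually restricted to the
1000–2500 genes with the largest standard deviation (`select_top_variable`,
stable sort).

* **Hierarchical clustering** uses $1 - r$ (Pearson) distance and average
  linkage by default — the standard choice for expression heatmaps, where
  profile shape matters more than level; genes are row-centred first.
  Euclidean distance and other linkages are available. A zero-variance item
  has no defined correlation; its correlations are set to 0 with a warning
  rather than aborting.
* **k-means** runs on row-standardised genes (mean 0, SD 1) with a fixed
  seed and at least 10 restarts, so results are reproducible and the
  within-group sum of squares (WSS) curve over $k = 1..\max(15, k)$ is
  effectively non-increasing. Clusters are renamed A, B, … by decreasing
  size, a stable labelling across reruns. When $k$ equals the number of
  distinct profiles the Lloyd algorithm is used (Hartigan–Wong cannot
  start with as many centres as points).
* **PCA** treats samples as observations and genes as variables, centred
  but not scaled. Loadings are unit length; the arbitrary sign of each
  component is fixed by making its largest-magnitude loading positive.
  Variance fractions are eigenvalue shares and are non-increasing.

## Differential expression

The package deliberately does not fit count GLMs; dedicated tools do that
better, and their output (gene, log2 fold-change, FDR) can be imported with
`read_de_table()` and drives everything downstream. For an end-to-end run
without external results, `welch_de()` provides a transparent fallback:
per-gene Welch $t$-test on the transformed scale, log2 fold-change as the
difference of group means, Benjamini–Hochberg FDR across genes. DEG lists
use the conventional strict thresholds FDR $< 0.1$ and fold-change $> 2$
(both configurable); a gene at exactly the cut is excluded, matching the
strict inequalities.

## Gene-set enrichment

For a DEG list (query) against a GMT collection, enrichment is the upper
tail of the hypergeometric distribution: with background size $N$,
effective set size $K$ (set ∩ background, within the 15–2000 size window),
query size $n$ (query ∩ background) and overlap $k$,
$p = P(X \ge k)$, $X \sim \mathrm{Hypergeom}(N, K, n)$. BH-FDR is applied
across the sets of one collection — per database, the way enrichment
tables are conventionally reported. The default background is all genes in
the collection, but passing the processed matrix's gene universe is the
better-calibrated choice and is what the pipeline does.

Enriched GO terms are redundant; `build_term_summary()` condenses them by
the *overlap coefficient* on members restricted to the query list:
$d(A, B) = 1 - |A \cap B| / \min(|A|, |B|)$. Division by the smaller set
(rather than the union) makes a term nested inside a bigger one maximally
similar, which is precisely the redundancy worth collapsing; Jaccard is
available for users who prefer union-normalisation. The terms are clustered
with average linkage on $d$ (exported as Newick) and connected in a network
wherever the overlap coefficient reaches 0.5.

## Pathway activity

`page_scores()` implements the parametric gene-set statistic: for a score
vector (log2 fold-changes) with global mean $\mu$ and sample SD $\sigma$, a
set of $m$ genes with mean $S_m$ gets
$$Z = \frac{(S_m - \mu)\sqrt{m}}{\sigma},$$
with a two-tailed normal $p$ and BH-FDR across sets. $\sigma$ uses the
$n-1$ denominator; at transcriptome scale the population/sample distinction
is negligible, but the choice is fixed and documented. The normal
approximation ignores the finite-population correction of sampling without
replacement — for $m \ll G$ this is immaterial, and the test suite checks
the approximation against a 10,000-draw permutation oracle. `abs_mode`
scores $|fc|$ instead, catching pathways perturbed in both directions.

`pgsea_sample_scores()` applies the same statistic per sample: genes are
centred across samples (each sample is then expression relative to the gene
mean — the reference is the row mean, not a designated control group, so no
control needs to be nominated), and $Z$ is computed per set within each
column using that column's mean and SD. The result is a pathways × samples
activity matrix. Two consequences worth knowing: the all-genes set scores
exactly 0 everywhere, and adding a constant to a sample leaves its scores
unchanged.

Ranking the activity matrix: per set, a one-way ANOVA of its per-sample
$Z$ across design groups, BH-FDR across sets, keep `fdr < 0.05`, then rank
by *spread* — the SD of the set's $Z$ over all samples — descending. After
the FDR cut has established that a set differs between groups, spread puts
the strongest contrasts on top, which is what one wants a heatmap ordered
by. (An alternative spread definition, SD of group means, gives nearly the
same order; the per-sample SD is used because it also reflects
within-group coherence.) A set with identical $Z$ everywhere carries no
contrast and is assigned $p = 1$.

`pca_loading_pathways()` treats each principal component's gene loadings
as a score vector and, per set, runs a one-sample $t$-test of member
loadings against the mean loading of all genes, BH-adjusted within each
component. The top 5 sets per component are reported, sets already shown
for an earlier component are skipped, and labels carry the FDR then the
component. Sets with fewer than 3 loaded members are skipped (no
meaningful $t$).

## Promoter motif enrichment

Rather than calling binding sites at an arbitrary cutoff, every promoter ×
motif pair is summarised by the *best* log2-odds score over all offsets on
both strands: $\sum_j \log_2(p_{b_j,j}/q_{b_j})$, where $p$ is the PWM
probability and $q$ a 0-order background defaulting to the pooled base
composition of the supplied promoters. An `N` contributes 0 at its
position; promoters shorter than the motif are recorded as missing. PWMs
load from MEME-minimal or labelled 4-row count blocks; counts get a 0.01
pseudocount per cell before normalisation. Scores are raw maxima — not
length-normalised — with the promoter length recorded so the analyst can
stratify 300 nt vs 600 nt runs.

Enrichment compares the best scores of a gene list's promoters against all
remaining promoters with Welch's $t$-test, one-sided (`greater`) by
default: "enriched" means the list's promoters look more bindable, and a
depletion alarm from a two-sided test is rarely what is wanted (the
two-sided alternative remains available). BH-FDR across motifs.

## Synthetic data

The simulators generate every input format and define the conditions under
which the statistical guarantees are tested:

* `simulate_counts()`: counts $\sim$ NB with mean $\mu_{ig}$ and dispersion
  $\phi$ (variance $\mu + \phi\mu^2$), $\phi = 0.1$ — a typical biological
  replicate regime. Baseline gene means are log-normal with meanlog
  $\log 100$ and sdlog 1.5, spanning roughly 1–10,000 counts the way
  filtered bulk RNA-seq does. A `de_fraction` of genes (default 5%) gets
  its mean multiplied by $2^{\pm 2}$ (up for half, down for half) in
  non-reference groups. Two groups of five samples is the default study
  shape; the knockdown-style analogue used in the acceptance checks widens
  the DE fraction to 40% with dispersion 0.01 to emulate technical
  replicates.
* `simulate_genesets()`: random sets (sizes 15–50) drawn from the gene
  universe plus planted sets passed through verbatim.
* `simulate_promoters()`: i.i.d. uniform A/C/G/T promoters of 300 or 600
  nt; planted promoters receive one exact consensus occurrence at a random
  offset and strand.
* `simulate_mapping()`: per-species id spaces with optional cross-species
  overlap so that one species strictly dominates matches.

Everything is seed-deterministic: identical seeds give byte-identical
files.

What the simulations do **not** emulate: batch effects, GC and length
bias, correlated gene–gene noise, realistic promoter composition (CpG
islands), overlapping biological pathway structure, or the long tail of
weakly expressed genes below the filter. Passing the planted-recovery and
calibration tests therefore demonstrates correctness of the statistics
under their stated model, not performance on any particular real dataset.

## Problem sizes and numerical conventions

The calibration and recovery checks run at 2000 genes, 1000 gene sets and
500 motifs over 100 promoters of 300 nt — large enough for stable
fractions (Monte-Carlo SE of a 5% rate at 2000 genes is about 0.5
points) and small enough to iterate on quickly. Exact-oracle checks
enumerate universes up to 12 genes.

Tie-breaks are deterministic everywhere: input order for equal SDs,
alphabetical for species and set names, size-then-index for cluster
letters. Degenerate inputs have defined behaviour rather than errors where
an analysis can continue (zero-variance items in correlation clustering,
constant activity rows, all-`N` promoters), and hard errors where it
cannot (zero-total libraries, empty queries, factors with one level).

## Known limitations

* The Welch fallback is a two-group test on transformed data; it does not
  model counts, shrink dispersions, or handle factorial designs beyond one
  factor at a time. Import external DE results for anything serious.
* The hypergeometric background is only as good as the supplied universe;
  using all collection genes when the experiment measured a subset
  inflates significance.
* PAGE's normality assumption weakens for very small sets; the size window
  (default minimum 15) is the guard.
* Best-score motif enrichment inherits PWM quality and ignores positional
  preference relative to the TSS.
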