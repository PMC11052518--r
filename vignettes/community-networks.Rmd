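---
title: "Community diversity and RMT-thresholded co-occurrence networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Community diversity and RMT-thresholded co-occurrence networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecomena)
```

`ecomena` implements the community-level analysis stack used in
host-associated microbiome surveys — gut microbiomes of wild fish being
the motivating case — from a denoised ASV count table onward: rarefaction,
alpha diversity with rank-based group comparisons, dissimilarity-based
ordination and permutation statistics, and molecular ecological network
analysis (MENA) with a random-matrix-theory (RMT) threshold and Zi/Pi
keystone classification. Everything upstream of the ASV table (read
merging, quality trimming, denoising, taxonomy assignment) is out of
scope: the package consumes the table, a taxonomy and sample metadata as
plain TSV.

This vignette is the package's account of the methods: the models, the
tunable parameters and why their defaults are what they are, what the
synthetic-data generator does and does not emulate, and the numerical
choices made where the literature leaves them open.

## Data model

An `asv_table()` is a non-negative integer matrix, ASVs × samples, with
unique labels. Metadata carries three closed-vocabulary factors: host
`species`, `season` (spring/summer/autumn/winter) and `gut_part`
(foregut/hindgut/whole — "whole" exists because very small fish are
sampled as an entire intestinal tract). Taxonomy is a ranked lineage per
ASV with the explicit sentinel `"unclassified"`; aggregation keeps
unclassified lineages as named pseudo-taxa (`unclassified_<parent>`)
rather than merging them, because in fish gut data they are often among
the dominant groups and silently pooling them would misstate composition.

## Rarefaction

`rarefy()` subsamples each sample's reads **without replacement** to a
common depth, the standard equalisation of sequencing effort before
diversity estimation. Samples below the target depth are dropped, never
padded, and the dropped ids are recorded (and land in the pipeline
manifest). The default depth is 17,248 reads — a typical refinement depth
for fish gut 16S surveys — and should be overridden for other datasets.
Subsampling draws from the explicit multiset of reads, so a retained
column always sums exactly to the target and a fixed seed reproduces the
table bit for bit.

## Alpha diversity

Per sample, `alpha_diversity()` reports:

* **Shannon** $H=-\sum_i p_i\ln p_i$ (natural log by default; the base is
  an argument because some traditions report bits),
* **inverse Simpson** $1/\sum_i p_i^2$, the effective number of equally
  abundant taxa,
* **observed richness**, and
* **Chao1** in the bias-corrected form
  $S_{obs} + F_1(F_1-1)/(2(F_2+1))$, which never divides by zero when
  doubletons are absent. Chao1 requires integer counts (it is built from
  singletons and doubletons) and, unlike the entropy-based indices, is
  not invariant under count rescaling — hence the insistence on a
  rarefied integer table.

Group differences use the **Mann–Whitney U** test with average ranks for
ties. When $\binom{n+m}{n}\le 20{,}000$ the two-sided p-value is exact by
complete enumeration of group assignments, defined as
$P(|U-nm/2| \ge |U_{obs}-nm/2|)$; otherwise a normal approximation with
tie and continuity corrections is used. Comparison tables report
unadjusted p-values with significance stars, as is conventional in
descriptive surveys; Holm correction is available behind a flag.
Diversity is computed after rarefaction by default — the natural reading
of a workflow that fixes a depth before "calculating α-diversity".

## Beta diversity and ordination

`distance_matrix()` offers Bray–Curtis
$\sum|x_i-y_i| / \sum(x_i+y_i)$ and Jaccard dissimilarities. The Jaccard
default is the **binary** (presence/absence) form — the common reading
when a survey says only "Jaccard" — with the quantitative Ružička
variant (`"jaccard_quant"`) available since the choice is genuinely
ambiguous.

`nmds()` is a from-first-principles Kruskal stress-1 implementation:
isotonic regression (pool-adjacent-violators) of configuration distances
on the rank order of the dissimilarities, alternated with gradient
descent on $\sqrt{\sum(d-\hat d)^2/\sum d^2}$ under a backtracking line
search, so stress is provably non-increasing within each start. Ties are
handled by Kruskal's primary approach (tied dissimilarities may be
fitted in whichever order improves the fit). One start is classical
metric scaling — which already solves exactly embeddable inputs — and
the rest are random Gaussian configurations; the best of 20 starts (10
in the pipeline, where the matrix is larger) is centred and rotated to
principal axes. Stress around or below 0.2 on 2-D embeddings of
factorial community data is typical and matches what `vegan::monoMDS`
achieves on the same matrices.

**PERMANOVA** is one-way, matching a design where each factor (species,
season, gut part) is tested separately:
$SS_{total}=\frac1N\sum_{i<j}d_{ij}^2$, within-group analogues per
group, pseudo-$F=[SS_B/(a-1)]/[SS_W/(N-a)]$, significance by whole-label
permutation. **MRPP** uses the group-size weights $w_g=n_g/N$, reports
the chance-corrected agreement $A=1-\delta/E(\delta)$ with $E(\delta)$
estimated from the permutation distribution, and a p-value for small
$\delta$. Both report p with add-one smoothing,
$p=(1+\#\{stat^* \ge stat\})/(n_{perm}+1)$, so $p\ge 1/(n_{perm}+1)$;
both offer an exhaustive mode enumerating every distinct label
arrangement for small designs, where p becomes the exact proportion.

## Co-occurrence networks (MENA)

The network stage for one sample group (by default one host species,
pooling seasons and gut parts — mirroring a seven-species survey that
builds seven networks) is `conet()`:

1. **Prevalence filter** — keep ASVs present in *strictly more than*
   half of the group's samples; groups under 4 samples are refused.
2. **Spearman correlation** across samples (average ranks for ties;
   zero-variance ASVs excluded with a warning).
3. **RMT threshold** — see below.
4. **Graph** — edge wherever $|\rho| \ge$ threshold; the sign is kept as
   an edge attribute (negative associations are information, not noise),
   isolated nodes removed.
5. **Modules** — Clauset–Newman–Moore greedy modularity agglomeration,
   cut at the modularity maximum of the merge path, then refined by
   deterministic single-node moves and whole-module merges (ascending
   node-label order, only strictly improving steps, three fixed starting
   partitions). The refinement repairs the well-known small-graph
   artifacts of pure agglomeration while leaving clear modular structure
   untouched; module ids are relabelled by each module's smallest member
   so repeated runs are identical.
6. **Statistics** — node and link counts, mean local clustering
   coefficient (degree-<2 nodes contribute 0 — one of the two common
   conventions, recorded in the manifest), mean shortest-path distance
   within connected components, and Newman modularity Q of the stored
   partition.
7. **Zi/Pi and keystones** — within-module degree z-score
   $Z_i=(k_{i,own}-\bar k_{own})/\sigma_{own}$ (0 when the module is
   degenerate) and participation coefficient
   $P_i=1-\sum_m (k_{im}/k_i)^2$. Categories follow the conventional
   cutoffs with boundaries on the "≤" side: peripheral
   ($Z\le2.5, P\le0.62$), connector ($Z\le2.5, P>0.62$), module hub
   ($Z>2.5, P\le0.62$), network hub ($Z>2.5, P>0.62$); every
   non-peripheral node is flagged as a keystone taxon.

### The RMT threshold

The threshold scan (`rmt_threshold()`, default candidates 0.30–0.99 in
steps of 0.01) rests on a spectral observation: a correlation matrix
dominated by random noise has GOE-like eigenvalue statistics (level
repulsion, Wigner-surmise spacings), while a matrix reduced to genuine
modular structure has uncorrelated eigenvalues with Poisson
($e^{-d}$) spacings. At each candidate the matrix is hard-thresholded,
rows without surviving off-diagonal entries are dropped, eigenvalues are
computed, near-duplicates (within $10^{-8}$) removed, and the spectrum is
*unfolded* by fitting the empirical cumulative eigenvalue count with a
cubic smoothing spline (default 10 degrees of freedom — enough to follow
the global density, too stiff to absorb local fluctuations) and mapping
eigenvalues through the fit. Nearest-neighbour spacings, rescaled to unit
mean, are tested against the exponential law by a chi-square
goodness-of-fit on $\lceil\sqrt{\#spacings}\rceil$ equal-probability
bins (equal-probability binning keeps expected counts uniform, where
equal-width bins would starve the tail). The chosen threshold is the
smallest candidate that is not rejected at $\alpha=0.05$ *and* stays
unrejected for the next two candidates — a stability window that stops a
single lucky p-value from fixing the cut. Candidates with fewer than 20
spacings are unevaluable and cannot anchor or extend the window; if no
candidate qualifies the scan fails loudly and asks for a manual
threshold.

These internals (scan range, spline df, binning, $\alpha$, window) are
package defaults with config overrides: published MENA-style tools leave
them unstated, so reproduction of any specific published network is
expressly *not* a goal — the validity criterion is instead behavioural:
the spacing discriminator must reject simulated GOE spectra and accept
simulated Poisson spectra at least 95% of the time each (it measures
100% and 96–99% at $n=200$ eigenvalues), and the end-to-end scan must
recover planted correlation blocks (below).

## The synthetic-data generator

No sequencing data ships with the package; both generators produce
study-shaped data with recorded ground truth, which is what every
downstream guarantee is tested against.

**`simulate_community()`** emulates the post-denoising table of a
factorial gut survey: by default 7 host species × 4 seasons × 2 gut
parts × 4 samples (224 samples, close to the ~210 of a real multi-species
survey), 300 ASVs. One base composition is drawn from a sparse Dirichlet
(concentration 0.3, giving realistically uneven communities); each
factor level shifts a fixed fraction (default 20%) of taxa by ±1
log-unit (±2 is used as the "strong planted effect" condition);
per-sample log-normal noise (sd 0.3) and a log-normal depth distribution
(median 30,000, sdlog 0.35) complete the model, so rarefaction at 17,248
drops a small minority of samples, as in real data. Crucially the base
composition is *shared* across species and groups differ only through
shift vectors: with all effects at zero the samples are exchangeable,
which is what makes the type-I-error calibration of PERMANOVA/MRPP a
well-posed check (measured 0.042–0.052 against the binomial 95% band at
500 replicates, α = 0.05, N = 20 in two groups).

What it does **not** emulate: phylogenetic correlation among taxa,
overdispersion beyond the softmax log-normal layer, taxon names or
abundances of any real survey, or spatial/temporal autocorrelation
between samples. Green tests therefore certify the statistics and the
recovery machinery, not field-data performance.

**`simulate_correlated_counts()`** plants correlation structure for the
network stage: taxa in a block share a per-sample Gaussian factor with
loading ρ (default condition: 3 blocks × 10 taxa, ρ = 0.9, 60 samples),
counts arising through a softmax-multinomial layer. Two design choices
deserve explanation:

* **Sign-balanced loadings.** Half of each block loads positively and
  half negatively on the block factor. A softmax (compositional) layer
  couples *all* taxa through its denominator; with coherent blocks and
  no background taxa this closure induces spurious cross-block
  correlations around −0.38 — large enough to merge planted modules.
  Balancing the signs cancels the block's contribution to the total and
  removes the artifact, while |ρ²| within-block rank correlation is
  unchanged (edges are formed on |ρ|, so a sign-mixed block is still one
  module).
* **Hub construction.** A planted connector must be *classifiable* as a
  connector: with M evenly-linked modules the participation ceiling is
  $1-1/M$, so clearing the 0.62 cutoff requires spreading over at least
  3 modules, and the hub-to-member correlation is bounded by
  $\rho\sqrt{(1+(k-1)c)/k}$ for a hub on k blocks whose factors are
  correlated at c. Hubs therefore track the normalized sum of their
  block factors exactly (unit loading, no idiosyncratic residual), and
  the hub study condition sets factor correlation c = 0.2 — lifting the
  hub ceiling to ≈ 0.66 while keeping cross-block member correlations
  (ρ²c ≈ 0.16) safely below any chosen threshold. Under these
  conditions the full pipeline recovers the planted blocks with ARI 1.0
  in 10/10 seeds and classifies the hub as connector/network hub in
  ~9/10.

## Numerical and degenerate-input choices

* Permutation p-values never reach 0 (add-one smoothing); exhaustive
  modes include the observed arrangement.
* Exact-mode Mann–Whitney switches to the approximation above
  $\binom{n+m}{n} = 20{,}000$ enumerated assignments.
* Isotonic regression is exact PAVA; all-tied dissimilarity vectors are
  fitted freely (primary tie treatment), so a perfectly symmetric input
  like three equidistant points reaches stress 0.
* NMDS accepts only stress-decreasing steps (30 halvings of the step
  before declaring convergence); `stress_trace` exposes the
  monotonicity for inspection.
* Zi is 0 in modules with zero within-degree variance (including
  singleton modules); isolated nodes are excluded from topology with a
  warning (the graph builder removes them anyway).
* Eigenvalue deduplication tolerance is $10^{-8}$; spacing counts below
  20 mark a scan candidate unevaluable rather than producing a fragile
  chi-square.
* All stochastic stages take explicit seeds and record them in their
  result objects; the pipeline derives per-stage seeds from one master
  seed and reproduces outputs byte-for-byte.

## Problem sizes used by the test suite

The suite validates closed forms and hand-derived examples directly;
oracle equivalence by exhaustive enumeration at N = 6 (permutation
tests), n, m ≤ 6 (Mann–Whitney), ≤ 20 nodes (Floyd–Warshall distances)
and ≤ 8 nodes / all set partitions (modularity, where the greedy
solution is checked against the exhaustive optimum per graph and against
90% of it in aggregate over a 50-graph sweep — per-graph 90% is not a
property any greedy agglomerator has on weak-structure random graphs);
calibration at 500 null replicates; recovery at 10 seeds of the planted
designs; discriminator validity at 100 GOE and 100 Poisson spectra of
dimension 200. These sizes were chosen so the full suite completes in
about half a minute while keeping every Monte-Carlo band meaningful.

## Known limitations

* The RMT threshold is selected on the unweighted spacing test alone; no
  alternative criteria (e.g. scale-free fit) are implemented.
* PERMANOVA is one-way with free permutation — no strata, no nested
  designs, no interaction terms, matching the analysis it reproduces but
  not general experimental designs.
* `jaccard` on unrarefied tables conflates depth with composition;
  rarefy first.
* Networks need groups of ≥ 4 samples, and realistically many more;
  co-occurrence networks from small groups are noise regardless of
  thresholding rigour.
* The generator's truth records make recovery *scoreable*, not easy:
  conditions with weak effects will and should fail recovery, and the
  package makes no attempt to hide that.
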