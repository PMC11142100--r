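---
title: "Scoring cell-specific alternative splicing with a uniqueness index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring cell-specific alternative splicing with a uniqueness index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Deep RNA-seq of sorted cell populations — for example the bulk
transcriptomes of individual *C. elegans* neuron classes, with 46 cell
types and 2–8 biological replicates each — makes it possible to ask not
just which genes a cell expresses but which *isoforms* it makes. A gene
can be expressed pan-neuronally yet spliced in only one cell type; finding
those events requires comparing splicing in every cell type against every
other one and then aggregating the comparisons into a single per-cell
score. `spliceuniq` implements that aggregation: pairwise differential
splicing over all ordered cell-type pairs, and a signed **uniqueness
index** that summarizes how specifically an event (or, in the expression
variant, a gene) behaves in one focal cell type.

## From junction reads to PSI

The unit of quantification is the splicing event: an annotated set of two
or more competing sub-junctions (cassette inclusion vs. skipping, intron
retention vs. excision, two alternative 3'/5' splice-site choices, two
mutually exclusive exons, or a composite combination). For each event,
replicate and sub-junction *j*,

usage(j) = reads(j) / Σ\_{j'} reads(j'),

with the denominator restricted to the event's own sub-junctions. The
event's PSI is the usage of its **representative junction**: the flagged
inclusion (retention) junction for cassettes and retained introns, and the
transcript-upstream junction for splice-site and mutually exclusive
choices — "upstream" follows the gene, so it is the smallest genomic start
on the plus strand and the largest on the minus strand. Composite events
use the most-upstream genomic sub-junction.

Two detection thresholds guard the estimates:

* `junction_min_reads` (default 5): a replicate with fewer total
  junction-spanning reads for the event is *undetected* (`NA`), never a
  PSI of 0. Missingness and zero inclusion are different observations.
* the *n − 1* rule: an event counts as detected in a cell type only when
  it is quantified in at least *n − 1* of the cell's *n* replicates. At
  *n* = 2 this admits a single replicate, which is why single-replicate
  cell types are warned about rather than rejected.

Events are called *alternative* when their replicate-mean PSI falls in the
closed band [0.10, 0.90] in at least one cell type. The band is applied to
cell-type means rather than single replicates because the mean is the
quantity every downstream statistic consumes, and per-replicate banding
would make the classification depth-dependent. Alternative 3'/5'
splice-site events offering more than two candidate coordinates are
removed up front (`filter_multi_coordinate()`): with three or more
competing coordinates, "upstream versus downstream" is no longer a
two-level contrast and the sign of a delta is ambiguous.

## Pairwise differential splicing

Every ordered pair of cell types (N types, N(N−1) comparisons; 46 types
give 2,070) is tested per event. The effect size is
ΔPSI = mean PSI(cell A) − mean PSI(cell B) over detected replicates. The
p-value comes from Welch's t-test on the replicate PSI values, with one
special case: when both groups have zero variance the p-value is defined
as 0 when the means differ and 1 when they are equal. That rule makes the
index's analytic extremes exact (a construction with PSI identically 1.0
versus 0.0 must be significant; identical constant PSI must not be).

Benjamini–Hochberg q-values are computed within one (pair × splicing
type) family, mirroring a per-run false-discovery-rate adjustment when
each pair is analyzed as its own experiment. A comparison is
**significant** only when all three gates pass:

|ΔPSI| > 0.10, p < 0.05, q < 0.05.

### Why Welch rather than a small-sample permutation test

An exact permutation test on the difference of means is the textbook
choice at 4-versus-4 replicates, and `two_group_test(method =
"permutation")` provides it. The pipeline nevertheless uses Welch
everywhere, for a structural reason: with n replicates split 4/4 the
permutation p-value cannot go below 2/choose(8,4) ≈ 0.0286. After BH
adjustment across an event family of size *m*, the smallest attainable
q-value is ≈ 0.0286·*m*/k for k events tied at the floor, so with
realistic family sizes no event can ever reach q < 0.05 — the
significance gates would silently zero the uniqueness index for every
event regardless of effect size. A continuous p-value does not have this
floor; Welch on 3–8 replicates of beta-distributed PSI is approximately
calibrated (the null simulations in the test suite confirm the
significant-call fraction stays below the nominal q), and for
well-separated groups it agrees with the permutation test in rank order.

## The uniqueness index

For one event *e* and focal cell *c* with *N* cell types,

U(e, c) = Σ\_{c' ≠ c} s(e) · ΔPSI\_first(e; c, c') · 1[significant(e; c, c')],

where ΔPSI\_first is the delta of the event's **first** sub-junction — the
one with the smallest genomic start (ties broken by the smaller end; the
tie-break matters only for pathological annotations and is fixed so
rankings are deterministic) — and s(e) ∈ {−1, +1} is the orientation
sign: −1 for alternative 3' splice sites on the plus strand and
alternative 5' splice sites on the minus strand, +1 otherwise. After the
sign correction, a positive contribution always means "more upstream (or
more included) usage in the focal cell." Composite events keep s = +1:
the reversal exists to express splice-site choice in transcript
coordinates, and a composite event's first sub-junction is already
reported in genomic orientation.

Non-significant and undetected comparisons contribute exactly zero but
still count toward `n_compared`, so the index is bounded:
|U| ≤ n\_significant ≤ N − 1. With 46 cell types the extremes ±45 are
attained exactly by an event whose PSI is identically 1.0 in the focal
cell and 0.0 everywhere else (or the mirror image), and an event with
identical PSI everywhere scores 0. ΔPSI enters in fractional units
(0.8, not 80%) — that is what makes N − 1 the bound.

`uniqueness_table()` scores every (event, focal cell) pair and sorts with
a deterministic tie-break (|index| descending, then feature and cell ids),
so equal scores always appear in the same order.

### Expression variant

The same aggregation applies to gene expression. Counts are converted to
CPM, each ordered pair is tested by Welch on log2(CPM + 1), the fold
change is log2((mean CPM_A + 1)/(mean CPM_B + 1)), and a pair is
significant when p < 0.01 and |log2FC| > 2 — deliberately stricter than
the splicing gates, as differential-expression analyses of sorted-cell
data conventionally are. The per-gene index is the **sum of significant
log2 fold changes** against all other cells. Summing (rather than
counting significant pairs or averaging) was a genuinely open choice; it
is the direct analogue of summing ΔPSIs, keeps the magnitude
interpretable (a gene 16-fold up in one of four cells approaches
3·log2 16 = 12), and preserves the sign convention. A gene-subset filter
supports focused scans, e.g. ranking only RNA-binding-protein genes to
nominate candidate splicing regulators for a cell type.

## Global statistics

* `count_differential()` tallies significant events per (pair, splicing
  type); within one comparison an event can be called at most once, so
  per-pair tallies keep a minimum threshold of a single count.
* `global_totals()` admits an event into genome-wide totals only when it
  is called differential in at least `global_min_comparisons` (default 5)
  pairwise comparisons. The threshold is read as "5 pairwise calls" —
  a read-count interpretation would duplicate `junction_min_reads`, which
  already exists. A gene counts as uniquely spliced when at least one of
  its events qualifies.
* `splice_type_correlation()` regresses per-pair counts of one category
  on another (OLS, adjusted R²), using each unordered pair once —
  ordered duplicates are antisymmetric copies and would double every
  observation. Constant count vectors return 0 with a warning instead of
  an undefined fit.
* `outlier_cells()` totals each cell's significant events per splicing
  type and flags robust z-scores |z| > 3.5 (median/MAD). The analyses
  this supports identified single neurons enriched for one splicing
  type; a median-based rule keeps one extreme cell from masking itself.
* `directional_bias()` reports the fraction of a cell's nonzero indices
  that are positive (upstream after orientation). A cell with no nonzero
  record returns `NA` — an undefined bias is not a bias of zero. The
  mirror identity (replacing every PSI x by 1 − x flips the bias to
  1 − b) is kept exact and is tested.
* `usage_mega_matrix()` builds, per splicing type, the event × cell-type
  matrix of replicate-mean representative usage with `NA` for undetected
  cells; `export_vista_table()` emits one event's row as a per-cell-type
  percent-inclusion table (0–100, one decimal) for spatial-heatmap
  front ends.

## The synthetic-data generator

`simulate_splicing()` produces data shaped like a sorted-cell neuronal
atlas so every stage can be validated without any sequencing download.
Defaults: 46 cell types × 4 replicates, 10 events in each of the six
classes, mean depth 200 junction reads per event and sample, beta
concentration κ = 100 for replicate noise, 5% of events planted as
cell-unique with a PSI shift of Δ = 0.6.

The hierarchy is the minimal one reproducing replicate overdispersion in
junction data: per event a baseline mean PSI is uniform on [0.1, 0.9];
planted events shift the focal cell's mean by Δ away from 0.5, clipped
into [0.02, 0.98] (clipping at exact 0/1 would create degenerate
zero-variance groups, which are reserved for the explicit bound
constructions); replicate PSI ~ Beta(μκ, (1−μ)κ); totals ~ Poisson(depth);
representative-junction reads ~ Binomial(total, PSI), with remaining reads
split over the other sub-junctions by fixed per-event proportions.
Configurations whose Δ would clip more than half of the planted events
(an analytic property of Δ, not of the draw) are rejected as infeasible.
Strands alternate across events so both orientation-reversal classes
(A3S on plus, A5S on minus) are exercised. Everything is reproducible
from the seed, and the emitted truth table records each planted event's
focal cell, true effect and the expected *sign of its index* — which
folds in both the orientation rule and whether the representative
junction is the first one.

`simulate_expression()` draws negative-binomial counts (default 200
genes, dispersion 0.1) with planted genes 16-fold up in one focal cell.

What the generator deliberately does **not** emulate: alignment and
mapping biases, shared junctions between events of the same gene,
correlated replicates (batch structure), cell-type phylogeny (all
non-focal cells share one baseline), or library-size variation beyond
what count sampling induces. Passing recovery tests therefore show that
the statistics do what they claim on cleanly generated beta-binomial
data; they do not show robustness to misannotation or mapping artifacts.

## Numerical choices and degenerate inputs

* Equal-means detection in the zero-variance rule uses a 1e−12 absolute
  tolerance; PSI values arriving from file are exact decimals, so this
  only matters for means computed in floating point.
* Sub-junction usage must sum to 1 within 1e−9 per detected
  (event, sample); `compute_psi` guarantees this by construction.
* PSI is stored as a fraction in [0, 1] everywhere internally; only
  display surfaces (the spatial export) use the 0–100 scale. Coordinates
  are 1-based inclusive genomic positions.
* The PSI writer emits 6 decimals; round-trips are exact to 1e−6 and
  byte-identical between runs. All writers are deterministic (fixed
  column order, fixed formatting, no timestamps — run logs record
  version, seed and thresholds only).
* Welch's statistic treats a single-replicate group as contributing zero
  variance; the zero-variance rule catches the fully degenerate cases
  first.

## Validation problem sizes

The test suite validates the index against an independent brute-force
summation on hundreds of small random comparison sets (≤6 cell types),
checks the ±45/0 extremes on exact constructions at the full 46-type
scale, and runs two full default-scale simulations (46 types × 4
replicates × 60 events, one with planted effects for recovery and one
null for type-I control). Those sizes keep a complete run of the suite
under a minute on a single core while still exercising the all-pairs
machinery at the real pair count (2,070).

## Known limitations

* The two-group test substitutes a replicate-level location test for a
  count-aware model; at very low depth the beta-binomial uncertainty of
  PSI itself is not propagated.
* The expression variant is a deliberate emulation of a conventional
  differential-expression screen (CPM + Welch), not a negative-binomial
  GLM; use it for ranking, not for calibrated effect estimates.
* BH within (pair × type) families controls FDR per comparison run, not
  globally across all 2,070 runs.
* The ≥5-comparison rule for global totals is one reading of an ambiguous
  convention; the per-event call counts are exposed so any other
  threshold can be applied downstream.
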