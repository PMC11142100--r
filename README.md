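# spliceuniq

Cell-specific alternative splicing analysis for sorted-cell RNA-seq
atlases: percent-spliced-in (PSI) quantification from splice-junction
counts, differential splicing across **every ordered pair of cell types**,
and a signed **uniqueness index** that ranks splicing events — or genes,
via an expression variant — by how specific they are to a single cell
type. A beta-binomial simulator with planted ground truth makes the whole
pipeline testable end to end without sequencing data.

The package is aimed at transcriptomics of deeply sequenced sorted cell
populations (the motivating shape is a *C. elegans* neuronal atlas: 46
neuron types, 2–8 biological replicates each), where a gene may be
expressed broadly yet spliced uniquely in one cell.

## The model in brief

For an event with competing sub-junctions, each replicate's PSI is the
read share of the event's *representative* junction (inclusion junction
for cassettes/retained introns; transcript-upstream junction for
alternative 5'/3' splice sites and mutually exclusive exons). For every
ordered pair of cell types (A, B):

* ΔPSI = mean PSI(A) − mean PSI(B) (fractions, detected replicates only),
* p from Welch's test on replicate PSI (p = 0/1 at zero variance with
  different/equal means),
* q from Benjamini–Hochberg within the (pair × splicing type) family,
* significant ⇔ |ΔPSI| > 0.10 and p < 0.05 and q < 0.05.

The uniqueness index of event *e* in focal cell *c* over *N* cell types is

    U(e, c) = Σ_{c' ≠ c}  s(e) · ΔPSI_first(e; c, c') · 1[significant]

where ΔPSI_first is the delta of the event's most-upstream sub-junction
(smallest genomic start) and s(e) = −1 for A3S(+ strand) and A5S(− strand)
events — so positive always means "more upstream / more included in the
focal cell" — and +1 otherwise. The index is bounded by ±(N − 1): with 46
cell types, +45 means fully included in the focal cell and fully skipped
in all 45 others, and 0 means no systematic difference. The expression
variant sums significant log2 fold changes (CPM scale, gates p < 0.01 and
|log2FC| > 2).

## Worked example

Simulate a small atlas (8 cell types × 4 replicates, 18 events, 10% of
them planted as cell-unique), run the full pairwise analysis, and rank:

```r
library(spliceuniq)

cfg <- sim_config(n_cell_types = 8, n_replicates = 4,
                  events_per_type = c(CASSETTE = 6, IR = 6, A3S = 6),
                  planted_fraction = 0.1, seed = 42)
sim  <- simulate_splicing(cfg)
psi  <- compute_psi(sim$counts, sim$annotations)
comp <- run_all_pairs(psi)            # 8 x 7 = 56 ordered comparisons
uniq <- uniqueness_table(comp, sim$annotations)
head(uniq, 5)
#> # A tibble: 5 × 6
#>   as_type feature_id focal_cell  index n_significant n_compared
#>   <chr>   <chr>      <chr>       <dbl>         <int>      <int>
#> 1 A3S     A3S_006    CT03       -4.21              7          7
#> 2 A3S     A3S_003    CT01       -3.45              7          7
#> 3 A3S     A3S_006    CT06        0.622             1          7
#> 4 A3S     A3S_006    CT07        0.613             1          7
#> 5 A3S     A3S_006    CT05        0.605             1          7
```

The two top records are exactly the two planted events in their planted
focal cells, significant against all 7 other cell types, with |index|
close to 7 × their planted effect:

```r
sim$truth[, c("feature_id", "focal_cell", "true_effect", "direction")]
#> # A tibble: 2 × 4
#>   feature_id focal_cell true_effect direction
#>   <chr>      <chr>            <dbl>     <dbl>
#> 1 A3S_006    CT03             0.6          -1
#> 2 A3S_003    CT01             0.510        -1
truth_eval(uniq, sim$truth)$precision_at_k
#> [1] 1
```

Both planted events are alternative 3' splice sites on the plus strand,
so their positive PSI shifts are sign-reversed during summation
(`direction` −1): a negative index reads "uniquely *downstream* splice
site choice in this cell". Rows 3–5 show the echo of a planted event in
the other cells: each non-focal cell differs from the focal one in
exactly 1 of its 7 comparisons.

A shell entry point wrapping the same functions ships in
`inst/cli/spliceuniq.R` (`simulate`, `psi`, `compare`, `uniqueness`,
`stats`, `megamatrix`, `export`, `run-all`), driven by a YAML config of
thresholds and writing TSVs plus a run log.

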