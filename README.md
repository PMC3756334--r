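# stemward

Simulated fossilization experiments for morphological phylogenetics:
how does losing the soft-part characters of a morphological matrix —
the data that decay destroys before fossilization — distort parsimony
trees, and does it drag taxa *stemward*, toward the root?

The package is aimed at systematists and palaeobiologists who work with
partitioned morphological matrices (characters labelled biomineralized
"hard" vs non-biomineralized "soft") and want to quantify taphonomic
bias on extant-taxon datasets, and at methodologists studying
structured missing data in parsimony.

## What it computes

For a matrix with benchmark strict-consensus clade set *B* (from the
full data) and test clade set *T* (after a perturbation and a new
search over all most parsimonious trees, MPTs):

* **Node recovery index** `r = |B ∩ T| / |B|`, compared between the
  systematic deletion of one whole partition and *n* random deletions of
  the same number of characters, with the rank-based permutation
  p-value `p = (#{r_null ≤ r_sys} + 1) / (n + 1)` (one-tailed low; 0 of
  500 nulls below gives p ≈ 0.002). Pooling across matrices sums node
  counts and pairs the i-th null replicates.
* **Taxon shift** `Δ = d_foss − d_orig`, where `d` is the mean over all
  MPTs of the number of intervening nodes between a terminal and the
  root (a patristic variant sums ACCTRAN parsimony steps instead);
  `Δ < 0` is stemward ("down"). Each taxon's `|Δ|` is ranked against
  matched random degradations of its own row (same number of scored
  cells blanked).
* **Cross-dataset statistics**: exact binomial tests on direction
  splits, the log-likelihood-ratio test `G = 2 Σ O ln(O/E)` (χ²₁) on
  the condition-by-direction 2×2 table, and a 50× dataset jackknife
  (each matrix included with probability 0.5) of the pooled comparison.

Everything runs on a self-contained compiled parsimony engine (Fitch /
Wagner scoring, random-addition + SPR/TBR searches that collect the
full MPT plateau with no branch collapsing, exhaustive enumeration up
to 9 taxa as an exact oracle, outgroup-rooted strict consensus), plus a
synthetic-data generator that emulates compiled matrix collections with
a tunable decay-biased signal (soft characters own the crownward
synapomorphies). NEXUS and TNT matrices are read and written directly,
with a CSV partition sidecar.

## Worked example

```r
library(stemward)

# one decay-biased synthetic dataset with known truth
suite <- make_benchmark_suite(1, "decay_biased", n_taxa = 20, n_char = 60,
                              hard_fraction = 0.5, seed = 42,
                              homoplasy_rate = 0.2)
m <- suite$matrices[[1]]
m
#> char_matrix: 21 taxa x 56 characters (28 hard, 28 soft), outgroup 'OUT'
#> missing: 8.3% overall (hard 7.3%, soft 9.4%)

# Stage 1: does deleting all soft characters destroy more consensus
# structure than deleting 28 characters at random?
run_node_recovery(m, "fossilization", n_reps = 100,
                  settings = desk_settings(), seed = 1)
#> node recovery (fossilization): 10/17 nodes (0.59) vs null mean 0.78; p = 0.0396

# Stage 2: pseudofossilize one taxon and track its root distance
sh <- run_taxon_shift(m, "t1", n_reps = 60, settings = desk_settings(), seed = 1)
sh
#> taxon shift 't1' (nodes): 8.000 -> 7.678 (delta -0.322, down), p = 0.4098
classify_shift(sh)
#> $direction    "down"
#> $significant  FALSE
```

Reading the output: the fossilization filter kept only 10 of the 17
benchmark consensus nodes (59%), while random deletions of the same
size kept 78% on average — only 4 of 101 rank outcomes were as bad, so
p ≈ 0.04. Taxon `t1` moved 0.32 nodes toward the root when its soft
cells were blanked, a shift within the range of matched random
degradations (p = 0.41), so it moved down but not significantly.

## The analysis workflow

The full experiment is a numbered script sequence (thin drivers over
the package functions) writing tables under `results/`:

| script | what it does |
| --- | --- |
| `analysis/01_simulate_suites.R` | builds a 20-matrix exchangeable (null) suite and a 20-matrix decay-biased suite; serializes them as TNT + partition sidecars |
| `analysis/02_curate.R` | re-reads the files and runs the curation protocol (informativeness, taxonomic equivalents, missing-data balancing, inclusion thresholds) |
| `analysis/03_node_recovery.R` | node recovery in both directions (soft deleted vs hard deleted) with 100 random-deletion replicates each, pooled tests and jackknife |
| `analysis/04_taxon_shift.R` | per-taxon pseudofossilization with 60 matched random replicates per taxon, direction and significance summaries |
| `analysis/05_meta_stats.R` | binomial and G tests over the pooled direction counts |

On the decay-biased suite the workflow recovers the expected
signatures: fossilization-mode recovery falls significantly below its
random null while inverse fossilization (deleting hard characters) does
not, and significantly shifting pseudofossils move predominantly
stemward. The exchangeable suite calibrates both permutation tests.

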