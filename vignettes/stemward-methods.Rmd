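---
title: "Simulated fossilization and stemward slippage: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulated fossilization and stemward slippage: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question

Fossils preserve a biased subset of morphology: biomineralized ("hard")
structures such as bones, teeth and shells survive, while
non-biomineralized ("soft") tissues are lost to decay. Because the
phylogenetic placement of fossils is almost always inferred by parsimony
on morphological characters, this taphonomic filter may not merely add
noise — it may *systematically distort* inferred trees. The package
implements a pseudoextinction experiment that quantifies two effects on
extant-taxon matrices whose characters are labelled hard or soft:

1. **Node recovery.** Does deleting *all* soft characters destroy more of
   the original consensus structure than deleting the same number of
   characters at random?
2. **Taxon shift ("stemward slippage").** When a single taxon is
   simulated as a fossil (its scored soft cells replaced by `?`), does it
   drift from its original position, and preferentially *toward the
   root*, relative to matched random degradation of the same row?

Both questions are answered by permutation: the systematic perturbation
is ranked within a null distribution of random perturbations of exactly
the same size.

## Data model and curation

A `char_matrix` is a taxa-by-characters grid of discrete state sets
(alphabet 0–9, `?` missing, `-` collapsed to missing, polymorphic sets
allowed), a per-character `hard`/`soft` partition, a named outgroup, and
an optional per-character ordering flag (default unordered; ordered
characters are counted with Wagner/interval parsimony). Inapplicable
codings are treated as missing because the fossilization protocol codes
taphonomic absence as uncertainty, not as a state.

Curation mirrors the editing protocol used to build compiled matrix
collections, in order:

* drop parsimony-uninformative characters (a character is informative
  when at least two states are each scored unambiguously in at least two
  taxa);
* drop taxonomic equivalents — a taxon whose scored cells never conflict
  with and never exceed another's is removed (first-listed retained on
  ties; the outgroup is never removed);
* balance missing data: when the partitions differ by ≥ 10 percentage
  points of missingness, remove taxa with > 30% missing cells, then
  characters with > 50%, iterating to convergence (a single-pass mode is
  available; the protocol source does not state whether the removals were
  iterated, and iteration is the conservative reading because it
  guarantees the gap condition on exit);
* apply inclusion thresholds: ≥ 30 characters, ≥ 10 taxa, hard fraction
  `|hard| / (|hard| + |soft|)` in [0.20, 0.80], boundaries inclusive. The
  hard:soft phrasing is ambiguous between a fraction and an odds ratio;
  the fraction reading is used and the thresholds are arguments.

## The parsimony engine

The engine is compiled code built for this experiment's workload:
tens of thousands of small searches per run, each of which must return
the *set* of most parsimonious trees (MPTs) fully resolved, rooted on
the outgroup, with no branch collapsing — zero-length branches are
retained so that node counting is unambiguous.

* **Scoring.** Fitch optimization over bitmask state sets (missing = full
  set) for unordered characters; Farris interval counting for ordered
  ones. Scoring is invariant under re-rooting and is cross-checked in the
  tests against an independent implementation and against brute-force
  hand-derived cases.
* **Search.** Random-addition-sequence stepwise addition (ties broken
  uniformly at random) followed by first-improvement branch swapping,
  SPR or TBR. TBR moves are implemented as prune + reroot + regraft,
  which covers the full unrooted TBR neighbourhood.
* **MPT plateau.** All distinct optimal trees encountered are collected,
  deduplicated by a canonical rooted form, and the plateau is then
  *swapped to closure*: every held tree's neighbourhood is scanned for
  further equal-length trees until no unswapped tree remains or a cap is
  hit (`max_trees`, and an evaluation budget). When a cap is hit the
  flag is recorded; consensus and mean-root-distance summaries computed
  from a truncated plateau are approximations that err toward
  over-resolution. At the problem sizes used here the caps are
  essentially never reached (plateaus of 1–50 trees are typical).
* **Exhaustive oracle.** For ≤ 9 taxa all `(2n−5)!!` unrooted topologies
  are enumerated and every minimum-length tree kept. The heuristic is
  validated against this oracle on hundreds of random matrices (score,
  MPT set, and consensus clades).

Search profiles: `full_settings()` uses 100 random additions with TBR,
holding 1000 trees per replicate and 10000 overall. `desk_settings()`
(the default for the simulation studies) uses 5 additions with SPR and
caps of 200 trees / 5×10⁴ plateau evaluations; on the matrix sizes used
in this package's studies it returns the same scores as the exhaustive
and TBR searches while keeping a single search at a few milliseconds.
The swap type, caps and budgets only trade runtime against plateau
completeness; the statistical logic is unchanged.

**Rooting and clades.** All MPTs are rooted on the outgroup before any
consensus, and the strict consensus is taken over rooted clades. A clade
set contains every proper subset of 2 to n−1 leaves; the ingroup clade
(everything but the outgroup) is a genuine node of every outgroup-rooted
tree and is counted. Root distances use the "intervening nodes" reading
with both endpoints excluded: a terminal attached directly to the root
scores 0. The patristic variant sums per-edge parsimony steps along the
terminal-to-root path under a rooted ACCTRAN resolution (downpass sets,
then a top-down pass that retains the parent state whenever the child's
preliminary set allows it, placing changes as rootward as possible; the
root state is resolved toward the outgroup). A minimum-length
(DELTRAN-like) resolution was considered and rejected because
accelerating changes keeps stem edges — the edges the slippage statistic
travels — consistently weighted.

## The two tests

**Node recovery** (per matrix): let `B` be the clade set of the strict
consensus of the full-matrix MPTs. Deleting the soft partition (k
characters) and re-searching yields a test consensus with clade set `T`;
the recovery index is `|B ∩ T| / |B|`. The same index is computed for
`n` random deletions of exactly k characters, and

&nbsp;&nbsp;&nbsp;&nbsp;`p = (#{null ≤ observed} + 1) / (n + 1)`,

one-tailed low, ties counted in the rank. This convention is pinned by
its own arithmetic: 0 of 500 nulls below the observed value gives
1/501 ≈ 0.002 and 259 of 500 gives 260/501 ≈ 0.52. The
inverse-fossilization control deletes the hard partition instead.
Deletions that leave no informative character score a recovery of 0 and
are flagged; random deletions are never redrawn, since redrawing would
bias the null. Across matrices, *counts* are pooled — summed recovered
nodes over summed benchmark nodes — and the i-th pooled null replicate
pairs the i-th replicate of every matrix, so the pooled test uses the
identical rank convention. A dataset jackknife (each matrix included
with probability 0.5, 50 resamples) probes whether the pooled verdict
depends on a few matrices.

**Taxon shift** (per taxon): with `d` the mean over all MPTs of the
number of intervening nodes between the terminal and the root,
`delta = d_fossilized − d_original`; negative is stemward ("down").
The matched null blanks the same number of that taxon's *scored* cells,
drawn uniformly across both partitions — counting only scored soft cells
keeps the row's missingness exactly matched, which the protocol's "same
number of characters" phrasing leaves open. Significance is two-sided in
direction: `p = (#{|null| ≥ |delta|} + 1) / (n + 1)`. A taxon is a
"mover" when `|delta| > 10⁻⁹` (a pure float-noise tolerance for means
over MPT sets). The outgroup is never fossilized; a taxon with no scored
soft cells is flagged unperturbable. Random-condition direction counts
use each taxon's first null replicate ("matched" accounting, one draw
per taxon — the same design size as the fossilization condition); an
all-replicates pooling is also available.

Cross-dataset statistics: exact binomial tests (one-sided = upper tail;
two-sided by summing outcomes no more probable than the observed one)
and the log-likelihood-ratio test `G = 2 Σ O ln(O/E)` against χ²₁ for
the 2×2 condition-by-direction table.

## The synthetic-data generator

No machine-readable compilation of suitable published matrices exists,
so the generator emulates one with known truth. Each dataset is built
on a Yule (unit birth rate) ingroup topology conditioned on the taxon
count, with an all-plesiomorphic, fully scored outgroup attached at the
root. Every character receives one primary derived-state change on an
internal ingroup edge whose clade could make it parsimony-informative;
with probability `homoplasy_rate` an extra convergent or reversal change
lands on a uniformly chosen ingroup edge; missing entries are injected
per partition at `missing_rate`.

The *signal mode* decides which tissue type owns each change. Candidate
edges are ranked by node depth from the root and cut into three zones
(rootward / mid / crownward terciles of the depth range).

* `exchangeable`: placement is uniform and ownership ignores depth, so
  hard/soft labels are statistically interchangeable. This is the null
  condition used to calibrate both permutation tests: by construction
  the systematic deletion is one more draw from its own null.
* `decay_biased`: soft changes are placed uniformly over all candidate
  edges — soft anatomy informs every depth of the tree, so a soft-only
  matrix resembles a random remainder of the full matrix. Hard changes
  go to the root zone with probability `hard_root_bias` (0.6) and
  otherwise avoid the crown zone with probability `crown_bias` (0.8):
  recent divergences are diagnosed by soft tissue, deep divergences
  redundantly by biomineralized characters.

This zone-ownership construction was chosen over the superficially
simpler alternative — concentrating a fixed fraction of soft changes
*onto* the crown tercile — after analysis showed the latter cannot
reproduce the experiment's known qualitative behaviour: once soft
characters are concentrated crownward, a soft-only matrix has no deep
signal, so the inverse-fossilization control comes out strongly
significant, which contradicts both the decay premise (soft anatomy is
the information-rich superset) and the empirical pattern the experiment
is built around. Under zone ownership the two signatures emerge
structurally rather than by tuning: hard-only matrices lose the crown
(fossilization significantly worse than random), soft-only matrices
behave like random remainders (inverse ≈ null), and a pseudofossilized
taxon keeps mostly deep-clade evidence and slips stemward.

Defaults: binary characters (most cells of real morphological matrices
are binary; multistate is available), `homoplasy_rate = 0.5` (about 1.5
changes per character, a consistency index near 0.6 — typical of
published morphological matrices), `missing_rate = 0.10` per partition
(keeps the partition gap below the 10-point balancing threshold in
expectation). `make_benchmark_suite()` draws per-matrix sizes from
10–40 taxa and hard fractions from 0.2–0.8, curates each matrix and
redraws until it passes the inclusion thresholds, so every emitted
matrix is analysis-ready.

What the generator does **not** emulate: correlated character evolution,
ordered/continuous characters, rate variation among lineages, realistic
taxon-sampling structure, or graded decay stages. Passing tests on these
suites therefore demonstrate the *internal* correctness and calibration
of the pipeline, not the empirical magnitudes of the published
compilation, whose exact percentages depend on 78 specific matrices.

## Problem sizes and what the studies show

The packaged studies run at desk scale with `desk_settings()`:

* oracle equivalence: 200 random 5–7-taxon matrices, heuristic vs
  exhaustive;
* null calibration: 50 exchangeable matrices (15 taxa, 60 characters),
  100 node-recovery replicates and 60 per-taxon replicates;
* decay-biased experiment: 20 matrices of 18–28 taxa and 60 characters
  (the mid-range of the suite's 10–40 span, large enough for distinct
  depth zones), hard fractions 0.2–0.8, `homoplasy_rate = 0.2`,
  `crown_bias = 0.8`, per-taxon shifts on the first 8 ingroup taxa of
  each matrix;
* noiseless sanity: 100 seven-taxon zero-homoplasy matrices solved
  exactly by exhaustive search.

One calibration property of real compilations is not reproduced by
these synthetic suites and is reported rather than hidden: *random*
per-taxon degradation is itself stemward-biased here (about 70% of
movers go down on 15-taxon matrices, about 60% on 25-taxon ones,
attenuating with tree size but not vanishing at desk scale). The
mechanism is geometric: movers are overwhelmingly crownward taxa — the
majority of leaves on a Yule tree — for which losing own-clade support
opens equal-cost stemward attachments, whereas moving up requires
positive homoplastic attraction; averaging over the MPT plateau then
regresses them toward the root. Published compilations report a
balanced random baseline (≈49/51); their matrices are larger, more
heterogeneous, and their taxa sit in less uniformly crown-heavy
positions than Yule leaves. The acceptance script reports the random
baseline at both 15 and 25 taxa so the scale trend is visible. Because
the fossilization condition is always compared against *its own matched
random null* (the direction G test and the per-taxon magnitude ranks),
this drift affects the isolated direction split of the null, not the
fossilization-vs-random contrasts that carry the experiment's
conclusions.

## Reproducibility

Every stochastic unit — each search, each random deletion, each
replicate — derives its seed from the master seed and its identifiers
via `derive_seed()`, so results are independent of execution order and
bit-reproducible. The analysis drivers under `analysis/` run the whole
experiment from serialized files (TNT matrices + partition sidecars +
outgroup configs) and write all tables under `results/`;
`scripts/acceptance.R` recomputes the headline statistics from scratch
against the installed package.

## Known limitations

* The engine targets matrices up to a few dozen taxa; it is not a
  general replacement for dedicated parsimony software on hundreds of
  taxa.
* Strict-consensus summaries from a capped MPT plateau can be
  over-resolved; caps are recorded per search and are not reached at the
  packaged problem sizes.
* Multistate support in the generator is simplified (each extra change
  assigns one random state to a subtree).
* Clade bookkeeping uses 64-bit masks, limiting matrices to 64 taxa —
  ample for the compiled-matrix regime emulated here.
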