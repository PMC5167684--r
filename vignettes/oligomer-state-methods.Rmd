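---
title: "Methods: sequence descriptors and tree benchmarking for FP oligomeric state"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sequence descriptors and tree benchmarking for FP oligomeric state}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oligoFP)
```

## The problem and the modelling approach

Fluorescent proteins (FPs) are either monomeric or oligomeric, and the
distinction decides their usefulness as fusion tags. oligoFP treats the
question as a binary QSPR classification problem: encode each amino acid
sequence as a fixed-length numeric descriptor vector, then learn an
interpretable decision tree mapping descriptors to
`monomer` / `oligomer`. The choice of a tree over stronger black-box
learners is deliberate: the induced rules and the features they use are
themselves the biological readout (which residues and residue
combinations track oligomerization), and the repeated-split protocol
turns "which features does the tree pick" into a stable usage score.

Two assumptions underlie the whole pipeline. First, the oligomerization
signal is (at least partly) encoded in sequence-derived statistics —
compositions, physicochemical profiles, order correlations. Second,
curated FP sets are full of near-identical mutants, so performance
estimates are only meaningful after homology reduction; the pipeline
therefore clusters sequences at an identity threshold before any model
building.

## Descriptor classes

All six classes operate on validated sequences over the 20 canonical
residues and produce deterministically ordered, named features.

* **Composition (8420)** — overlapping k-mer frequencies:
  f(r) = N_r/N, f(r,s) = N_rs/(N−1), f(r,s,t) = N_rst/(N−2). Each block
  sums to 1.
* **Autocorrelation (720)** — for each of 8 AAindex scales
  (CIDH920105, BHAR880101, CHAM820101, CHAM820102, CHOC760101,
  BIGC670101, CHAM810101, DAYM780201; resolved at run time from the
  AAindex catalogue bundled with seqinr), standardized to zero mean and
  unit population SD over the 20 residues, and each lag d = 1..30:
  the normalized Moreau–Broto sum Σ P_i P_{i+d} / (N−d), the Moran
  statistic (deviation products over the sequence variance) and the
  Geary statistic (squared differences over the unbiased variance).
* **CTD (147)** — seven properties, each encoding residues into three
  groups (the standard Dubchak-style groupings, shipped as an auditable
  TSV since the properties are named but the groupings are conventions);
  per property: 3 compositions n_r/N, 3 unordered transition frequencies
  (n_rs + n_sr)/(N−1), and 15 distribution values — the positions, as a
  percentage of N, of the ⌈q·n_r⌉-th occurrence of each group for
  q ∈ {first, 25%, 50%, 75%, 100%}.
* **Conjoint triads (343)** — residues mapped to seven side-chain
  dipole/volume classes ({A,G,V}, {I,L,F,P}, {Y,M,T,S}, {H,N,Q,W},
  {R,K}, {D,E}, {C}); triad counts over length-3 windows,
  max-normalized within the sequence.
* **Quasi-sequence-order (160)** — coupling numbers
  τ_d = Σ d(R_i, R_{i+d})² for d = 1..30 under two residue distance
  matrices, followed by 20 composition and 30 coupling components per
  matrix, all over the shared denominator Σf + w Στ.
* **PseAAC / APseAAC (130)** — type-1 pseudo amino acid composition
  (20 + λ components from the mean squared differences of standardized
  hydrophobicity, hydrophilicity and side-chain mass) and the
  amphiphilic type-2 variant (20 + 2λ components from lagged
  hydrophobicity/hydrophilicity products). The shared denominator forces
  each vector to sum to 1.

### Parameters

| parameter | default | meaning |
|---|---|---|
| lag / λ | 30 | autocorrelation and sequence-order depth (residues); fixed by the canonical block widths (8 × 30 = 240 per autocorrelation kind; 20 + 30 and 20 + 60 for PseAAC/APseAAC). Requires N > 30. |
| w | 0.5 | weight of order terms in QSO and PseAAC denominators |
| identity threshold | 1.00 | clustering threshold; 0.95/0.99/1.00 are the standard grid |
| correlation cutoff | 0.7 | max allowed kept pairwise absolute Pearson r |
| minLeaf / CF | 2 / 0.25 | tree leaf minimum and pruning confidence (documented C4.5/J48 defaults) |
| iterations | 100 | 80/20 split repeats (tests and examples use 10–25 to stay fast) |

### The distance matrices

Two 20 × 20 matrices feed the quasi-sequence-order block. The Grantham
matrix is computed exactly from the published 1974 formula
(50.723·√(1.833 Δc² + 0.1018 Δp² + 0.000399 Δv²)) over packaged
composition/polarity/volume properties. The second matrix,
`physchemSynthetic`, is a **synthetic** physicochemical distance built by
this package — the Euclidean distance over the three standardized
PseAAC scales divided by √3. It plays the structural role of a second
published sequence-order matrix without claiming to reproduce one; all
dimensionalities and invariants are unaffected by this choice, and the
matrices are injectable (`computeQSO(..., matrices = )`) for anyone who
wants to substitute a published table.

## Homology reduction

Greedy incremental clustering in decreasing length order: each sequence
joins the first cluster whose representative identity reaches the
threshold, else founds a cluster, so representatives are always the
longest members (ties keep input order; results are reproducible).
Identity is the number of identical aligned positions of a global
alignment (match +1, mismatch 0, linear gap penalty 1) divided by the
shorter length. A composition bound — no alignment can match more
positions than the summed per-residue minimum counts — soundly skips
candidate alignments that cannot reach the threshold; surviving
candidates are aligned in cluster order, so the first-match rule is
exact, not approximate. The k-mer prefilters of production clustering
tools are out of scope: at hundreds of sequences, exact O(n²) behaviour
is affordable and auditable. At threshold 1.00 the procedure reduces to
exact-duplicate removal for sets without subsequence containment, which
the tests verify against a hash-based oracle.

## Collinearity pruning

Highly correlated descriptor pairs add model complexity without
information. The pruning rule is iterative: find the pair with the
largest absolute Pearson correlation above the cutoff and remove the
member with the larger mean absolute correlation against all remaining
features (ties remove the later column), until no pair exceeds the
cutoff — the post-condition `max |r| ≤ cutoff` over kept features is
asserted in the tests, and an independent solver of the same task
(caret's exact `findCorrelation`) is used as a cross-check. Zero-variance
columns get correlation 0 and are flagged rather than silently dropped.
By default pruning is computed **per iteration on the internal set
only**: computing it on all records before splitting would leak external
information into the modelling pipeline. `pruneScope = "all"` restores
the simpler whole-data variant for comparability.

## The decision tree

Binary numeric splits only (all descriptors are numeric): candidate
thresholds are midpoints between consecutive distinct sorted values,
children must hold at least `minLeaf` rows, and the chosen split
maximizes the gain ratio (information gain over split information; plain
information gain is available via `criterion = "info_gain"`). Ties keep
the first feature in column order and the lowest threshold, so fits are
deterministic. Values exactly at a threshold route left (`<=`).

One growth detail deserves a note. A node at which *no* split has
positive information gain is usually turned into a leaf, but layouts
exist — XOR being the canonical one — where every individual split has
exactly zero gain yet the class is perfectly determined two levels down.
At an impure node with no positive-gain split the implementation
therefore still takes a zero-gain partition (first feature, lowest
admissible threshold). Recursion terminates because both children
strictly shrink, and subtrees that never pay off are collapsed by
pruning, so the practical effect is confined to grid-like data.

Pruning is pessimistic error estimation: the error count of a node is
inflated to its upper binomial confidence bound
`n · qbeta(1 − CF, e + 1, n − e)` (the exact form whose
zero-error case is the textbook 1 − CF^(1/n)); a subtree is replaced by
a leaf when the leaf's bound does not exceed the sum of its leaves'
bounds. Subtree raising is not implemented.

Feature usage — the interpretation layer — is the percentage of
iterations whose induced tree contains the feature. The accompanying
mean ± SD is computed over up to 10 contiguous blocks of iterations:
block-level presence percentages give a dispersion estimate without
re-running the benchmark.

## Evaluation protocol

Each iteration draws a stratified 80/20 internal/external partition
(largest-remainder rounding of per-class counts, seeded as master seed +
iteration). The tree is fitted on the full internal set (train surface),
assessed by stratified tenfold cross-validation on the internal set with
confusion counts pooled over folds (cv surface), and applied to the
untouched external set (external surface). Stratification everywhere is
a deliberate deviation from plain random splitting: on small FP-sized
data sets unstratified folds frequently degenerate to single-class
training sets. Ac, Sn and Sp are percentages; MCC is computed from the
pooled counts with a zero denominator defined as MCC = 0 (the
random-prediction convention, so one-class predictors score 0, not NaN).
The positive class is `monomer` by default and configurable.

## The synthetic generator

`simulateProteins` emulates the *statistical shape* of an FP data set —
two classes, lengths 220–240 (FP-like chain lengths), i.i.d. residues
from a uniform (default, auditable) or Swiss-Prot-like background — with
a controllable class signal: `composition_bias` interpolates the
oligomer class towards a 3× hydrophobic-enriched composition (echoing
the hydrophobic character of real oligomerization interfaces), and
`motif_insertion` plants round(3·strength) copies of chosen tripeptides
into oligomers while scrubbing chance occurrences from monomers, giving
a guaranteed-separable positive control; strength 0 yields identically
distributed classes for null calibration. What the generator does *not*
emulate: phylogenetic relatedness, mutational series, real FP domain
architecture, or chromophore chemistry. Passing the synthetic controls
therefore demonstrates that the machinery is correct and calibrated —
not that any particular accuracy will be reached on curated FP data.

## Numerical conventions and degenerate inputs

* Moran and Geary autocorrelations of a zero-variance property profile
  (homopolymers) return 0 with a warning rather than NaN.
* Composition blocks, PseAAC and APseAAC vectors sum to 1 within 1e-9;
  descriptor values agree with independent naive-loop oracles within
  1e-9 (asserted over random length 35–60 sequences).
* A group absent from a sequence contributes five zeros to the CTD
  distribution block.
* Non-canonical residues are rejected by default with id, position and
  character; an opt-in `drop` policy discards the sequence with a
  warning, since curation conventions for B/J/O/U/X/Z vary.
* Empty confusion tables are an error; MCC with a zero denominator is 0.
* All randomness (splits, folds, simulation) is seed-derived; iteration
  i of a benchmark uses master seed + i, so runs are bit-reproducible
  and individually re-creatable.

## Problem sizes

The shipped tests and the acceptance script run at desk scale by choice:
25 random sequences for the oracle comparisons, 1000 records (250
distinct) for the duplicate-removal equivalence, a 500 × 200 table for
the pruning audit, 100 sequences per class with 25 iterations for the
positive/negative benchmark controls, and 10-iteration
selected-feature runs for determinism checks. The full protocol (100
iterations, all six classes, three thresholds) is a single
`runBenchmark` configuration away and scales linearly in iterations.

## Known limitations

* The tripeptide block (8000 features) makes whole-grid tree induction
  on `aac_dpc_tpc` the slowest cell; the selected-feature mode exists
  precisely because production use only needs the handful of
  high-usage features.
* Identity clustering is exact but quadratic; tens of thousands of
  sequences would need the k-mer prefilter this package intentionally
  omits.
* The second QSO distance matrix is synthetic (see above).
* Single trees have high variance; the repeated-split protocol reports
  it honestly (the SDs) rather than hiding it in an ensemble, but users
  wanting maximum raw accuracy should expect ensembles to do better.
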