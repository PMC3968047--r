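---
title: "Structural class prediction from integrated profile, physicochemical and annotation features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural class prediction from integrated profile, physicochemical and annotation features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(strucclass)
```

## The problem and the model

A protein's structural class — all-α, all-β, α/β or α+β — is a coarse but
valuable summary of its secondary-structure content. `strucclass` predicts
it from three complementary, sequence-derivable information sources, ranks
the pooled features, and classifies with a support vector machine. This
vignette is the package's own account of the modelling choices, their
assumptions, and what the test suite does and does not establish.

### Evolutionary profile block: sigmoid + linear predictive coding

A PSI-BLAST position-specific scoring matrix (PSSM) is an L×20 table of
integer log-odds scores describing, per sequence position, the substitution
propensity toward each residue type. Raw log-odds are unbounded, so every
entry is first mapped through the logistic sigmoid f(x) = 1/(1+e^(−x));
this is monotone and bounded in (0, 1), so positional structure is
preserved while extreme scores are compressed.

Each of the 20 columns is then treated as a one-dimensional positional
signal and summarized by linear predictive coding (LPC), the classical
autoregressive encoding from speech analysis. The order-p predictor
ŝ_t = Σ_{k=1..p} a_k s_{t−k} is fit by the autocorrelation method: the
biased estimate r(k) = Σ_t s_t s_{t+k} enters the Toeplitz normal
equations, solved in O(p²) by the Levinson–Durbin recursion. The predictor
coefficients a₁…a_p are the features; the gain/error term is excluded, so
order p contributes exactly p values and the default order set 3–10 yields
20 × (3+4+…+10) = 1040 dimensions. The coefficients capture *positional
autocorrelation structure* of conservation — information that composition
statistics discard — which is why a row-permuted profile produces a
different block (a tested property).

Numerical conventions, chosen once and tested:

* signal = the column's normalized values in sequence order; no mean
  removal, windowing or pre-emphasis (the simplest reading, and the values
  are already in (0, 1));
* r(0) = 0 (an all-zero signal) returns the zero coefficient vector;
* if the recursion's prediction error underflows (a perfectly predictable
  column), r(0) is regularized by +1e−10 and the solve retried once;
* sequences shorter than max(order) + 1 are a hard error — zero-padding
  would silently corrupt the autocorrelation estimate.

The oracle for all of this is a direct `solve(toeplitz(...))` on the same
normal equations; Levinson–Durbin must agree within 1e−8, and does over
hundreds of random signals in the acceptance suite.

### Physicochemical descriptor block

The 1080-dimensional descriptor block reimplements the familiar
PROFEAT-style descriptor families locally (no web service): amino-acid and
dipeptide composition, three autocorrelation families (normalized
Moreau–Broto, Moran, Geary) over standardized property scales,
composition/transition/distribution (CTD) over three-group physicochemical
partitions, and the sequence-order families SOCN and QSO built on
inter-residue distance matrices.

The precise group composition behind a 1080-dimensional "all features"
vector is not recoverable from any single convention, so the package makes
the preset explicit, configurable, and dimension-checked in closed form
(`preset_dim()`). The shipped default is:

| group | parameters | dims |
|---|---|---|
| aac | — | 20 |
| dpc | — | 400 |
| autocorrelation | 3 types × 7 scales × maxlag 21 | 441 |
| ctd | 7 partitions × (3+3+15) | 147 |
| socn | 2 matrices × maxlag 8 | 16 |
| qso | 2 matrices × (20 + 8), w = 0.1 | 56 |
| **total** | | **1080** |

The seven numeric scales (hydropathy, hydrophilicity, van der Waals volume,
polarity, polarizability, isoelectric point, residue mass) and the seven
CTD partitions are classical tables packaged as code. The autocorrelation
lag of 21 is the one parameter tuned to make the closed-form total come out
at 1080; the SOCN/QSO lag of 8 keeps those descriptors defined for short
sequences (the preset requires L ≥ 22 overall). The two 20×20 distance
matrices are *derived in code* from the packaged scales (Euclidean distance
in standardized property space, scaled to max 1) — they are documented,
deterministic physicochemical distance matrices, not reproductions of any
published table, and every identity the tests rely on (zero diagonal,
symmetry, simplex normalization of QSO) holds for them.

Degenerate-input conventions: Moran and Geary return 0 for a zero-variance
encoded sequence (e.g. a homopolymer); CTD distribution entries are 0 for
an absent group; the distribution quantile for fraction f is occurrence
`max(1, ceiling(f·n))`. Non-standard residues are an error by default, with
an opt-in documented substitution map (B→D, Z→E, J→L, U→C, O→K, X→A).

### Gene Ontology block

GO annotations arrive as GAF 2.x or a two-column TSV. Proteins without any
annotation are discarded (and reported): their annotation vector would be
identically zero, i.e. pure noise for the classifier. The vocabulary is the
set of distinct terms over the (training) dataset, ordered
lexicographically — the ordering is arbitrary in principle, so it is fixed
to the one deterministic choice that is stable across platforms and input
row orders. Encoding a protein against a *frozen* vocabulary ignores unseen
terms (logged); note the deliberate consequence: building the vocabulary on
the full dataset before cross-validation leaks vocabulary membership, which
mirrors the usual per-dataset protocol and is documented rather than
"fixed". No GO-graph ancestor propagation is performed: the table is taken
as given.

### Feature selection

SVM-RFE eliminates exactly one feature per iteration: fit linear one-vs-one
SVMs on the survivors, score feature f by Σ over binary machines of w_f²,
drop the minimum (ties → lowest column index, for determinism). The
multiclass fold-in (summing squared weights across the 6 pairwise machines)
is the standard multiclass extension and is consistent with the one-vs-one
classifier used downstream. Features are standardized once before ranking —
weight magnitudes are scale-dependent, and leaving features on wildly
different scales would make the criterion meaningless. The linear-SVM C
defaults to 1 and is configurable; an optional `step > 1` exists for very
wide matrices but is off by default since it deviates from the
one-at-a-time definition.

The first iteration's criterion is testable against a single independently
fitted linear SVM with identical solver settings; the acceptance suite does
exactly that on a 20×5 problem.

Two evaluation protocols are provided. The default, `rank_once`, ranks
on the full dataset, truncates once to top-k, and jackknifes only the
classifier — this reproduces the conventional rank-then-validate protocol
and carries its optimistic selection bias, which we document rather than
hide. `nested` re-ranks inside every leave-one-out fold; it is unbiased and
correspondingly expensive, and is the right choice when the accuracy
estimate itself is the scientific claim.

### Classifier and evaluation

The classifier is a one-vs-one RBF SVM (libsvm via e1071, 6 binary machines
for 4 classes; one-vs-rest is avoided because its positive/negative sets
are badly unbalanced). (C, γ) are tuned by grid search, by default over the
canonical libsvm grid C ∈ 2^{−5,−3,…,15}, γ ∈ 2^{−15,−13,…,3}, scored by
stratified cross-validated overall accuracy; ties resolve toward smaller C
then smaller γ (weaker regularization pressure, smoother kernel).
Standardization statistics are always computed on training rows only inside
each evaluation fold.

Jackknife evaluation trains N models, each predicting the single held-out
protein. From the pooled confusion matrix we report per-class accuracy
(diagonal over row sum), overall accuracy (trace over N), and per-class
MCC from the binarized counts, with the 0/0 → 0 convention for degenerate
margins. ROC curves are one-vs-rest per class; since the model is
one-vs-one, the per-class score is the sum of that class's signed pairwise
margins (vote-margin aggregation — a documented choice, as probability
estimates are deliberately not used). The macro curve vertically averages
the four curves' TPR on a common 101-point FPR grid with linear
interpolation; AUC is trapezoidal throughout, so the label-flip identity
AUC + AUC′ = 1 holds to machine precision. Note that vote-margin scores are
not calibrated *across* samples, so a model can classify perfectly (every
row-wise argmax correct) while its column-wise ROC stays below 1 — visible
in the synthetic runs and inherent to the aggregation, not a defect of the
curve construction.

## The synthetic-data generator

Real benchmark datasets require PSI-BLAST runs against NR and a GOA
snapshot; the generator instead emulates the full input stack with planted,
recoverable signal so the pipeline is testable end to end:

* **PSSMs:** designated profile columns (the first 6 residue columns by
  default) follow a rounded, clamped AR(1) process whose coefficient is
  class-specific — 0.8, −0.8, 0.4, 0.0 for the four classes — with white
  noise in the remaining columns. AR(1) autocorrelation is exactly what LPC
  measures: the lag-1 predictor coefficient estimates the planted
  coefficient, so the informative features are known by construction
  (`planted_feature_names()`).
* **GO:** each class has a marker term carried by 90% of its proteins
  (enrichment 0.9), plus class-independent background terms
  (Poisson-distributed count, mean 2, from a 36-term pool); a configurable
  fraction of proteins is left unannotated to exercise the filtering path.
* **Sequences** are uniform random 120–200-mers: composition itself is
  deliberately *uninformative*, so the descriptor block acts as a realistic
  nuisance block and each signal-bearing block can be credited separately.

Defaults (25 proteins per class, the AR coefficients and enrichment above)
are the package's study conditions for the end-to-end checks. Everything is
a deterministic function of the seed, to the point of byte-identical output
files.

What passing these tests shows: the implementation recovers signal of the
kind each block is designed to carry, at realistic noise levels, and the
full chain (extract → rank → truncate → tune → jackknife) is wired
correctly. What it does not show: performance on real proteins. Real PSSMs
have position-dependent, residue-correlated structure, real GO annotation
depends on study bias and the DAG, and real class boundaries (α/β vs α+β
especially) are far subtler than an AR-coefficient contrast. Benchmark
accuracies must come from benchmark data.

## Problem sizes and numerical choices in the checks

The packaged checks run on one CPU in a few minutes; sizes were chosen as
the smallest that still exercise every code path at study conditions:
end-to-end runs use 100 proteins (25 per class), LPC orders 3–6 with the
compact aac+dpc descriptor preset (~820 integrated features before
ranking), top-50 truncation, a 3×3 sub-grid for (C, γ), and leave-one-out
over all 100 proteins. The dimension checks use the full default
configuration (orders 3–10, 1080-dim preset). Monte-Carlo null checks
(permuted-label MCC, random-score AUC) use 50 replicates. The selection
contrast uses 50 seeded replicates of an 80-sample, 20-feature dataset in
which two features are jointly separating but individually ~uninformative
(class signal in their difference, masked by a shared noise component);
this is the construction under which a backward-eliminating multivariate
ranker provably can, and a univariate F-score provably cannot, credit the
pair — a literal XOR labelling would defeat a *linear* ranking criterion
too, so the realizable form of the claim is tested.

## Known limitations

* The `rank_once` protocol's selection bias means its jackknife
  accuracy is an optimistic estimate whenever top-k < all features; use
  `nested` for unbiased numbers.
* The GO vocabulary is dataset-scoped; transferring a model to proteins
  annotated under a much newer GO release will silently ignore new terms
  (it logs, but cannot impute). Homology-based GO imputation is out of
  scope.
* Checkpoint/binary PSSM formats are not parsed — only the ASCII dialect.
* The packaged distance matrices are computed from the packaged property
  scales rather than taken from published sequence-order tables; rankings
  of QSO/SOCN features may therefore differ from implementations built on
  those tables.
* Vote-margin one-vs-rest scores make macro-AUC conservative relative to
  calibrated probability outputs.
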