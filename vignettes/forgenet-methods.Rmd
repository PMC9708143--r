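---
title: "Compound activity screening with forest graph-embedded networks"
author: "forgeNet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compound activity screening with forest graph-embedded networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(forgeNet)
```

# The problem

Given a table of compounds known to be active or inactive against a disease
target (actives typically defined by a potency cut-off such as IC50 below
5000 nmol/L, inactives by property-matched decoys), we want a classifier that
(i) copes with a few hundred to a few thousand samples described by several
hundred correlated molecular features, and (ii) can then rank unlabelled
candidate compounds — for example the constituents of a herbal prescription —
by predicted activity.

forgeNet (forest graph-embedded deep feedforward network) addresses the
dimensionality problem by letting a tree ensemble decide which feature-feature
interactions the network is allowed to use: the first layer of a deep
feedforward classifier is connectivity-restricted to a *feature graph* mined
from a fitted random forest.

# The model

## Featurization

Each compound enters as a SMILES string and is converted to a 374-dimensional
vector: 208 molecular descriptors followed by the 166 MACCS substructure keys.
The descriptor set is frozen in a shipped manifest
(`inst/extdata/descriptor_manifest_208.txt`) so the feature dimension cannot
drift with toolkit versions. It covers:

* whole-molecule OpenBabel properties (molecular weight, exact mass, logP,
  molar refractivity, TPSA, hydrogen-bond donor/acceptor counts);
* element, bond, charge and ring counts;
* Kier–Hall connectivity indices $\chi_0$–$\chi_4$ (simple and valence),
  kappa shape indices, Wiener, Harary, Balaban J, Zagreb, Platt, eccentric
  connectivity, graph radius/diameter and Petitjean shape;
* Moreau–Broto, Moran and Geary autocorrelations at topological lags 1–8 over
  atomic mass, electronegativity, covalent radius and polarizability;
* 44 SMARTS fragment counts (functional groups and carbon environments).

MACCS keys are computed from OpenBabel's SMARTS definitions and emitted as
keys 1–166 (the unused key 0 of the 167-bit convention is dropped). On the
package's fixture molecules the resulting bit sets are identical to RDKit's
implementation, with a single caveat: aromaticity models differ on fused
rings carrying exocyclic carbonyls (on caffeine the two toolkits disagree on
key 125, "more than one aromatic ring"). Distance-based descriptors of
disconnected structures (salts) are computed per component and summed;
degenerate quantities (single atoms, zero-variance properties) are defined as
zero rather than NA, and `cleanMatrix()` imputes any remaining non-finite
value by the column median.

No scaling happens at featurization time. Standardization is owned by the
network trainer and is computed on training folds only, which keeps repeated
cross-validation free of leakage.

## Feature graph construction

A random forest with $p$ trees is fitted to the labelled training matrix.
Every tree is read as a directed graph over *features*: for each internal
node $u$ and each internal child $c$ of $u$, the edge
$(\mathrm{split}(u), \mathrm{split}(c))$ is recorded. Leaves hold predictions,
not features, and contribute nothing; a parent and child splitting on the
same feature produce the self-pair $(f, f)$. The per-tree graphs are combined
by set union — duplicate edges collapse, there are no edge weights — and the
union is realized as a binary $d \times d$ mask.

Two realization options matter and are exposed:

* **Symmetrization** (default on): a first-layer weight mask has no
  meaningful direction, so $(u,v)$ also switches on $(v,u)$.
* **Self-loops** (default on): the diagonal is set to one so that every
  feature feeds its own first-layer unit. Without this, a feature the forest
  never split on would be erased from the network entirely.

## The graph-embedded network

With mask $G$, input $X$ (standardized), and elementwise activation
$\sigma$ (rectifier by default; sigmoid and tanh are supported):

$$Z_1 = \sigma\!\left(X (W_{in} \odot G) + b_{in}\right), \qquad
  Z_{k+1} = \sigma\!\left(Z_k W_k + b_k\right), \qquad
  \hat y = \mathrm{softmax}\!\left(Z_{out} W_{out} + b_{out}\right)$$

The Hadamard product $\odot$ forces $W_{in}$ to be $d \times d$ — one hidden
unit per feature. The mask is applied *inside* the forward pass, not by
post-hoc zeroing, so a masked slot contributes exactly zero to every
prediction and receives exactly zero gradient; perturbing such a slot
provably cannot change the output (this is asserted by a test).

Training minimizes class-weighted cross-entropy by mini-batch
adaptive-moment (Adam) gradient descent. The class weighting default is
*balanced* (inverse prevalence), because the target tables are roughly one
active per 5.6 inactives and the metrics of interest (Cohen's kappa, Matthews
correlation) reward a balanced operating point.

# Tunable parameters

| Parameter | Default | Notes |
|---|---|---|
| forest size `ntree` | 500 | graph densifies as `ntree` grows (see below) |
| feature subsampling `mtry` | $\lfloor\sqrt d\rfloor$ | forest convention |
| node size / `maxnodes` | 1 / unlimited | grow to purity |
| hidden sizes | 64, 16 | after the mandatory $d \times d$ masked layer |
| activation | relu | sigmoid, tanh available |
| learning rate | $10^{-3}$ | Adam |
| epochs | 100 | sigmoid needs more on tiny batch counts |
| batch size | 32 | training size must be at least this |
| L2 penalty | $10^{-4}$ | on all weights |
| dropout | 0.1 | hidden activations, training only |
| class weighting | balanced | `none` available |
| decision threshold | 0.5 | on the active-class probability |
| activity threshold | 5000 nmol/L | strict inequality (`<`) |

None of the network hyperparameters are claims about the method's source —
they are this package's defaults, chosen as ordinary values for a network of
this size, and all are in `netConfig()`.

# Graph density and the interpretability regime

The mask is a set union over all trees, so its density grows monotonically
with forest size and tree depth. At the reference benchmark size
($n = 966$, $d = 100$, 10 informative features), 500 unlimited-depth trees
visit essentially every feature and the union saturates: about 9 of every 10
possible feature pairs become edges, and the fraction of edges touching the
informative set falls to the uniform baseline. The classifier is unaffected —
a dense mask simply approaches an ordinary dense first layer — but the
*graph itself* stops being informative.

Graph recovery is therefore demonstrated (tests, acceptance script) in an
explicitly sparse regime: `ntree = 100`, `maxnodes = 7`, `mtry = d/2`.
Shallow trees rarely chain two uninformative splits, and a larger `mtry`
ensures informative features are available at almost every split. In that
regime roughly 93% of mask edges touch the 10-feature informative set
(uniform expectation: 19%). Users who want to read the mask as a feature
interaction map should fit a second, shallow forest for that purpose rather
than reuse the deep 500-tree ensemble that maximizes classification
performance.

# The synthetic benchmark

Real activity tables of this kind are assembled from database extracts that
cannot be redistributed, so the package generates benchmarks with the same
statistical shape (`generateTabular()`):

* $n = 966$ samples, $d = 100$ features; features 1–10 form the informative
  set $S$ and are correlated along a chain graph. The covariance is built as
  the inverse of a precision matrix with off-diagonal weight $-0.4$ on graph
  edges and a diagonally dominated diagonal, which guarantees positive
  definiteness by construction.
* Labels are Bernoulli draws from a logistic model on $S$ with same-sign
  coefficients of magnitude 2; the intercept is solved numerically so the
  expected prevalence matches a 5.6:1 inactive:active ratio (the shape of a
  146-active / 820-inactive table; a 1403-sample, 6.27:1 preset mirrors the
  second table size). Coefficients share a sign because alternating signs on
  positively correlated features cancel marginally, leaving a signal no tree
  or linear learner can see at realistic sizes.
* The effect size was fixed once so that standard classifiers reach held-out
  ROC-AUC near 0.93 — the operating band observed on real tables of this
  kind — and is not adjusted per experiment. At these settings forgeNet's
  held-out ROC-AUC averages about 0.93 over ten seeds, and about 0.51 under
  the zero-effect null.

What the generator deliberately does *not* emulate: discrete/binary feature
blocks (MACCS-like columns), heavy-tailed descriptor distributions,
activity cliffs, and the property-matched structure of real decoys. Passing
the synthetic benchmark shows the estimator and protocol work when the
model's assumptions hold; it does not certify performance on any particular
chemical series.

A toy bioactivity generator (`generateBioactivityTable()`) draws potencies
log-uniformly on each side of the 5000 nmol/L threshold and records its own
below-threshold count, giving the activity filter an exact self-reported
oracle.

# Evaluation protocol

`crossValidate()` implements stratified k-fold cross-validation for
$k \in \{3, 5, 10\}$ (any $2 \le k \le n$ works) and leave-one-out, each with
repeated reshuffling (10 repeats by default) driven by per-repeat seeds.
Folds are stratified by class — at a 1:5.6 imbalance unstratified small folds
can lose the minority class entirely — and the two classes receive their
remainder folds in opposite order, so 966 samples at $k = 3$ split into
exactly 322/322/322. Each fold's model, including its forest and its
standardization statistics, is fitted on the training split only.
Leave-one-out pools the $n$ held-out predictions of a repeat into one metric
row, since per-fold confusion tables are undefined at fold size one.

Metrics use the standard definitions: SN = TP/(TP+FN) on the active class,
SP = TN/(TN+FP), binary F1 on the active class, Matthews correlation, and
Cohen's kappa. A metric whose denominator degenerates to zero is reported as
0 and flagged rather than NA, so aggregation never silently drops folds.
ROC and PR curves are evaluated at every distinct score threshold with
trapezoidal areas; the PR staircase is anchored at the smallest attained
recall. The "Mean ± SD" aggregate uses the $n-1$ SD over all fold × repeat
rows. Tests pin the implementations to independent oracles: exhaustive
concordant-pair counting for ROC-AUC, the Pearson correlation identity for
MCC, and an external kappa implementation.

Baseline adapters (`baselineAdapter("rf" | "lr" | "nb")`) wrap a random
forest, logistic regression and naive Bayes behind the same fit/score
contract for side-by-side protocol runs. Re-implementations of further
boosted/stacked comparators are out of scope.

# Screening

`screenCompounds()` scores featurized candidates with a trained model and
assigns dense ranks 1..n by descending active-class probability, breaking
ties by input order so ranks are reproducible. `aggregateRanks()` averages
ranks across models trained on different targets (arithmetic mean) and sorts
ascending; "ranks last on average" is operationalized as the maximum mean
rank. The shipped 20-compound candidate file carries compound names with an
empty, user-suppliable SMILES column (curated structures for these natural
products are not bundled) plus clearly-labelled synthetic stand-in structures
that tests and examples use.

# Numerical choices and degenerate inputs

* Masked first-layer slots are held at exactly zero by masking both the
  forward pass and the gradient; reloaded models predict identically to
  within text round-trip precision (weights persist as full-precision text).
* Softmax is computed with the row-max subtracted; cross-entropy clamps
  probabilities at $10^{-12}$; a non-finite epoch loss aborts with a
  diagnostic instead of returning garbage.
* Zero-variance features standardize with SD 1 (they become constant zero).
* Single-class labels are rejected up front (no splits, no loss signal).
* Probability ties in ranking resolve by input order; duplicated compounds
  get adjacent ranks.
* Invalid SMILES never abort a batch: each record is parsed independently,
  failures are returned as a rejected-ids report. (The underlying toolkit's
  batch converter silently truncates at the first bad record, which is why
  parsing is per-molecule.)

# Problem sizes used by tests and the acceptance script

Featurization checks run on a dozen small drug-like molecules. Network and
protocol tests use toy problems of 24–300 samples. The headline properties
are computed at the reference benchmark size ($n = 966$, $d = 100$): ten
seeds for the signal recovery average, twenty for the null calibration, ten
(tests) or five (script) for the feature-set ablation, and three for the mask
concentration average. These sizes are the package's documentation of its
own reference protocol.

# Known limitations

* Descriptor values are not numerically interchangeable with any other
  toolkit's 208-descriptor list; only the feature *count* and the TPSA spot
  value are cross-toolkit invariants. Models should be trained and applied
  with this package's featurizer only.
* OpenBabel's aromaticity perception differs from other toolkits on some
  fused heteroaromatics, which can flip individual MACCS keys and the
  aromatic-count descriptors.
* The mask saturates under large deep forests (see above); the feature graph
  is interpretable only in the shallow-forest regime.
* Binary classification only; multi-class targets and potencies in units
  other than nmol/L are out of scope.
* The pure-R training loop is adequate for $d$ in the hundreds and $n$ in the
  thousands (seconds per fit at the reference size) but is not a GPU deep
  learning stack.
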