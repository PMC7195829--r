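---
title: "Predicting extracellular matrix proteins from hybrid sequence features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting extracellular matrix proteins from hybrid sequence features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Extracellular matrix (ECM) proteins — collagens, laminins, proteoglycans and
their many associated factors — form the secreted scaffold around cells.
Proteomics studies of tissue ECM need a theoretical reference list of which
human proteins are ECM components, and curated resources cover only part of
the space. `ecmscout` frames the question as binary sequence classification:
given a protein sequence, its domain annotations and an evolutionary profile,
how probable is it that the protein is an ECM component?

The training corpus this design targets is heavily imbalanced — on the order
of five hundred experimentally supported ECM proteins against eleven thousand
intracellular negatives, roughly 1:21 — which drives two central choices:
an under-sampling ensemble for training and balanced accuracy as the headline
metric.

## Feature construction (63 + 24 + 80 = 167)

**ECM domain flags (63).** ECM proteins are multidomain and their domain
architecture is strongly conserved, so membership of curated ECM-associated
domain families is the single most biological feature family. For a catalog
of 63 domain accessions $D_1,\dots,D_{63}$ and a protein with annotated
domain set $A$, feature $i$ is

$$X_i = \begin{cases} 0 & D_i \in A \\ 1 & D_i \notin A \end{cases}$$

i.e. 0 marks *presence*. `domain_features()` implements exactly this
convention by default and offers a documented `presence` polarity switch;
tree ensembles are invariant to the polarity of a binary feature, so the
choice cannot change classification results. Annotations come from an
offline protein-to-domain table rather than live database queries, for
reproducibility.

**Physicochemical means (24).** Each of 24 amino-acid indices (AAIndex-style
tables assigning one value per residue) is averaged over the sequence:
$PP = \frac{1}{L}\sum_{i=1}^{L} \mathrm{AAIndex}_i$. Unknown residues (`X`)
carry no index value; they are skipped and $L$ reduced accordingly, the
smallest-surprise treatment of real database sequences. An all-`X` sequence
is an error rather than a silent `NaN`.

**PSSM descriptor (80).** A position-specific scoring matrix from iterative
profile search (3-iteration PSI-BLAST at E ≤ 0.001, produced externally and
consumed as ASCII files) gives an $L \times 20$ integer matrix $E_{ij}$ of
per-position substitution scores. It is compressed to a fixed 80-vector in
two steps:

1. *Standardization*: elementwise logistic squashing
   $f(E) = 1/(1+e^{-E})$, mapping scores into $(0,1)$. Strict positivity is
   required by the grey model's cumulative sum; the logistic is the standard
   choice in PSSM-feature work. (A per-protein z-score was the considered
   alternative; it does not guarantee positivity and was rejected.)
2. *Summary*: per column, the mean (20 values) plus the three coefficients of
   a second-order grey model GM(2,1) fitted to the standardized column
   treated as a short series (3 × 20 = 60 values). For a series
   $x^{(0)}$, with accumulation $x^{(1)}(k)=\sum_{i\le k}x^{(0)}(i)$,
   differences $\alpha(k)=x^{(0)}(k)-x^{(0)}(k-1)$ and background values
   $z^{(1)}(k)=\tfrac12(x^{(1)}(k)+x^{(1)}(k-1))$, the coefficients
   $(a_1,a_2,b)$ solve the least-squares system with rows
   $[-x^{(0)}(k), -z^{(1)}(k), 1]$ against $\alpha(k)$.

The GM(2,1) system is solved with the minimum-norm pseudo-inverse
(`MASS::ginv`): a constant column makes the target vector zero and the
minimum-norm solution is then exactly $(0,0,0)$, so degenerate inputs are
legal rather than fatal. The grey-model construction is the one established
for PSSM descriptors in the protein-classification literature; it is isolated
behind `pssm_features()` so an alternative summary could be swapped in
without touching any other module. Proteins shorter than 4 residues are
refused — the fit needs at least three difference rows.

The assembled vector (`extract_features()`) has a fixed global name order:
catalog accessions, property names, `pssm_mean_01..20`, then
`(gm_a1, gm_a2, gm_b)` per residue column.

## Feature selection: mRMR + IFS

Features are ranked by maximum-relevance minimum-redundancy in the
*difference* (MID) form, the canonical default of the mRMR family: the first
pick maximizes $I(f;c)$; each later pick maximizes
$I(f;c) - \frac{1}{|S|}\sum_{s \in S} I(f;s)$ over the already-selected set
$S$. Mutual information is the plug-in estimate in bits on discretized
features: binary features pass through unchanged, continuous features are
three-binned at mean ± 1 SD — the standard mRMR preprocessing for
protein-feature tables. Ties break by input column order, making the ranking
fully deterministic.

Incremental feature selection (`ifs_evaluate()`) then evaluates the nested
top-$k$ subsets with the full cross-validation protocol, reusing **one** fold
partition for all subset sizes so that the curve isolates the effect of $k$
from fold noise. The optimal subset (`select_optimal()`) is the smallest $k$
attaining the maximum balanced accuracy — better performance with fewer
features. A `max_k` truncation supports desk-scale runs; the default
evaluates every $k$.

## The under-sampling ensemble

With a 1:21 class ratio a single classifier buys accuracy by sacrificing
sensitivity. Instead, the negatives are shuffled and split into
$K = \lfloor n_{neg}/n_{pos} \rfloor$ *disjoint* near-equal subsets (sizes
differing by at most one, leftovers appended round-robin); base learner $j$
is a random forest trained on all positives plus negative subset $j$, so
every learner sees an approximately balanced problem while the ensemble as a
whole uses every negative exactly once. Disjoint coverage — rather than
independent random under-samples — is what lets the ensemble use the full
sample information. Predicted ECM probabilities are the unweighted mean of
the learners' probabilities (soft voting), which yields the continuous score
that the strict `> 0.7` rule later thresholds for high-confidence calls; a
hard majority vote would not.

Base learners use the conventional defaults of the random-forest engine:
500 trees and `mtry = floor(sqrt(p))`, both configurable. Learner $j$ trains
under a seed derived from the master seed by a fixed affine hash
(`derive_seed`), so ensembles are bit-reproducible while learners stay
decorrelated.

Classification labels a protein ECM at probability ≥ 0.5; the
*high-confidence* flag requires probability strictly above 0.7 (a probability
of exactly 0.7 is labeled ECM but not flagged).

## Evaluation protocol

Stratified 10-fold cross-validation: per-class fold counts differ by at most
one, and for each fold a fresh ensemble is trained on the other nine folds —
the negative partition is drawn *inside* that training split, so held-out
data can never influence training (a canary test asserts that flipping the
labels of a held-out fold leaves that fold's predictions bitwise unchanged).
Held-out predictions are pooled and one report is computed:
$Sn = TP/(TP+FN)$, $Sp = TN/(TN+FP)$, $Acc = (TP+TN)/n$,
$BAcc = (Sn+Sp)/2$. Pooling (rather than averaging per-fold metrics) is the
stable choice when a fold holds only ~50 positives. Metrics are kept at full
precision; reports round to 4 decimals at presentation time only.

`imbalance_experiment()` reproduces the classic imbalance demonstration:
training sets at ratios 1:1 … 1:21 (all positives plus $r \cdot n_{pos}$
negatives sampled without replacement), cross-validated with a *single*
forest — no ensemble, so the raw damage of imbalance is visible — and
averaged over repeats. The expected signature is specificity rising,
sensitivity falling, and balanced accuracy declining with the ratio; the
ensemble-vs-single comparison is the `cross_validate` path with `K = "auto"`
versus `K = 1` on identical folds.

## The synthetic data generator

Real training data needs externally computed PSSMs, so the package ships a
generator (`generate_dataset()` / `simulate_labeled_features()`) that
emulates the statistical structure the features assume, with class-dependent
signal in all three families:

* domain assignment: each catalog domain independently with probability
  `p_domain_pos` (default 0.10) in positives vs `p_domain_neg` (0.005) in
  negatives — positives are multidomain and essentially always carry at
  least one catalog domain, negatives rarely do;
* composition: positives shift `composition_shift` (0.15) of probability
  mass toward Gly/Pro/Cys, a collagen-like enrichment, on top of natural
  background frequencies;
* conservation: positive-class PSSMs receive a mean offset `pssm_signal`
  (2.0) on four designated columns; scores are discretized normal (SD 3)
  clipped to [−10, 10], the typical PSI-BLAST log-odds range.

Defaults are 100 positives vs 2100 negatives — the 1:21 imbalance of the
realistic corpus — with sequence lengths 50–300 and a 0.2% `X` rate. Under
this default condition the full pipeline reaches held-out balanced accuracy
at or above 0.9 in 10-fold cross-validation, the desk-scale stand-in for
corpus-scale performance claims.

Two deliberate departures from the default are used in the trend
experiments. A *null* condition (equal domain probabilities, zero shift and
signal) must and does yield BAcc ≈ 0.5. An *attenuated-signal* condition
(`p_domain_pos` 0.03 vs 0.015, shift 0.04, signal 0.5, 40 vs 840 proteins)
deliberately overlaps the classes: a near-perfectly separable dataset cannot
exhibit imbalance degradation (every ratio would score ≈ 1.0), so the
imbalance sweep and the ensemble-vs-single comparison are run where the
learner is imperfect, which is the regime the experiments are about.

What passing these tests does *not* show: synthetic PSSMs have independent
rows and columns, whereas real profiles carry strong positional and
inter-column correlation; synthetic domain assignments are independent
Bernoulli draws, whereas real domain architectures co-occur; and the
synthetic catalog/property fixtures are stand-ins with the right shape, not
the curated lists. Desk-scale results therefore validate the machinery and
the directional claims, not corpus-scale accuracy values.

## Numerical and design notes

* Grey-model fits and the mutual-information estimator are each checked
  against independent brute-force oracles (explicit SVD pseudo-inverse;
  joint-histogram summation) to 1e−8 over a thousand random instances.
* Discretization statistics (mean, SD) are per-feature over the supplied
  matrix; a zero-variance feature collapses to one code and contributes zero
  information rather than an error.
* All randomness flows from a single seed: fold assignment, negative
  shuffling, per-learner seeds and the generator are deterministic functions
  of it, and identical seeds give byte-identical primary outputs.
* Desk-scale problem sizes used by the test suite and the acceptance script:
  100–150 trees per learner (500 is the analysis default), 2–10 simulation
  seeds per trend, repeats = 2 in the sweep. These sizes keep the suite fast
  while leaving every directional conclusion unchanged.
* Proteins whose profile search returns no hits (an empty PSSM) are refused
  with an explicit message rather than imputed — there is no principled
  zero-information default for the descriptor.

## Known limitations

The 80-D PSSM construction and the mRMR variant are the established
literature choices for this family of predictors, but other summaries
(e.g. per-protein z-scoring, MIQ-form mRMR) are plausible; both are isolated
behind single functions. The shipped domain catalog and property table are
synthetic stand-ins — corpus-scale reference performance (balanced accuracy
≈ 0.91 with the top 151 of 167 features) additionally requires the curated
catalogs and real PSI-BLAST profiles, and is documented here as a reference
number, not reproduced at desk scale.
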