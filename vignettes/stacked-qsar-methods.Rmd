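---
title: "Stacked ensemble QSAR classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stacked ensemble QSAR classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Given only SMILES strings and assay potencies, decide whether a small
molecule antagonizes a protein target — the motivating application is the
progesterone receptor (PR), a steroid nuclear receptor whose antagonists are
of interest in breast and gynecological cancer. Compounds with
IC50 ≤ 1 µM count as active, ≥ 10 µM as inactive; the 1–10 µM band is
excluded from modelling as ambiguous. Both thresholds are inclusive of their
class, reading the convention literally.

## The model

`molstack` implements stacked generalization over a grid of
fingerprint-based classifiers:

1. **Baseline layer.** Twelve molecular fingerprint families (AP2D, Circle,
   CKD, CKDExt, CKDGraph, Estate, FP4, FP4C, Hybrid, KR, MACCS, PubChem) are
   crossed with six algorithms — ridge logistic regression (LR), partial
   least squares (PLS), k-nearest neighbours (KNN), RBF support vector
   machine (SVM), extremely randomized trees (ET) and random forest (RF) —
   giving 72 baseline models. Each is tuned by tenfold cross-validated MCC
   over its search grid (`n_estimators` ∈ {20, 50, 100, 200, 500} for
   ET/RF, `C` ∈ {0.001, …, 100} for LR, `C` ∈ {1, 2, 4, 8, 16, 32} for SVM;
   KNN and PLS use defaults). Features are min–max normalized to [0, 1] with
   scalers fitted on training rows only; out-of-range test values are
   clipped.

2. **Probabilistic features.** Every baseline emits a predicted confidence
   (PF) in [0, 1] per compound. A compound's 72-dimensional PF vector is the
   concatenation over the baseline grid in its fixed enumeration order.
   Training-set PFs come from **out-of-fold** predictions under one shared
   stratified tenfold assignment — the fold model that predicts a compound
   never saw it — so the meta learner cannot exploit in-sample optimism.
   Test-set PFs come from full-training refits. An `insample` mode exists
   for comparison but is not the default.

3. **GA-SAR selection and the meta forest.** A chromosome carries 72 binary
   selection genes plus a 3-bit parametric gene whose MSB-first value,
   taken modulo 5, indexes the meta random forest size in
   {20, 50, 100, 200, 500} (the modulo makes all 8 codes decode). A repair
   operator enforces 5 ≤ Σ genes ≤ 20 with exactly deficit/excess many
   flips. Fitness is the tenfold-CV MCC (pooled out-of-fold class
   predictions) of a random forest with the chromosome's decoded size on the
   selected PF columns. Independent GA runs are aggregated by a
   self-assessment report: the per-column frequency of appearing in each
   run's best chromosome. Columns are ranked by frequency, ties broken by
   the mean fitness of evaluated chromosomes containing the column, and the
   ranking is truncated at the cardinality in [5, 20] whose refitted CV MCC
   is highest. The final predictor is a random forest on the selected
   columns; probability ≥ 0.5 calls a compound active (the exact tie goes to
   the positive class).

## Design choices in the open corners

Several details are not fixed by the method description; the
package resolves them as follows and treats them as its own design.

* **GA numerics.** Population 50, 100 generations, tournament size 3,
  uniform crossover at rate 0.8, per-gene mutation 1/75, elitism 1, 10
  independent runs. All are exposed in `gasar_config()`.
* **Parsimony tie-break.** When a candidate ties the best-so-far fitness,
  the chromosome with fewer selected features wins. On strong signal the CV
  MCC saturates and many gene sets tie; without parsimony the reported best
  chromosome is an arbitrary early winner padded with uninformative genes,
  which blunts the self-assessment report. Preferring the smaller set at
  equal accuracy matches the purpose of a selection stage.
* **Truncation ties.** When several cardinalities tie on refitted CV MCC
  (again common at saturation), the largest tied cardinality is kept: the
  SAR ranking has already ordered the columns by evidence, and retaining
  more of that ranked evidence is the conservative choice for regimes where
  the extra columns do carry signal the refit could not resolve.
* **Fitness forest size.** Fitness is evaluated with the chromosome's own
  decoded `n_estimators`, so selection and size are optimized jointly.
* **SVM confidences.** Decision values are mapped through a Platt-style
  sigmoid fitted by logistic regression on the fold's training rows. The
  usual libsvm probability machinery draws from an unseeded internal RNG,
  which would break the package's determinism guarantees.
* **PLS as a classifier.** Regression on the 0/1 label with 2 components;
  predictions clamped to [0, 1] serve as the PF.
* **Ridge LR under ties.** Grid ties resolve to the smaller parameter;
  for LR that is the strongest regularization, so on easily separable data
  its PFs hover near 0.5 while still ranking compounds correctly. This is a
  property of the tie rule, not a defect; downstream forests consume the
  ranking.
* **Duplicate structures.** After salt stripping and canonicalization,
  repeated structures collapse to one record with the geometric-mean IC50.
* **Tautomers.** Standardization is salt stripping plus Open Babel canonical
  SMILES, which normalizes aromaticity and atom order. No enumeration-based
  canonical tautomer is computed; that is a documented limitation of the
  toolkit layer.

## Fingerprint backends

MACCS (166 keys) and FP4/FP4C (the first 307 functional-group SMARTS, as
bits and as match counts) are computed exactly from Open Babel's published
pattern sets. Circle is Open Babel's ECFP4 — a radius-2 circular
fingerprint — folded from 4096 to 1024 bits. CKD uses Open Babel's linear
path fingerprint (paths up to 7 atoms, 1024 bits). AP2D hashes atom-pair
descriptors to 780 bits. The remaining families (Estate 79, KR 4860,
PubChem 881, CKDExt/CKDGraph/Hybrid 1024) are deterministic hashed
atom-type, environment or path fingerprints at the widths PADEL-style
tables use; they are labelled approximations because the original key
definitions belong to a Java toolkit whose tables are not reproduced here.
The four CDK-path families require an explicit `allow_approx = TRUE` (or a
precomputed table via `load_precomputed_fingerprints()`, which validates
width and value type). Every family contract — width, binary/count type,
determinism — holds for both backends, and the stacking layer is agnostic
to which one produced a matrix. All hashed families use one fixed
polynomial hash with per-family salts, so outputs are reproducible across
runs and platforms.

## What the synthetic generators emulate

`make_synthetic_pf()` emulates the PF layer directly: informative columns
are centred at 0.5 ± `effect` by class with Gaussian noise, clipped to
[0, 1]; the rest are Uniform(0, 1). The between-class mean difference of an
informative column is 2·`effect` before clipping. `make_synthetic_compounds()`
emits structurally unique, valid molecules from a scaffold × decoration
pool with IC50s drawn log-uniformly inside each class's range, so labels
round-trip exactly through curation. These fixtures test the machinery —
leak-freedom, selection, calibration of the pipeline — not chemistry: the
synthetic labels are independent of structure, so passing tests say nothing
about predictive power on real SAR data, and the planted PF signal is far
cleaner than real baseline confidences.

## Benchmark scales and numerical choices

The planted-recovery benchmark defaults to its study conditions: 400
training and 150 test compounds, 72 PF columns with 8 informative
(effect 0.35, noise 0.1), GA population 30 × 40 generations. A single
replicate at that scale costs a few minutes of CPU, so the shipped test
suite and the acceptance script run the same benchmark at a reduced scale —
5 seeds, population 20, 12 generations, one GA run per seed — which the
experiments behind this vignette show recovers a median of 7–8 of the 8
planted columns across disjoint seed sets. Chromosome fitness values are
cached within `run_gasar()` (the population converges and re-evaluations
are pure waste); the cache also guarantees that identical chromosomes get
identical fitness within a run. At `effect = 0.35, noise_sd = 0.1` a single
informative column separates the classes almost perfectly, so CV MCC
saturates at 1 — the regime in which the parsimony and truncation tie rules
above do the discriminating work.

Degenerate inputs are rejected early: empty chromosomes cannot be scored
(repair first), folds with a single class raise a stratification error,
single-class inputs make ROC AUC an error rather than a silent 0.5, and a
zero denominator in MCC returns 0 by the no-information convention.

## Known limitations

* Native Estate/KR/PubChem bit *identities* differ from the original
  published key sets (widths and semantics class match; exact tables can be
  supplied precomputed). Models trained on native and precomputed matrices
  are therefore not interchangeable with each other.
* No applicability-domain machinery beyond what a user can build from the
  PF layer; predictions far outside the training chemistry are extrapolation.
* The curation step expects exported assay tables; there is no database
  client, and replicate aggregation is limited to the geometric-mean rule.
* Runtime scales linearly in the 72-model grid; the full grid with tenfold
  tuning on hundreds of compounds is minutes-scale, and GA-SAR dominates
  end-to-end cost through its CV-per-chromosome fitness.
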