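---
title: "Correlation-guided swarm feature selection for essential protein prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-guided swarm feature selection for essential protein prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Essential proteins are those whose loss is lethal to an organism. In a
protein–protein interaction (PPI) network, essentiality correlates with many
node-level quantities — hubs tend to be essential, as do proteins in many
complexes or in particular subcellular compartments — and supervised
classifiers built on such features predict essentiality reasonably well. The
catch is redundancy: most topological centralities measure closely related
things and are strongly mutually correlated, and feeding a learner a pile of
near-duplicate columns rarely helps.

This package implements a wrapper feature-selection strategy built around a
binary Flower Pollination Algorithm (FPA) with an *elite search* mechanism
(ESFPA), together with everything needed to exercise it end to end: feature
extraction from a PPI network and annotation sources, a correlation-derived
"gold standard" of distinct features, balanced-dataset construction by
undersampling, and a seven-learner voting classifier evaluated under
repeated stratified cross-validation. A synthetic-data generator supplies
desk-scale study inputs so the full pipeline is testable without any
external database.

## Features

Eighteen feature columns are assembled per protein:

* **Topological (6):** degree (DC), eigenvector (EC), subgraph (SC),
  information (IC), local average connectivity (LAC) and neighbourhood
  centrality (NC). SC is the diagonal of the matrix exponential of the
  adjacency matrix; IC follows the Stephenson–Zelen current-flow
  construction, computed per connected component by inverting `L + J`
  (isolated nodes score 0); EC is the entrywise non-negative principal
  eigenvector, L2-normalised per component (power iteration on `A + I`, so
  bipartite components also converge); NC sums the edge clustering
  coefficient `ECC(u,v) = triangles(u,v) / (min(deg u, deg v) - 1)` over
  incident edges, with a 0 convention when the denominator vanishes. The
  exact NC/IC variants are stated here because the literature has several;
  the package pins these and tests them against independent numerical
  oracles (truncated walk series, eigen-residuals, literal pairwise
  current-flow sums).
* **Annotation-based (8):** the GO score (sum over network neighbours of the
  term-set intersection size — term identifiers are opaque; all GO branches
  are pooled, since nothing in the scoring depends on the branch), the
  module score (number of complexes containing the protein), and six
  subcellular compartment columns. Compartment `c` carries weight `w_c`,
  the share of all localization *assignments* of the standard essential
  proteins that fall in `c` (assignments, not distinct proteins, so
  multi-localised essentials contribute to each of their compartments); a
  protein scores `w_c` if annotated to `c`, else 0. Preprocessing keeps the
  top `k = 6` compartments by `w_c` (descending, ties broken by name),
  which mirrors discarding the less predictive compartments.
* **External (4):** precomputed hybrid predictors (orthology-,
  expression- and domain-based scores such as ION, PeC, WDC, UDoNC) enter
  as externally supplied columns; their internal formulas are out of scope.
  The synthetic generator fabricates stand-ins so the 18-column layout is
  reproducible.

## The gold standard of distinct features

Let `cc_ij` be the Pearson correlation between feature columns `i` and `j`
(defined as 0 when either column is constant; constant columns are flagged
in a message so users can drop them upstream). The *correlation value* of
feature `i` is

    cv_i = sum_{j != i} |cc_ij| / (fn - 1),

the mean absolute correlation with every other feature. Features are sorted
by ascending `cv` (ties broken by original column order) and the first
`floor(gold_fraction * fn)` — two-thirds by default, so 12 of 18 — form the
**gold standard** of "distinct" features. `floor` is used so the rule
extends to feature counts not divisible by three. Note what this objective
is and is not: it rewards *non-redundancy only*. A pure-noise column is
maximally distinct under it; relevance to the labels never enters. This is
a property of the method itself and is visible in the experiments below.

## The optimizer

Each candidate subset ("pollen") is a continuous position `x` in `R^D`
(one dimension per feature, encoded in ascending-`cv` order so the leading
dimensions are the most distinct features) with a derived binary mask. Per
iteration each pollen takes, with switch probability `p = 0.8`, the global
branch `x + L (x - G*)` with Lévy-distributed step magnitudes `L` (Mantegna
sampler, tail index `lambda = 1.5`, truncated below at `s0 = 0.01`), or
otherwise the local branch `x + mu (x_j - x_k)` with `mu ~ U(0, 1)` and two
population peers. The position is binarized through the transfer function
`S(x) = 1/(1 + e^x)` thresholded against fresh per-bit `U(0, 1)` draws. The
decreasing orientation of this sigmoid is unusual (most binary swarm
methods use `1/(1 + e^-x)`); it is the package default for faithfulness to
the method's printed form, and because thresholds are uniform and positions
sign-synchronised it only flips which sign encodes selection — the standard
orientation is available via `sigmoid_orientation = "standard"`.

**Fitness.** A mask is scored against the gold standard by the confusion
counts TD/FD/TI/FI (true/false distinct/indistinct):

    Fperformance = (TD + TI) / fn
    fitness      = alpha * Fperformance + (1 - alpha) / |N|,   alpha = 0.8

where `|N|` is the subset size. The empty mask is invalid (sentinel -1) and
is never accepted as a global best. For gold size `m`, enumeration shows
the optimum is always a prefix of the gold set, and the full gold mask is
the unique optimum exactly when `m = 1` or `alpha/fn > (1 - alpha)/m` (the
binding competitor is the single most-distinct feature alone); at the
default `m = floor(2 fn / 3)`, `alpha = 0.8` this always holds, so the
optimizer's target is the gold mask and an exhaustive-search oracle can
verify convergence.

**Elite search.** Over the leading `ceil(cons * D)` positions
(`cons = 2/3`), bits that disagree with the global best `G*` trigger the
update rule: the continuous position is assigned `cons * G*` there and the
bit re-binarized. This pulls every pollen toward `G*` over the most
informative window while leaving genuine exploration noise in place. A
fully deterministic bit copy (`elite_mode = "bitcopy"`) is also provided,
but it is not the default for a structural reason: if every candidate's
window is forced identical to the global best's window, then under greedy
acceptance no candidate can ever *change* the global best's window bits,
which freeze at their initial values — the position-level rule keeps the
window explorable and is what makes the optimizer reliably reach the
exhaustive optimum.

**Acceptance.** A pollen is replaced only when its fitness improves
(greedy), so per-pollen fitness and the best-so-far trace are
non-decreasing by construction; the reported result is the global best
after `max_iterations`. Population 20, 100 iterations (300 in the
package's own experiments), and the `p`, `lambda`, `s0` values above are
conventional swarm-literature defaults; all are configurable and every run
is fully determined by `(seed, config, inputs)`.

## Classifier and evaluation

Proteins are labelled essential or non-essential (unknowns are excluded
upstream). Because non-essentials dominate, balanced datasets are built by
keeping every positive and drawing an equal-sized uniform sample of
negatives; 10 repeats share the positives and differ only in the drawn
negatives. Following the single-dataset protocol, evaluation defaults to
the first balanced dataset (the repeats are statistically exchangeable;
`evaluate_all_repeats = TRUE` evaluates each).

The voting classifier averages the predicted class probabilities of seven
members and calls the positive class at 0.5: naive Bayes; a linear SVM
with Platt-calibrated probabilities; an information-gain decision tree; a
ridge-regularised logistic regression; a random forest (100 trees); a
single fully randomised (extra-trees) tree; and a cost-complexity-pruned
decision tree. Four members are nearest-standard-equivalents of learners
whose reference implementations live in a Java ecosystem (logistic model
trees, SMO, random tree, reduced-error-pruning tree); per-learner outputs
are therefore not expected to reproduce any external tool's cells, only
the ensemble protocol. Evaluation is stratified k-fold cross-validation
(fold sizes differ by at most one per class), pooled over held-out folds
(micro averaging), repeated with fresh fold assignments and averaged.
Reported metrics: TP rate, precision, recall, F-measure, MCC, and AUC
computed as the Mann–Whitney rank statistic on the ensemble probability
(hence invariant under monotone score transforms). Zero-denominator ratios
report 0 with a `degenerate` flag. In the averaged report the F-measure is
the harmonic mean of the report's own averaged precision and recall, so
the printed triple is always internally consistent.

## The synthetic study generator

The generator emulates the statistical structure the pipeline assumes,
not any particular organism's data:

* **Network:** preferential attachment (`n = 800`, `m = 3`, giving mean
  degree ~6, comparable to a curated yeast interactome) plus triadic
  closure (`clustering_p = 0.15`): real PPI networks are far more
  clustered than plain preferential attachment, and without triangles the
  LAC and NC columns would be degenerate zero-variance features.
* **Labels:** essentiality log-odds `a + 0.6 z(log deg) + u`, `u ~ N(0,1)`
  a latent propensity, with intercept `a` calibrated by root-finding so
  the expected essential fraction is 0.23 (the share of essentials among
  the yeast proteins the method was designed around); labels are then
  flipped with probability 0.05 to emulate annotation error.
* **Annotations, conditional on labels:** enriched compartments have
  essential-to-nonessential localization rate ratios (nucleus 3.0 down to
  golgi 1.8 over six compartments, on base rates 0.12–0.05 across eleven);
  interacting pairs share GO terms (probability 0.25, 0.4 if both
  essential), making the GO score degree-flavoured; complex membership is
  degree- and essentiality-weighted; external stand-ins mix standardised
  log-degree, the latent propensity and unit Gaussian noise.

The design places the eighteen columns in two blocks: six compartment
indicator columns that are mutually nearly independent (the *planted
informative* features), and a strongly intercorrelated degree-flavoured
block (six centralities, GO, module, four externals). That is exactly the
redundancy structure the correlation gold standard is designed to exploit,
and it is what real PPI feature sets look like. What the generator does
*not* emulate: biological identity of nodes, realistic GO term hierarchies
and semantics, the size of real interactomes, assortativity and
date/party-hub structure, or correlated noise between annotation sources.
Tests passing on these fixtures therefore certify the method's internal
logic and statistical behaviour, not organism-level performance.

## Experiments the package runs on itself

The test suite and `scripts/acceptance.R` recompute, from scratch:

* closed-form fitness values (gold mask: `0.8 + 0.2/12`; all-ones:
  `0.8 * 2/3 + 0.2/18`);
* optimizer-vs-exhaustive agreement for `fn` in {8, 10, 12} (population
  20, 300 iterations, 20 seeds each);
* exhaustive gold-optimality under the exact condition above (50 random
  instances, `fn <= 14`);
* centrality agreement with independent oracles (20 random graphs,
  `n <= 30`, tolerances 1e-8/1e-6);
* the duplicate-column property: appending an exact copy of a column
  raises that column's `cv` and expels both copies from the gold set;
* planted-feature recovery: on default studies, ESFPA run with
  `gold_fraction = 1/3` — the subset size matched to the six planted
  features — attains Jaccard >= 0.8 against the planted set in >= 80% of
  20 seeds. The size matching is deliberate: with the default two-thirds
  fraction the selected subset has 12 members by construction, so its
  Jaccard index against a 6-member planted set can never exceed 0.5;
  asking the selector for a 6-member subset is the meaningful recovery
  question, and `gold_fraction` is an explicit configuration field;
* selection harmlessness: on studies whose five external columns are pure
  noise, the cross-validated F-measure on the ESFPA-selected subset stays
  within 0.02 of the all-features baseline (5 seeds). Note the selected
  subset *retains* the noise columns — they are maximally distinct under
  the correlation objective — and sheds the redundant centralities
  instead; this is the honest behaviour of a redundancy-only criterion;
* balanced-dataset invariants, including pairwise Fisher independence
  checks of the negative draws.

Problem sizes (n = 800 studies, 10–20 seeds, 300 iterations, 10-fold
cross-validation with 1–3 runs) were chosen as the smallest at which the
statistical claims are stable.

## Numerical and degenerate-input conventions

* Zero-variance feature columns: correlation 0 against everything, so they
  rank maximally distinct; flagged via a message.
* `gold_size` rounding: `floor`; sorting ties: stable original column
  order; compartment-weight ties: name order.
* Empty selection mask: fitness sentinel -1, never a global best.
* Lévy steps: truncated below at `s0`, so `L > 0` always.
* Isolated nodes: EC and IC 0, SC 1, LAC and NC 0, GO score 0.
* Protein identifiers are opaque, case-sensitive strings assumed
  pre-harmonised across input files; no identifier normalisation is
  attempted.
* Cross-validation requires at least `k` members per class; a fold that
  would lose a class is impossible under stratified assignment.
* `cv` ranking is computed on the assembled (post-preprocessing,
  18-column) table.

## Known limitations

* The correlation gold standard measures redundancy, not relevance; it
  will happily keep pure-noise features (demonstrated in the tests).
  Pairing it with a relevance filter is sensible future work.
* Four ensemble members are stand-ins for learners with no exact R
  equivalent; per-member behaviour differs from the originals even though
  the ensemble protocol is faithful.
* The decreasing printed sigmoid and the position-level elite rule are one
  concrete reading of a loosely specified update; both alternatives are
  behind configuration flags (`sigmoid_orientation`, `elite_mode`).
* Real-data adapters (database-specific formats, identifier mapping) are
  out of scope; inputs must already be in the package's simple dialects.

```{r example}
library(esfpa)
spec <- synthetic_spec(seed = 5)
study <- synthetic_dataset(spec)
cfg <- esfpa_config(seed = 5, max_iterations = 300)
sel <- esfpa_run(study$features, cfg)
sel$selected_features
ds <- labeled_dataset(study$features, study$essential_ids,
                      features = sel$selected_features)
bal <- build_balanced_datasets(ds, n_repeats = 10, seed = 5)
cross_validate(make_hybrid_classifier(), bal[[1]], k = 10, n_runs = 3, seed = 5)
```
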