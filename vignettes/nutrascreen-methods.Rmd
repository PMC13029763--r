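---
title: "Methods: ligand-based screening of food chemical space"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ligand-based screening of food chemical space}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope

`nutrascreen` implements a complete ligand-based virtual-screening analysis
for a metabolic enzyme target: curation of public-database-style bioactivity
records into binary interaction labels, structure canonicalization and
deduplication, Bemis–Murcko scaffold-grouped data splitting, circular
fingerprint classification with seeded tuning, calibration and threshold
selection, applicability-domain (AD) analysis, feature attribution with
substructure mapping, R-group series summaries, and ensemble screening of a
compound library with Butina diversity selection. Structure-based stages
(docking, molecular dynamics) are out of scope: the pipeline ends at the
prioritized shortlist.

Because the real inputs of such a study are large external snapshots, the
package ships a first-class synthetic-data module that emulates their data
regime with known ground truth. Every downstream stage is tested against
that ground truth.

## The model and its assumptions

Activity records report a concentration (IC50/Ki/Kd/EC50) in nM or µM. After
filtering (exact relations, confidence ≥ 7, positive numeric values, valid
flags), concentrations are standardized to nM and transformed to
`pActivity = 9 − log10(value_nM)`, the negative decadic logarithm of the
molar concentration (1000 nM ↔ 6.0 exactly). Per compound the *maximum*
pActivity is retained — the most favourable reported interaction — and the
binary label is positive iff the aggregate is ≥ 6.0 (inclusive, i.e. ≤ 1 µM
potency). Only IC50-derived records feed labeling; other assay types pass
the record filter but take no further part, since the analysis defines no
other use for them.

Molecules are represented as binary circular fingerprints (radius 2, 2048
bits, no chirality) computed on canonical isomeric SMILES, so any two SMILES
dialects of a molecule share one bit vector. Classifiers (random forest,
penalized logistic regression, gradient boosting) operate on these vectors;
the underlying assumption is that interaction propensity is carried by
recurring local atom environments that transfer across scaffolds. Scaffold
splitting is exactly the evaluation of that assumption: all molecules
sharing a Bemis–Murcko scaffold stay in one subset, so test performance
measures generalization to unseen chemical series, not memorization.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `pactivity_threshold` | 6.0 (log10 units) | inclusive label boundary, 1 µM |
| `min_confidence` | 7 | assay confidence filter |
| fingerprint | radius 2, 2048 bits | fixed between training and screening (hash-checked) |
| split fractions | 0.8 / 0.1 / 0.1 | compound-count targets for train/val/test |
| split seeds | 1, 2, 3 | independent scaffold permutations |
| `n_iter`, `cv_folds` | 25, 5 | randomized search budget, stratified CV |
| AD threshold | 0.35 | inclusive max-Tanimoto in-domain cutoff |
| similarity bins | 0–.2, .2–.35, .35–.5, .5–.7, .7–1 | error-analysis strata, half-open, last closed; the 0.35 edge aligns with the AD onset |
| scaffold-frequency bins | 0, 1, 2–5, 6–20, ≥21 | train+val occurrences of a test scaffold |
| calibration bins | 10 equal-width on [0,1] | empty bins omitted, counts conserved |
| explain / background | ≤ 2000 / ≤ 200 | attribution sample caps, drawn without replacement under the split seed |
| Butina cutoff | 0.35 | sphere-exclusion distance (1 − Tanimoto) |
| `top_n`, pair support | 200, ≥ 3 | screening head; minimum support for an R1×R2 grid cell |

Random-forest fixed-budget defaults are 300 trees, `mtry` = 5 % of bits and
a minimum node size of 5 — ordinary probability-forest settings; the
randomized search explores 200–800 trees, 2–20 % `mtry`, node sizes 1–10 and
subsampling 0.632–1.0.

## What the synthetic generator emulates

Each synthetic compound is a ring-system core (one of `n_scaffold_families`
distinct Murcko scaffolds, enumerated deterministically from aromatic units
chained up to four rings) carrying two pool substituents (R1 on the head
ring, R2 on the terminal ring). The latent activity is
`base + Σ motif effects + N(0, noise_sd)`; by default a sulfonamide
substituent adds +1.5 log units, a carboxamide +0.8, a carboxyl −0.7, on a
base of 5.2 with noise SD 0.3. Records report
`IC50 = 10^(9 − (latent ± record noise))` nM; 30 % of records are converted
to µM, compounds receive Poisson(0.4) replicate records, 5 % of records have
inexact relations (">"), 2 % unparsable SMILES from a fixed list, and 5 %
hydrochloride salt forms. These rates were fixed once as a realistic public
extract regime and are never adjusted per run.

Because substituents are acyclic, every family member shares its core's
scaffold, so scaffold splits operate on families; and because motif effects
attach to substituents shared *across* families, the signal is learnable on
unseen scaffolds — the property the scaffold-split evaluation is meant to
probe. The screening library mixes fresh in-family compounds with aliphatic
decoy chemotypes (verified to fall below the 0.35 AD threshold against the
aromatic training space), plus duplicates, salts and invalid rows.

What the generator does **not** emulate: assay-format heterogeneity beyond
Gaussian noise, correlated replicate errors, activity cliffs, tautomer and
charge-state ambiguity, stereochemistry, and the strongly positive-skewed
class balance of real curated extracts (the synthetic set is
positive-minority at the default base). Passing tests therefore demonstrate
correctness of the machinery and recoverability of planted structure, not
real-data performance; the headline numbers of any specific real study are
out of reach by construction.

## Numerical and design choices

- **Chemistry backend.** Parsing, canonical isomeric SMILES and bulk
  properties (MW, logP, HBD, HBA, TPSA) come from OpenBabel via ChemmineOB.
  Circular fingerprints, Murcko scaffolds, ring/rotatable-bond counts,
  R-group decomposition and Butina clustering are implemented in the
  package on a molfile-derived molecular graph; the fingerprint keeps its
  bit→(atom, radius) map so substructure attribution is exact by
  construction. Implicit hydrogens are recovered from a standard-valence
  model for the organic subset, which is sufficient for the chemistry the
  pipeline generates and audits.
- **Scaffold definition.** Iterative pruning of terminal atoms, then atoms
  multiply bonded to the retained framework are kept (a linker carbonyl
  oxygen stays; an acetyl side chain goes). Acyclic molecules get the empty
  scaffold, which forms one shared split group. The scaffold examples are
  cross-checked in the test suite against an independent reference
  implementation.
- **Split assignment.** Groups are ranked by size, permuted under the seed,
  and assigned greedily to the subset whose *compound* count is furthest
  below target (ties: train > val > test). This is deterministic per seed,
  never splits a group, and converges to the target fractions as group
  granularity shrinks; deficit is measured in compounds because the
  fractions refer to compounds. A sequential fill (train until 80 %, then
  val, then test) was considered and rejected: it systematically starves
  the tail subsets of large groups.
- **Thresholds.** Candidate decision thresholds are 0 and 1 plus midpoints
  between consecutive sorted unique out-of-fold probabilities — the
  coarsest set that realizes every achievable confusion matrix on the OOF
  sample. Ties in the criterion go to the smallest candidate. The selected
  threshold is frozen before touching test data.
- **Metric conventions.** AUC is the rank statistic with ties counting ½;
  AP is the step-wise precision–recall area over unique thresholds (order
  independent under ties); predicted positive means probability ≥
  threshold; MCC is 0 when a confusion marginal is empty; balanced accuracy
  drops absent-class terms so one-class strata still report a number;
  AUC/AP in one-class strata are explicit NA markers. All-zero versus
  all-zero fingerprints have Tanimoto 0 (avoids 0/0).
- **Attribution.** The explainer is matched to the family: an exact
  path-dependent TreeSHAP (compiled, with node covers reconstructed by
  routing the background set through each tree; zero-cover branches carry
  no expectation mass, preserving additivity) for random forests, the
  boosting library's own TreeSHAP for gradient boosting (log-odds scale),
  closed-form linear attributions for logistic models (link scale), and a
  seeded permutation-sampling estimator as fallback. A fingerprint bit may
  encode several environments; all are reported rather than guessing one.
- **R-group decomposition.** The series core is the modal Murcko scaffold
  (ties: higher mean score, then lexicographic SMILES). Members are matched
  to the core by color-constrained subgraph isomorphism; among symmetric
  matches the lexicographically smallest decomposition is used, so
  equivalent members decompose identically. Substituents are canonicalized
  with a single dummy-atom attachment convention; absent substituents count
  as hydrogen so position counts always sum to the series size. The
  minimum series size defaults to 10 (unstated in the source analyses;
  configurable).
- **Embedding.** The 2-D chemical-space map reduces fingerprints by PCA
  (≤ 50 components) and then applies Kruskal non-metric MDS, a
  neighbourhood-free nonlinear embedding chosen for determinism and zero
  extra dependencies. It is reporting plumbing: only shape, forced
  inclusion of top-ranked candidates, and seeded determinism are
  contractual, never coordinate values.
- **Butina tie-breaks.** Equal neighbour counts resolve by higher ensemble
  score then identifier; ranking ties resolve by identifier. Both choices
  exist purely for determinism.
- **Screening AD reference.** Training-stage AD is evaluated per seed (each
  test set against its own train+val); the screening stage instead pins one
  fixed reference — the seed-1 train+val set — so the whole library carries
  a single domain definition alongside its ensemble scores. In/out counts
  partition the library by construction.

## Problem sizes

The default synthetic study uses ~2000 compounds in 60 scaffold families
(≈1300 unique structures after deduplication), seeds 1–3, and a screening
library of ~1500 rows. The test suite exercises the full pipeline at
120–250 compounds and the attribution stage at 250 explained samples per
seed with a 200-row background; these sizes were chosen so that every stage,
including the exhaustive oracles, runs comfortably on a single CPU while
keeping all planted-signal checks well-powered.

## Known limitations

- The valence model covers the organic subset (B, C, N, O, P, S, halogens,
  common counterions); exotic elements or charge states would need
  extension.
- Aromaticity is handled through Kekulé structures from the canonicalizer;
  fingerprint invariance across dialects is guaranteed by canonicalizing
  first, not by aromaticity perception.
- No tautomer or charge standardization beyond largest-fragment keep.
- The sampling attribution fallback has Monte-Carlo error and looser
  additivity than the exact tree/linear paths.
- The neural-network family of the original workflow is not registered;
  the harness accepts any family implementing the sample/fit/predict
  contract.
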