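---
title: "Methods: comparative metabolomics of hydroxyanthracene herbal drugs"
author: "hadmet package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative metabolomics of hydroxyanthracene herbal drugs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hadmet)
```

## Scope and model of the data

`hadmet` compares the untargeted LC--MS/MS metabolite profiles of four
anthraquinone-containing botanical drugs — Cascara (*Rhamnus purshiana*
bark), Frangula (*Rhamnus frangula* bark), Rhubarb (*Rheum palmatum* root)
and Senna (*Cassia angustifolia* leaves) — each measured in technical
triplicate. The pipeline consumes vendor feature-table exports (one row per
detected feature with compound name, formula, precursor $m/z$, neutral
monoisotopic mass, retention time, maximum peak area, ionization mode,
reference-database matches, MS2 availability and MSI confidence level),
never raw spectra: peak picking, alignment and spectral matching are
upstream, vendor-side steps. Column dialects differ between export
versions, so reading goes through a small mapping (`cd_dialect()`) from
internal field names to column headers; one default dialect ships with the
package.

## Annotation screening

A feature is retained when five rules all hold:

1. **Database confirmation** — at least one match among mzCloud, mzVault,
   Metabolika, ChemSpider, MassList;
2. **Mass accuracy** — $|(m/z_{obs} - m/z_{theo})/m/z_{theo}| \cdot 10^6
   \le 3$ ppm, with $m/z_{theo}$ derived from the neutral mass assuming
   $[M+H]^+$ / $[M-H]^-$ (proton mass 1.007276 Da); other adducts are out
   of scope because annotated exports already resolve adduct grouping;
3. **Retention window** — 5–50 min by default, replaceable by an extended
   0–120 min window for unusual gradients;
4. **Minimum peak area** — default $1.0 \times 10^5$ instrument counts.
   The threshold is fully configurable; a literal threshold of
   $10^{-5}$ counts would retain every real peak and make the rule
   vacuous, so the package defaults to the physically meaningful
   magnitude while leaving the value open to the user;
5. **MS2 availability** — an MS/MS spectrum must exist for the feature.

Each rule is a pure predicate, so the retained set is independent of rule
order; only the attribution of a failing record to a rule depends on order,
which is fixed (db, ppm, rt, area, ms2) to make reports deterministic.
Records missing a field an active rule needs are excluded and counted
separately, so `n_pass + sum(failures) + errors = n_input` always holds.
MSI confidence levels follow the evidence hierarchy: authentic standard
plus MS2 → level 1; accurate mass plus MS2 database match → level 2. The
source text groups the remaining features as "levels 3/4"; the package
splits them monotonically by evidence — database hit without MS2 → 3,
neither → 4.

## Molecular graphs

Each annotated structure enters the classifier as a heavy-atom graph built
from its SMILES (OpenBabel via ChemmineR). Node features: element, degree,
hybridization, formal charge, aromaticity. Edge features: bond type
(single/double/triple/aromatic) and conjugation. Three derivations are
package conventions worth stating precisely:

* **Aromaticity** is perceived on rings of up to eight atoms; all bonds
  within an aromatic ring are typed aromatic (the SDF intermediate is
  kekulized, so ring perception restores the aromatic typing).
* **Hybridization** is derived from the bond pattern: any triple bond or
  two doubles → sp; any double bond or aromatic membership → sp2;
  otherwise sp3 for main-group organics and "other" elsewhere. This
  bond-order heuristic agrees with valence-model assignments on the
  natural-product chemotypes the package targets.
* **Conjugation** flags bonds whose two endpoints are both sp/sp2 — a
  deliberate simplification that covers aromatic systems and alternating
  ene/carbonyl chains, and marks an isolated C=C as conjugated with itself
  (harmless for learning, since the underlying bond pattern is also in
  the features).

Hydrogens stay implicit and stereochemistry is ignored: neither
contributes features in this featurization, and the classification targets
are constitution-level. Categorical features are one-hot encoded against a
vocabulary built from the training set (elements plus an "other" bucket,
degrees 1–6, four hybridization states, charges −1/0/+1/other); edge
features enter the node representation as counts of incident bond types
and conjugated bonds. The vocabulary is persisted with trained models so
inference always uses the training layout.

## The per-level GIN classifier

One Graph Isomorphism Network is trained per hierarchy level (pathway,
superclass, class). A layer computes
$H' = \mathrm{MLP}\big((1+\varepsilon)H + AH\big)$
with a two-layer ReLU MLP; after the final layer, node states are
sum-pooled per molecule and mapped linearly to class logits with a
softmax. Sum aggregation with shared node transformations makes the whole
map invariant to atom input order — the property the test suite checks
numerically. The network is implemented directly in dense/sparse linear
algebra with hand-derived backpropagation and full-batch Adam; molecules
are processed as one block-diagonal sparse adjacency, which keeps training
a few seconds per fold at desk scale.

Defaults (`gin_hyper()`): 3 layers, hidden width 32, dropout 0.1,
Adam at $10^{-2}$, 60 epochs, $\varepsilon = 0$. Training runs a fixed
epoch budget rather than early stopping: with full-batch optimization on
desk-scale data the loss trajectory is smooth, a fixed budget keeps
cross-validation deterministic given the seed, and it avoids carving a
second validation split out of already small folds. All of it is exposed
in configuration; the acceptance surface is property-based (label
recovery, chance-level nulls, permutation invariance), not weight
matching, so architecture constants are not load-bearing.

Model selection and reporting use stratified 10-fold cross-validation:
each class is shuffled and dealt round-robin over folds with a rotating
offset, so per-fold class counts are within one of $n_c/k$. Performance is
macro-averaged F1 (each class weighted equally) and accuracy, reported per
fold with mean ± sd; the final model is refit on all data. A single
integer seed fixes fold assignment, weight initialization and the dropout
stream; per-fold seeds are derived as `seed + fold`. Confidence is the
maximum softmax probability per level. The three levels are trained
independently; hierarchical consistency (predicted class's parents equal
the predicted superclass and pathway) is checked post hoc, with an
optional stricter decoding that masks class logits to children of the
predicted superclass. Classes with fewer than 10 examples can be merged
into per-superclass "other" buckets (`merge_rare_classes()`) so
stratification stays meaningful. Curation follows the confidence flags:
`flag_low_confidence()` queues predictions whose minimum per-level
confidence falls below a threshold (0.99 by default, where assignments
above it are almost invariably confirmed) or whose hierarchy is
inconsistent, ascending by confidence.

## Expert concordance

A predicted superclass is confirmed when it equals the expert label after
case/whitespace folding — exact match, no synonym resolution, because the
superclass vocabulary is closed. Published per-species concordance
percentages of this kind are not always reconcilable with their own raw
fractions, so the report always carries the raw counts next to the
percentage and supports both denominator conventions for compounds the
expert did not label: counted as unconfirmed (default) or excluded.

## Comparative statistics

Compound identity across species is the normalized name
(case/whitespace/punctuation-folded); molecular formulas are never the
key, since positional isomers such as Aloin A/B share a formula. A
compound belongs to a species when it passed screening in at least one
replicate; duplicates within a species collapse to one entry, keeping the
higher-area ionization mode when both polarities detected the same name.

* **Venn regions**: every union compound is assigned to the exact subset
  of species containing it; the $2^k - 1$ region counts partition the
  union. A superclass-level variant (`by = "superclass"`) is provided for
  the class-set view of the same comparison.
* **Distribution table**: superclass × species counts with per-species
  percentages; column sums equal the per-species compound totals.
* **Abundance matrix**: union compounds × (species × replicates), zeros
  where a compound was not detected — absence is informative
  presence/absence, not missingness, so nothing is imputed.
* **PCA**: samples are observations, compounds variables; default
  preprocessing is autoscaling (per-compound z-score), constant rows are
  dropped and logged, and explained variance is reported relative to the
  retained total. Pareto and no scaling are available; no row filtering
  is applied by default because upstream tools differ silently on it.
* **HCA**: agglomerative clustering of samples on Euclidean distance,
  average linkage by default (ward/complete available), on the same
  scaled matrix as PCA so both views describe one geometry. `stats::hclust`
  supplies the merge tree; ties resolve by its leaf-index convention.
* **Heatmap matrix**: superclass × replicate counts of detected
  (area > 0) compounds — raw counts, not normalized — with rows and
  columns ordered by average-linkage Euclidean clustering.

Figures (score plot, dendrogram, heatmap, pies) are side effects of these
computed results, never the data of record. No univariate or supervised
testing is performed anywhere: all cross-species comparisons are
exploratory and descriptive, so no p-values or FDR control appear.

## The synthetic-data module

Every pipeline input can be generated with a known ground-truth ledger,
which is what the test suite and the acceptance script run on.

* `generate_cd_table()` emits vendor-shaped feature rows. Each row is
  planted to pass all five screening rules or to fail exactly one
  (mutually exclusive, default rates db 5%, ppm 10%, rt 5%, area 5%,
  ms2 5% — mass accuracy being the dominant real-world failure). Passing
  rows draw ppm error uniformly within ±80% of the tolerance, retention
  times inside 6–48 min, and lognormal areas clipped above the floor;
  violating rows are placed unambiguously outside the respective gate.
  Mutual exclusivity keeps the ledger arithmetic exact: per-rule failure
  counts are predictable without running the pipeline.
* `generate_labelled_molecules()` substitutes hydroxyl, methoxy, methyl,
  a glycosyl stand-in, or H at the marked positions of four scaffold
  templates (flavone, anthraquinone, cinnamate, stilbene — the dominant
  chemotypes of these drugs), enforcing uniqueness; labels are inherited
  from the family. The families are graph-separable by construction,
  which is what makes "cross-validated macro-F1 ≥ 0.90" a property of a
  correct implementation rather than a tuned outcome.
* `generate_species_profiles()` realizes a Venn-region design exactly.
  The default design fixes the regions the study reports — a 4-compound
  core (carrying the names Phloretin, Kaempferol, Hispidulin,
  4-Heptyloxyphenol), 21 Cascara∩Frangula with 10 exclusive, 13
  Senna∩Rhubarb with 5 exclusive, and totals 93/83/83/51 — and
  distributes the remaining freedom once (triple overlaps 4/3/2/2,
  remaining pairs 3/2/3/1, singles 65/56/60/32). Per-species superclass
  counts are planted to equal the study's distribution table exactly:
  shared compounds are Flavonoids (except the aromatic-polyketide core
  compound), species-unique compounds fill the remainder, and the
  generator validates feasibility. Peak areas are lognormal
  (multiplicative MS intensity noise, replicate sd 0.15 on the log
  scale) around per-compound loadings on two latent species axes — one
  separating Senna from the rest, one spreading the other three — so
  species separate in PCA score space.

What the generator does **not** emulate: raw spectra, chromatographic
peak shapes, isotope patterns, adduct multiplicity, correlated annotation
errors, or batch drift. Passing tests therefore demonstrate correctness
of the screening logic, the classifier, and the comparative statistics on
cleanly planted structure — not robustness to vendor-side artifacts of
real acquisitions.

### A note on PCA variance concentration

With the default (study-shaped) region design, most compounds are unique
to one species. After autoscaling, each such row is a centered indicator
of its species, and with four species those indicators span a
three-dimensional space with roughly balanced weight, so the first two
components cannot carry 90% of the variance no matter how strong the
planted mean shifts are. The latent two-axis structure expresses itself
only through compounds shared across species. The package therefore
demonstrates the "strong mean shifts concentrate variance on two axes"
property under an all-shared design (`shared_region_design()`), where
PC1+PC2 exceed 90%, and reports the default-design PCA as what it is: a
three-axis presence/absence geometry.

## Problem sizes and numerical choices

The shipped defaults are chosen for desk-scale runs: 1000-row screening
tables, 300 molecules (3 families × 100) for classifier validation,
four species × three replicates (252 union compounds) for the
comparatives. On one CPU the full test suite and the acceptance script
each complete in minutes, the classifier cross-validation dominating.
Numerical conventions: softmax is computed with max-subtraction;
cross-entropy clips probabilities at $10^{-12}$; prediction ties break by
label order; PCA drops zero-variance rows before scaling; all RNG flows
from one user-visible integer seed, and model fitting saves/restores the
global RNG state so it never perturbs the caller's stream.

## Known limitations

* The classifier validates on synthetic scaffold families; published
  trained weights for real natural-product corpora are not reproduced,
  and confidence is raw softmax (no calibration).
* Adduct handling is limited to protonation/deprotonation; isotope and
  adduct regrouping is assumed done upstream.
* Compound identity is name-based; two species annotating the same
  structure under different names will not intersect.
* The concordance report cannot adjudicate which denominator convention
  produced any given published percentage; it reports both.
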