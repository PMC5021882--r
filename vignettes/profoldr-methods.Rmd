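---
title: "Multi-view fold classification: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view fold classification: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(profoldr)
```

## The problem and the model

Assigning a protein to a structural fold class is a multi-class problem in
which no single representation of the protein is decisive. `profoldr`
builds four *views* of each protein and combines them late, at the
probability level:

* **DSSP view (40D)** — descriptors of the eight-state secondary-structure
  string parsed from a DSSP file;
* **AAsCPP view (188D)** — amino-acid composition plus
  composition/transition/distribution (CTD) descriptors under eight
  physicochemical groupings;
* **PSSM view (20D)** — column means of the PSI-BLAST log-odds profile;
* **FunD view** — binary occupancy over a fixed functional-domain
  universe, set where a hit's expect value is at most 0.001.

Training proceeds per view: a roster of base classifiers is scored by
stratified k-fold cross-validated overall accuracy Q = C/N on that view's
feature matrix, the argmax entry is selected, and the winner is refit on
the full matrix. Prediction averages the per-view class posterior
probabilities and takes the argmax. The implicit assumptions are (i) that
views err on partly disjoint subsets of proteins, so averaging suppresses
individual mistakes, and (ii) that the per-view posteriors are comparable
enough in scale for a plain mean — which is why every roster adapter must
return row-stochastic matrices over a single fixed class ordering (rows
are renormalized defensively, with a uniform fallback for degenerate
all-zero rows).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k_folds` | 5 | CV folds for selection; reduced (never below 2, with a warning) when the smallest class is smaller |
| `threshold` | 0.001 | FunD expect-value cutoff, *inclusive* ("at most") |
| `seed` | — | controls fold assignment and every stochastic fit; identical seeds reproduce selections and models exactly |
| roster | `default_roster()` | any named list of `classifier_spec()` entries |
| `chain` | first chain | DSSP chain selector |

The roster deliberately spans model families — random forest, RBF SVM,
multinomial logistic, naive Bayes, LDA, CART — as pragmatic analogues of
the learners commonly used in fold-recognition studies. They are *not*
re-implementations of any specific toolkit's algorithms; hyperparameters
are fixed, sensible defaults, and the roster is configuration, not code.

## Descriptor definitions and conventions

Several descriptor blocks required concrete definitions where the field's
usage is loose; these are the conventions implemented and tested:

* **Runs.** A "continuous" segment is a maximal run of length ≥ 2 of one
  state (or state group). The two count blocks are raw run counts; the
  two composition blocks are the fraction of all residues lying inside
  qualifying runs. These readings reproduce the canonical block dimensions
  (8/4/8/4) and the count-versus-composition naming.
* **Alternation (4D).** For group g, the number of adjacent residue pairs
  whose groups differ and that touch g, divided by L − 1; zeros for
  single-residue strings. Each component is at most 1.
* **CTD distribution.** For group g with n_g occurrences in the
  standard-residue sequence of length L′, the reported values are the
  positions of occurrence 1 and occurrence ⌈q·n_g⌉ for
  q ∈ {0.25, 0.5, 0.75, 1}, each divided by L′ — fractions in (0, 1], not
  percentages. An absent group contributes five zeros.
* **Nonstandard residues** (B, J, O, U, X, Z) are retained by the parsers
  but removed before AAsCPP computation, from numerators and denominators
  alike.
* **Polarity grouping.** The classical three-group polarity partition is
  used with group 1 = LIFWCMVY; one widely circulated transcription of
  this table duplicates F in place of Y, which is not a partition of the
  20 amino acids and is corrected here. The other seven groupings verify
  as exact partitions and are used verbatim.
* **Selection rule.** Strict argmax on cross-validated accuracy, ties to
  the earlier roster entry. When the rule is applied to an externally
  supplied report whose own winner marking disagrees with its printed
  maximum, the printed maximum wins — the package follows the rule, not
  the marking.
* **Tie-breaking at prediction** goes to the lowest class index; together
  with seeded folds this makes every pipeline stage deterministic.
* **Degenerate inputs.** Empty structure strings, sequences without
  standard residues, empty PSSMs, single-class label vectors and empty
  rosters are all rejected with specific errors rather than propagating
  NaNs.

## File-format dialects

The parsers commit to the standard dialects: DSSP residue records start
after the `  #  RESIDUE` header with the chain id at character 12 and the
structure-summary letter at character 17 (blank mapping to `L`, `!`
break rows skipped); ASCII PSSMs contribute columns 3–22 of each residue
row (the log-odds block), ignoring the trailing weighted-percentage and
information columns; hit tables are 12-column BLAST tabular with the
E-value in column 11 and a `gnl|CDD|` subject prefix stripped. Feature
matrices are TSV with a `sample_id` first column, written with 17
significant digits so read∘write is bit-exact.

## What the synthetic generator does and does not show

`gen_labelled_dataset()` plants class structure directly in feature
space: per view and class, a Gaussian centroid with standard deviation
`separation`, plus unit-variance noise. This emulates exactly what the
ensemble consumes — labelled multi-view matrices with controllable
difficulty — and makes the pipeline's properties testable: accuracy is at
chance when `separation = 0`, rises monotonically with it, and the
averaging rule provably recovers from disjoint single-view errors.

What it does *not* emulate is the mapping from real sequences and
structures to features: synthetic matrices are isotropic Gaussians,
whereas real descriptor blocks are bounded, correlated and partly
discrete, and real fold classes are not equidistant. Passing tests on
synthetic data therefore validate the machinery (parsers, descriptors,
selection, averaging, persistence), not benchmark-level accuracy on real
fold datasets, which additionally requires PSI-BLAST and RPS-BLAST runs
against large external databases and is out of scope here. The default
synthetic FunD dimension is 500 — large enough to exercise
high-dimensional sparse views while keeping test runtimes in seconds
(a full domain database would be tens of thousands of columns).

## Problem sizes used by the shipped checks

The test suite exercises descriptor oracles on 1,000 random inputs of
length ≤ 30 against independent brute-force loop implementations;
format round-trips across 100 seeds per format; and ensemble recovery on
a 5-class, 60-samples-per-class dataset at separation 10 with a
three-member roster, holding out 20% stratified. The acceptance script
uses the same dataset shape with the full default roster, plus an
equal-width four-view configuration (30 columns each) at separation 0.15
where no single view saturates, to quantify the averaging gain.

## Known limitations

* CV accuracy used for selection is pooled over folds (equivalent to the
  fold-average for equal fold sizes); no variance estimate accompanies
  the selection, so near-ties are resolved by roster order rather than by
  a significance test.
* Probability averaging assumes roughly calibrated posteriors; trees and
  SVMs are used with their native probability outputs, without an extra
  calibration layer.
* Multi-chain DSSP entries are reduced to a single chain (first by
  default); merging chains is not supported.
* The FunD view depends entirely on the supplied domain universe; hits to
  domains outside it are ignored (with a warning), not appended.
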