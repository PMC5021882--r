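# profoldr

Protein fold recognition from multiple complementary representations of a
protein. Structural biologists and bioinformaticians classifying proteins
into SCOP-style fold classes rarely find one representation sufficient:
secondary-structure content, sequence composition, evolutionary profiles
and domain annotations each capture a different facet of a fold. `profoldr`
extracts all four as separate feature groups and combines them with a
multi-view ensemble in which **each view gets its own best classifier**,
chosen by cross-validation, and predictions are made by **averaging the
per-view class posterior probabilities**.

## The four feature groups

| Group  | Source input | Dimension | Content |
|--------|--------------|-----------|---------|
| DSSP   | DSSP file    | 40        | eight-state secondary-structure descriptors |
| AAsCPP | FASTA        | 188       | amino-acid composition (20) + CTD physicochemical descriptors (168) |
| PSSM   | PSI-BLAST ASCII PSSM | 20 | column means of the L×20 log-odds profile |
| FunD   | RPS-BLAST hit table  | one per domain | binary occupancy, E-value ≤ 0.001 |

**DSSP (40D).** The eight states {G,H,I,E,B,T,S,L} (L = no structure
assigned) are grouped into helix {G,H,I}, strand {E,B}, turn/bend {T,S}
and irregular {L}. Seven blocks are concatenated: state composition (8),
group composition (4), counts of maximal runs of length ≥ 2 per state (8)
and per group (4), the fraction of residues inside such runs per state (8)
and per group (4), and a per-group alternation frequency (4) counting
adjacent group-changing residue pairs.

**AAsCPP (188D).** For each of eight physicochemical properties
(hydrophobicity, van der Waals volume, polarity, polarizability, charge,
surface tension, secondary-structure propensity, solvent accessibility)
the 20 amino acids are partitioned into three groups, and the classical
CTD descriptor is computed: composition (3), transition frequencies
between group pairs (3), and the normalized positions of the first /
25% / 50% / 75% / 100% occurrences of each group (15). 20 + 8·21 = 188.

**PSSM (20D).** With `S[i, j]` the log-odds score of amino acid `j` at
position `i` of an L-row profile, the descriptor is the column mean
`P[j] = Σᵢ S[i, j] / L`.

**FunD.** Over a fixed, ordered universe of functional domains, component
`d` is 1 iff some RPS-BLAST hit to `d` has expect value ≤ 0.001
(inclusive).

## The ensemble

1. For every feature group, each classifier in a configurable roster is
   scored by stratified 5-fold cross-validated overall accuracy
   **Q = C/N** (C correct of N tested; per class, cᵢ/nᵢ).
2. The classifier with the highest CV accuracy wins the group (ties go to
   the earlier roster entry).
3. Each winner is refit on the full training matrix — one model per view.
4. At prediction, every model emits class probabilities `P[i, j]`; the
   ensemble probability is the across-view mean, and the predicted fold is
   its argmax.

The built-in roster (`default_roster()`) covers random forest, RBF-kernel
SVM, multinomial logistic regression, naive Bayes, linear discriminant
analysis and a CART tree; any `classifier_spec()` can be swapped in.

## Worked example

Everything below runs without external data: the synthetic generator
produces a labelled four-view dataset whose class separation you control.

```r
library(profoldr)

d <- gen_labelled_dataset(synthetic_dataset_spec(
  n_classes = 3, n_per_class = 20, separation = 0.4, seed = 42))
ids      <- names(d$labels)
test_ids <- ids[unlist(lapply(split(seq_along(ids), d$labels),
                              function(ix) ix[1:5]))]
train_ids <- setdiff(ids, test_ids)

ens <- train_ensemble(lapply(d$feature_groups, function(m) m[train_ids, ]),
                      d$labels[train_ids], seed = 42)
ens
#> <profold_ensemble> 3 classes, groups: DSSP, AAsCPP, PSSM, FunD
#>   DSSP     -> random_forest
#>   AAsCPP   -> svm_rbf
#>   PSSM     -> naive_bayes
#>   FunD     -> random_forest

ens$cv_reports$PSSM
#> <cv_report> PSSM (selected: naive_bayes)
#>         classifier cv_accuracy
#>      random_forest   0.5777778
#>            svm_rbf   0.5333333
#>  multinom_logistic   0.6000000
#>      naive_bayes *   0.6222222
#>                lda   0.4888889
#>               cart   0.4000000

p <- predict(ens, lapply(d$feature_groups, function(m) m[test_ids, ]))
q_accuracy(d$labels[test_ids], p$labels)
#> <evaluation_result> Q = 1.0000 (15/15 over 3 classes)
#>   class n correct accuracy
#>  fold01 5       5        1
#>  fold02 5       5        1
#>  fold03 5       5        1
```

At this separation no single view is reliable (the best PSSM classifier
reaches 62% in cross-validation), yet averaging the four views classifies
the held-out samples perfectly — the point of the per-view-selection,
probability-averaging design.

A command-line wrapper drives the same pipeline from a shell
(`exec/profold`): subcommands `simulate`, `extract`, `train`, `predict`,
`evaluate`, `cv-report`.

```sh
Rscript exec/profold simulate --out toy --classes 3 --per-class 10 --seed 1
Rscript exec/profold train --features DSSP=toy/dssp.tsv,AAsCPP=toy/aascpp.tsv,PSSM=toy/pssm.tsv,FunD=toy/fund.tsv \
    --labels toy/labels.tsv --out toy/bundle --seed 1
```

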