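---
title: "Predicting proteasomal cleavage sites from VHSE descriptor profiles"
author: "procleave"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting proteasomal cleavage sites from VHSE descriptor profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(procleave)
```

## The problem

The proteasome degrades intracellular proteins into short peptides, and in
the MHC class I antigen-presentation pathway it is the proteasome that
generates the C-terminus of the presented peptide. Predicting where the
proteasome cuts is therefore a key step in epitope discovery. procleave
implements a sequence-based predictor: the residues flanking a candidate
scissile bond are encoded with physicochemical descriptors and a support
vector machine separates cleaved from uncleaved bonds. Because the
descriptors have physical meaning and the default kernel is linear, the
trained model is directly interpretable as a per-position
cleavage-specificity profile.

## From ligands to labeled windows

Training data are ligand records: short peptides (MHC-I ligands or
in vitro digest products, typically 8-12 residues) paired with their
source proteins. Positions around a bond are named in Schechter-Berger
style, `P_n ... P1 | P1' ... P_n'`, with P1 the residue immediately
N-terminal to the cut. The corpus builder applies two conventions:

* the ligand's **C-terminal bond is a cleavage site** (P1 = the ligand's
  last residue), because that terminus was made by the proteasome;
* the bond after the ligand's **middle residue is a presumed
  non-cleavage site** — had the proteasome cut there, the intact ligand
  would not have been observed.

For even ligand lengths "middle" is ambiguous; procleave uses
`ceiling(L/2)`, the residue just upstream of center, which keeps the
presumed-uncut bond strictly interior to the peptide. Each site
contributes the window of `halfWidth` residues on both sides, and only
windows with full flanking context are kept (an `insufficient_context`
drop otherwise — the per-sample generalization of removing proteins
shorter than the full span). Exact duplicate `(window, label)` pairs are
collapsed, and a window observed under both labels keeps only its
cleavage copy: positive evidence of cleavage outweighs the positional
heuristic behind the negative label. When a peptide matches its source
protein more than once the first occurrence is used, with a warning —
the choice is arbitrary but deterministic. All dropped records are
tallied by reason, never silently discarded. Internally coordinates are
0-based; every human-facing report is 1-based.

The non-cleavage heuristic is imperfect by construction: nothing
guarantees the middle bond of a ligand is never cleaved in some other
copy of the substrate. This label noise is inherent to the data design
and bounds the accuracy any classifier can reach on such a corpus.

## VHSE encoding

Each of the 20 canonical residues carries eight VHSE scores — principal
component score vectors of hydrophobic (VHSE1-2), steric (VHSE3-4) and
electronic (VHSE5-8) property panels. The scores are dimensionless PCA
scores of auto-scaled property matrices, so every column is centered
over the 20 residues up to the two-decimal rounding of the published
table; the package embeds the table as fixed data
(`vhseTable()`) and refuses non-canonical residues (X, B, Z, U, O)
rather than imputing them, since no descriptor row exists for them —
affected samples are dropped upstream with a logged count.

By default only components 1, 3 and 5 are used — the first principal
component of each property block — so a window of `2h` residues becomes
a vector of `2h x 3` features (a `h = 14` window gives 84, `h = 10`
gives 60). The layout is position-major: the selected components of the
most upstream position first, positions running `P_h ... P1,
P1' ... P_h'`, components ascending within a position. This
index-to-(position, component) map is fixed and carried on every model
because the downstream weight interpretation depends on it. Other
selections are accepted (`componentSelection()`) but the reduced
1/3/5 set is the canonical configuration.

## Classification

Features are scaled linearly to `[0, 1]` per feature with the training
minimum and maximum; unseen values are clipped back into the interval
and constant features map to 0. Labels are `+1` (cleavage) and `-1`
(non-cleavage) throughout. The classifier is a soft-margin SVM (the
quadratic program is solved by libsvm via e1071); linear and RBF kernels
are supported, and the termination tolerance `epsilon` defaults to
`1e-3`. Classification has no regression tube, so `epsilon` here is a
solver setting only.

The cost `C` (and `gamma` for RBF) are selected by stratified 10-fold
cross-validation over a coarse log grid, `C` in `2^{-5}, 2^{-3}, ...,
2^5` and `gamma` in `2^{-7}, ..., 2^3`. Within each class the samples
are shuffled once with a fixed seed (default 20130909) and dealt
round-robin, so every fold's class ratio is balanced to within one
sample and the whole CV table is a deterministic function of (data,
grid, folds, seed). Held-out decision values are pooled over folds
before computing metrics — the pooled convention, rather than
averaging per-fold metrics — and the selected setting maximizes pooled
CV MCC, with ties broken by higher AUC, then smaller `C`, then smaller
`gamma`. MCC is the primary criterion because it stays informative when
the class sizes differ.

For the linear kernel the explicit weight vector
`w = sum_i alpha_i y_i x_i` and the bias are materialized, so the
decision function is a transparent dot product in scaled feature space.
Models persist to a single JSON document (kernel, hyperparameters,
scaler, support vectors or explicit `w`/`b`, index map, geometry, and a
provenance tag), which keeps them portable and diff-able.

## Evaluation measures

Accuracy, sensitivity and specificity are reported as percentages;
Matthews correlation coefficient as
`(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))` with the
conventional value 0 when any denominator factor vanishes; and AUC as
the rank statistic (Mann-Whitney probability that a random positive
outscores a random negative), with tied scores counted one half. A rate
whose denominator is empty returns `NA` rather than erroring. The tests
cross-check the rank AUC against trapezoidal ROC integration (pROC) to
`1e-12`.

## Interpreting the linear model

`positionWeights()` reshapes `w` onto the (position, component) grid.
For a residue `a` at position `p` the preference score is

```
score(a, p) = sum_k weight(p, k) * scaledVHSE_k(a)
```

where `scaledVHSE` passes the descriptor constant through the model's
own training scaler, so rankings live in the same space the model was
fit in and are invariant to the scaling choice. The top and bottom
`k = 4` residues per position form the favored/unfavored lists (the
published profile tables of this method list 3-5 residues per cell;
4 is the middle of that range). `siteScore()` sums these contributions
over a supplied `P.. | ..P'` context — for a profile with unit
hydrophobic weight at P1 and `-1` at P1', Leu|Lys scores
`1.36 - (-1.17) = 2.53`, a strongly favorable combination, matching the
known in vitro preference for cutting after Leu ahead of Lys.
`hydrophobicContrast()` condenses the hydrophobic profile into one
number — mean upstream VHSE1 weight minus mean downstream VHSE1
weight — positive when hydrophobic context upstream and hydrophilic
context downstream jointly favor cleavage.

Weights are reported in the scaled feature space where the model lives.
Since a weight's magnitude there depends on its feature's training
spread, `profileToRawSpace()` optionally divides each weight by its
training range to make magnitudes comparable per raw descriptor unit.
Published weight plots for this class of model do not state which space
they are drawn in, so cross-study magnitude comparisons should be
treated as approximate; within-model comparisons are exact either way.

## The synthetic-data generator

`generateProteome()` and `plantCleavages()` exist so the whole pipeline
can be exercised, and its parameter recovery verified, with no external
data. Proteins are i.i.d. uniform over the 20 canonical residues; the
latent cleavage score of each bond is

```
s = betaP1 * VHSE1(P1) + betaUp * mean VHSE1(P2..P10)
    - betaDown * mean VHSE1(P1'..P10') + Normal(0, noiseSd)
```

and bonds with `s > threshold` become planted sites, from which 8-12
residue ligands are emitted. The rule plants exactly the structure the
predictor is meant to find — hydrophobic P1, hydrophobic upstream
context, hydrophilic downstream context — and uses only VHSE1 so the
recovery target is unambiguous. Defaults: 120 proteins of 120 residues,
1200 ligands, `betaP1 = 3`, `betaUp = betaDown = 1`, `noiseSd = 0`,
`threshold = 4`, giving roughly 2200 window samples at `h = 10`. The
threshold keeps planted sites sparse (about 13% of candidate bonds),
matching the sparsity of real cleavage sites; a permissive threshold
would make cleavage so dense that the middle-bond negatives frequently
satisfy the rule themselves and the negative class would be polluted by
construction. All outputs are pure functions of the config, including
its seed.

What the simulation does not emulate: real amino-acid composition
(uniform, not proteome-like — a `UniProt`-style background would lower
descriptor variance per position), correlated neighboring residues,
multiple overlapping ligands per substrate region, allele-specific
binding preferences, or any influence of the other VHSE components.
Passing the recovery tests therefore shows the pipeline is correct and
the estimator identifies a hydrophobicity-governed rule at realistic
sample sizes — it does not certify performance on biological corpora.

## Validation experiments

Two experiments, run by the test suite and by `scripts/acceptance.R`,
frame what the package demonstrates end to end (problem sizes as
above — about 2200 training windows, 60 features, a 6-point cost grid,
10 folds):

* **planted-rule recovery** (zero noise, P1-dominated rule): the
  cross-validated linear model places its maximum positive weight at
  (P1, VHSE1), shows a positive hydrophobic contrast, and reaches
  pooled CV AUC well above 0.9; an independently simulated proteome
  scored by the same model confirms held-out accuracy.
* **null control** (all rule coefficients zero): sites are planted
  everywhere, labels carry no signal, and pooled CV MCC stays at
  chance level (within ±0.1 of 0) — the selection over the grid does
  not manufacture signal.

## Numerical choices and degenerate inputs

* Scaling constants with zero range map to 0; prediction clips unseen
  feature values into `[0, 1]`.
* libsvm orients decision values toward the first class it encounters;
  `trainSvm()` verifies the orientation against the fitted labels and
  flips the coefficients if needed, so positive decision values always
  mean cleavage.
* Residue rankings break exact score ties alphabetically (stable and
  deterministic); an all-zero profile is flagged `degenerate` rather
  than ranked meaningfully.
* Windows that cannot be scored (wrong length, non-canonical residues)
  are flagged per item with `NA` scores, preserving row order, instead
  of being dropped.
* MCC returns 0 when its denominator vanishes; rates with empty
  denominators return `NA`; AUC of a single-class input returns `NA`.
* Products in the MCC denominator are computed in double precision —
  integer arithmetic overflows already at a few thousand samples.

## Known limitations

* The non-cleavage labels are a positional heuristic, not measured
  negatives; label noise bounds achievable accuracy (see above).
* Exact numeric equality with models fit by other SVM implementations
  is not expected: optimizer internals, fold assignments and the pooled
  CV convention all shift coefficients and metrics at the second
  decimal even on identical data.
* The RBF kernel is supported for classification but offers no weight
  interpretation; polynomial and sigmoid kernels are deliberately out
  of scope.
* Whole-protein scanning scores every interior bond independently; it
  does not model cleavage-site interference or fragment kinetics.
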