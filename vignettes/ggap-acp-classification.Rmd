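---
title: "Classifying anticancer peptides from g-gap dipeptide composition"
author: "ggapACP"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying anticancer peptides from g-gap dipeptide composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ggapACP)
```

## The problem and the model

Anticancer peptides (ACPs) are short — mostly under 30 residues — cationic
peptides that disrupt the negatively charged membranes of cancer cells.
Screening candidate peptides experimentally is slow, so a sequence-based
classifier that flags likely ACPs is useful triage. ggapACP implements a
classical and still widely used pipeline for this task:

1. **Encoding.** A peptide $P = R_1 R_2 \dots R_L$ is represented by its
   *g-gap dipeptide composition*: for every position $i \le L - g - 1$ the
   ordered residue pair $(R_i, R_{i+g+1})$ — the two residues separated by
   $g$ intervening ones — is counted, and the 400 counts are normalized by
   $L - g - 1$ into frequencies $d_u^g$ that sum to 1. With $g = 0$ this is
   the ordinary adjacent-dipeptide composition; $g$ up to 4 captures
   short-range order beyond adjacency, which plain amino-acid composition
   (AAC, the 20 residue frequencies) discards entirely. Both encodings are
   instances of the general pseudo amino acid composition family: fixed
   length vectors retaining partial sequence-order information.

2. **Feature ranking.** Each of the 400 components is scored by the
   classical one-way ANOVA F-value across the two classes,
   $F(\xi) = S_B^2(\xi) / S_W^2(\xi)$, the ratio of the between-class mean
   square ($df_B = K - 1$) to the within-class mean square
   ($df_W = M - K$); for two classes this is exactly the squared
   pooled-variance t statistic. Large $F$ means class means far apart
   relative to within-class scatter.

3. **Incremental feature selection (IFS).** Features are sorted by
   descending $F$ and added one at a time; for each prefix size $\tau$ an
   SVM is evaluated by pooled stratified 5-fold cross-validation under one
   frozen fold partition, producing an accuracy curve over
   $\tau = 1, \dots, 400$. The optimal prefix $\Theta$ is the smallest
   $\tau$ at the curve's peak. Running this per $g \in \{0,\dots,4\}$ and
   taking the best peak selects the gap parameter itself.

4. **Classifier.** A soft-margin SVM with RBF kernel
   $\exp(-\gamma \lVert x - y \rVert^2)$, fixed at $C = 2$ and
   $\gamma = 0.125$ (values originally found by grid search;
   `gridSearch()` reproduces that step when wanted).

5. **Evaluation.** Sensitivity, specificity, accuracy and the Matthews
   correlation coefficient in the confusion-count parameterization
   ($N^+, N^-, N^-_+, N^+_-$), computed once from predictions pooled over
   all folds (jackknife, k-fold, or an independent set). The
   confusion-count MCC is algebraically the classical MCC; the test suite
   sweeps all small confusion matrices to hold the package to that.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `g` | 1 | gap between paired residues (0–4); selected by `selectBestG()` |
| `C` | 2 | SVM soft-margin penalty |
| `gamma` | 0.125 | RBF kernel width, on min-max scaled features |
| `k` | 5 | cross-validation folds in IFS and `kfoldEvaluate()` |
| `policy` | `"strict"` | whether invalid/too-short records abort or are dropped |
| `scale` | `TRUE` | per-feature min-max scaling to $[-1, 1]$ |

## Numerical and design choices

**Feature scaling.** Composition frequencies live on a scale of roughly
$1/(L - g - 1)$, so squared distances between 400-component vectors are of
order 0.05. At $\gamma = 0.125$ the RBF kernel is then nearly constant and
a $C = 2$ SVM degenerates to majority voting — we measured exactly that on
strongly separated synthetic data. The published hyperparameters only make
sense after the standard LIBSVM preprocessing step of min-max scaling each
feature to $[-1, 1]$, so that is the package default: the scaler is fitted
on training data only (refitted inside every cross-validation fold) and
stored in the model for prediction. `scale = FALSE` restores raw
frequencies for anyone wanting to study the degenerate behaviour.

**Canonical feature order.** Dipeptides are ordered alphabetically,
first residue major (`AA`, `AC`, ..., `YY`); `dipeptideIndex()` exposes the
0-based column index $u = 20\,\mathrm{rank}(R_a) + \mathrm{rank}(R_b)$.
Residue positions inside peptides are 1-based in all documentation. Any
bijection would do mathematically; one must be frozen for file outputs and
the signed F matrix, and alphabetical is the least surprising.

**Degenerate features.** A feature with $S_W^2 = 0$ but $S_B^2 > 0$
separates the classes perfectly; its F-value is reported as `Inf` and
ranks above every finite value. A constant feature gets $F = 0$. Ties in
the ranking break by ascending canonical index, making the ranking — and
therefore $\Theta$ — fully deterministic.

**Fold partitions.** The IFS curve is computed under one stratified fold
assignment fixed from a seed and shared across all $\tau$ and all $g$, so
curves differ only through the feature sets. The original description is
silent on stratification and averaging; freezing one partition removes a
large variance source and makes $\Theta$ reproducible. The curve is always
computed to $\tau = 400$ — it is not assumed unimodal and the code never
early-stops on a dip.

**Pooled metrics.** Cross-validated metrics are computed once from the
pooled confusion counts of all held-out predictions, not averaged over
folds, matching the global confusion-count formulation. `kfoldEvaluate()`
with $k = M$ is bit-for-bit the jackknife.

**Degenerate metrics.** When a factor under the MCC square root is
non-positive (e.g. everything predicted as one class), MCC is reported as
`NA` — an explicit undefined marker, never silently 0. Likewise Sn/Sp for
an absent class.

**Ties at the decision boundary** resolve to the positive class,
conservatively favouring sensitivity.

**Selection is done once, before evaluation.** The jackknife does not
re-run feature selection per left-out sample; the subset $S_\Theta$ is
fixed first. This matches the usual presentation order of this method
family but is a known source of mild optimism, and the same in-sample
ranking bias is visible on null data: with exchangeable classes at
benchmark size, an IFS peak over all 400 in-sample-ranked features sits
well above the majority rate (we measure roughly 0.75 against a 0.60
majority), purely through selection leakage. The package's null
calibration therefore uses a small fixed feature space, where the leak is
negligible, to check fold-level behaviour — and this paragraph is the
documentation of the residual bias.

## The synthetic data generator

`synthSpec()` / `generatePeptides()` produce labeled datasets emulating
the observable contrasts of the real ACP benchmark rather than membrane
biophysics:

* **Sizes** default to 138 positives + 206 negatives, the benchmark class
  balance; independent sets use 150 + 150.
* **Lengths** follow a two-part mixture: 80% uniform on [5, 30), 20%
  uniform on [30, 50], matching the "about 80% under 30 residues" summary
  of the real positive set (the exact published histogram shape is not
  reproduced, only its summary statistic).
* **Class signal** comes from over-representing C, E, F, G, I and K — the
  residues reported as abundant in ACPs — in the positive class via a
  multiplicative sampling-weight factor. The default factor 5 was
  calibrated once, at design time, so that the synthetic task's
  cross-validated accuracy lands in the low-to-mid 90s, comparable to the
  real benchmark; a factor of 1 gives exchangeable classes (the null).
* **Planted order signal**: optionally one fixed residue pair per
  peptide is planted at a chosen gap — in its stated orientation (default
  K..C) in positives and reversed (C..K) in negatives, at the same gap.
  The two classes then carry identical planted residue composition, so
  the class difference is purely the residue *order* at that gap, which
  only the matching g-gap encoding can see. This matched-control design
  is how the tests verify that `selectBestG()` recovers a known gap;
  one-sided or multi-position planting leaks compositional signal into
  every encoding and blurs the comparison.
* The background residue law is uniform by default (the simplest
  exchangeable null); a natural-abundance mode is available.

What passing synthetic tests do **not** show: real ACPs differ from real
non-ACPs in correlated, physicochemically structured ways (charge runs,
amphipathic periodicity) that an independent-residue generator cannot
produce, so absolute accuracies on synthetic data say nothing about
accuracy on real peptides — only that the pipeline's machinery behaves as
specified (signals planted are recovered, nulls stay null, protocols
agree with their definitions).

## Problem sizes used by the shipped checks

The test suite and the acceptance script run entirely from generated
data. The acceptance script reproduces the full workflow at benchmark
size (138 + 206; IFS over all five gaps at 5-fold CV; jackknife of the
selected model; 150 + 150 independent test). The planted-gap recovery
check uses 30 + 30 peptides with 3-fold CV over ten seeds, a size chosen
so ten full five-gap selection runs stay affordable while recovery
remains reliable; the null calibration uses 100 + 100 peptides. The
published-data reproduction (benchmark FASTA of the original study) is
implemented and documented in the acceptance test, and runs whenever
those journal-supplement FASTA files are placed under `inst/extdata/`.

## Known limitations

* The jackknife/IFS protocol shares one dataset between feature selection
  and evaluation (see above); reported accuracies are optimistic relative
  to a fully nested protocol.
* Sequences shorter than $g + 2$ cannot be encoded at gap $g$ and are
  rejected or dropped by policy — they are never silently zero-filled,
  which would break the sum-to-1 invariant.
* Only the 20 standard residues are supported; records containing B, U,
  X, Z (or gap/stop characters) must be cleaned or skipped.
* MCC on single-class test sets is undefined by construction and reported
  as such.
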