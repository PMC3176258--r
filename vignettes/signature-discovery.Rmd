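---
title: "Signature discovery by KLD-scored backward elimination: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Signature discovery by KLD-scored backward elimination: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the statistical machinery: the
model each stage assumes, the tunable parameters and their defaults, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the underlying procedure left them open.

## The problem

An in vitro skin-sensitization assay stimulates a dendritic-like cell line
with a panel of chemicals — sensitizers, non-sensitizers and solvent
(vehicle) controls, each in replicate — and profiles the transcriptome. The
goal is a compact transcript panel (a *prediction signature*) such that a
classifier trained on it separates the two chemical classes, plus an honest
estimate of how well the *selection procedure* generalizes to unseen
compounds. The pipeline has three stages: univariate filtering, wrapper-based
backward elimination, and compound-level resampling validation.

## Stage 1: ANOVA filtering

`anova_two_group()` computes, per transcript, a one-way fixed-effects ANOVA
across the two chemical classes. With two groups the F statistic equals the
squared pooled-variance t statistic, which the test suite exploits as an
independent oracle. `anova_multi_group()` uses one group per stimulation
(each compound, plus each vehicle control as its own group). Equal-variance
(pooled) ANOVA is used throughout — no Welch correction — matching the
classical one-way procedure. `bh_fdr()` delegates to
`stats::p.adjust(method = "BH")` after range validation.

Two open choices were resolved as follows:

* **Vehicle controls are excluded from the two-group comparison.** The
  classes being discriminated are the chemicals; controls are a reference
  for the single-marker screen, not a class. A flag
  (`include_controls_as_nonsens`) restores the pooled reading.
* **Selection is on raw p-values**, with q-values reported alongside;
  `select_candidates(use_q = TRUE)` switches. At reduced (simulated) gene
  counts a fixed `top_k` is more practical than a genome-scale threshold
  like 2×10⁻⁶, so both are supported.

Degenerate transcripts (no within- or between-group variation) get p = 1;
perfect separation with zero within-group variance is floored at the
smallest positive double so p stays in (0, 1].

## Stage 2: backward elimination

### The classifier

`train_classifier()` fits a linear soft-margin SVM (hinge loss, cost C,
default 1) on per-gene z-scaled features (centering and n−1 sd from the
training samples only; constant genes get scale 1 and therefore zero
weight). The solver is a dual coordinate-descent routine written for this
package (compiled, deterministic: cyclic coordinate order, no RNG, bias as
a regularized augmented feature, tolerance 10⁻³ on the projected gradient,
warm starts from the previous dual solution inside the elimination loop).
A linear kernel at C = 1 is the only tractable choice given the O(N²·S)
SVM fits the exact wrapper requires, and agreement with `e1071::svm` —
the conventional reference implementation — is asserted in the tests, on
decision values and predicted classes, rather than assumed.

Decision values are mapped to probabilities by Platt scaling:
p(+1 | d) = 1/(1 + exp(A·d + B)), fitted by the standard Newton scheme with
the prior-smoothed targets (N₊+1)/(N₊+2) and 1/(N₋+2). Those targets bound
calibrated probabilities away from 0 and 1, which in turn bounds the KLD of
a perfectly separated panel at a small positive value — the trajectory's
floor is set by sample size, not by the clipping constant.

### The elimination objective

The wrapper's score had to be fixed by this package, because "a
Kullback-Leibler divergence is recorded" admits several readings. The
definition used is:

> KLD = −(1/S) Σₛ ln p̂ₛ(yₛ),

the mean KL divergence between the one-hot true-label distribution of each
sample and its sigmoid-calibrated LOOCV class distribution — equivalently
the cross-entropy of the out-of-fold predictions. This is the unique
reading consistent with the procedure's documented dynamics: the score
*falls* as uninformative analytes are removed (less overfitting noise in
the folds) and *rises* once jointly informative analytes start being lost.
A divergence between the two classes' score distributions would move in the
opposite direction. That alternative — the symmetrized KLD between
class-conditional Gaussians fitted to the decision values, eliminated by
argmax and breakpointed at the trajectory maximum — is nevertheless
implemented behind `kld_variant = "separation"` for sensitivity analysis.

### The loop

At each step with N remaining analytes, `backward_eliminate()` computes N
candidate scores (LOOCV with analyte j removed, one Platt fit over the
collected out-of-fold decisions, then the KLD), eliminates the argmin, and
records that minimal KLD as the step's `kld_after`. One sigmoid per LOOCV
pass — not per fold — keeps the calibration deterministic and cheap while
using only out-of-fold decision values. Inside the compiled step routine
the fold's full-panel dual solution warm-starts all N candidate fits, and a
removed analyte is realized by pinning its weight at zero, so no matrix
copies are made.

Determinism and degeneracy rules:

* ties in the candidate score break toward the lexicographically smallest
  gene id (C-locale radix order), everywhere;
* LOOCV probabilities are clipped to [10⁻⁶, 1−10⁻⁶] so separable panels
  cannot produce infinite KLD;
* `floor` (default 1) stops the trace when that many analytes remain — the
  full trace — and `chunk > 1` eliminates several analytes per step as a
  labelled approximation for large panels (default 1 is the exact
  algorithm);
* LOOCV leaves out single samples by default; `by_compound = TRUE` leaves
  out whole compounds (all replicates), since the original procedure does
  not say which was used.

`find_breakpoint()` takes the step achieving the global minimum of
`kld_after` (ties resolve to the *latest* step, i.e. the smaller
signature); the signature is the analytes remaining after that step. The
`elimination_trace()` constructor is exported so breakpoint arithmetic can
be applied to recorded trajectories — e.g. a 1010-analyte trace with its
minimum at step 810 yields a 200-gene signature.

## Stage 3: resampling validation

`run_validation()` repeats, per iteration: a stratified compound-level
split (train fraction 0.7 by default; `round(0.7·k)` with round-half-up per
class, clamped so both sides keep at least one compound; all replicates of
a compound travel together); ANOVA filtering and candidate selection on the
training samples only; backward elimination on the training samples only;
SVM training on the derived test signature; and ROC/AUC on the held-out
samples. Scores are oriented so that higher = more sensitizer-like, fixed
by the training-class decision means, which prevents sign-flip artifacts in
the AUC. Per-iteration seeds derive deterministically from the master seed
by iteration index. Signature size per iteration follows either the
breakpoint (`signature_mode = "breakpoint"`, the default at simulation
scale) or a fixed panel size (`"fixed"`, mirroring a full-scale setting
where the signature was held at 200 transcripts).

The no-leakage property — perturbing test-set expression values never
changes a training-derived signature — is asserted by an instrumented test,
not assumed.

ROC curves sweep the unique scores; tied scores collapse to a single curve
point, making the trapezoidal AUC equal to the Mann–Whitney concordance
probability with half credit for ties (checked against brute-force pair
counting and against pROC in the tests).

**Permutation null.** The null check relabels *compounds*, not samples.
With only 20 compounds, a single permutation retains a hypergeometric
overlap with the true labels, so genuine signal survives (or inverts) in
any one permutation and all iterations sharing it are correlated; the null
therefore draws an independent permutation per iteration and averages,
which centers the null AUC at 0.5 with usefully small variance.

## The synthetic-data generator

`generate_dataset()` draws, in one seeded stream and documented order:
per-gene baselines N(7, 1.5²) (log2 scale, typical of normalized array
intensities); an informative subset (default 5% of genes) with shared-axis
loadings of random sign and magnitude |N(1, 0.25²)|; per-compound
idiosyncratic programs (a random 5% of genes shifted by N(0, 0.5²), in
*both* classes); and replicate noise N(0, 0.5²). Sensitizer compound c
shifts informative gene g by `potency_effects[π_c]`·u_g, with potencies
assigned round-robin over {extreme, strong, moderate, weak} (5 compounds
per category at the default 20; an explicit `potency_assignment` reproduces
any other distribution). Compounds listed in `outlier_compounds` have their
entire effect vector multiplied, emulating the occasional chemical whose
transcriptional profile would dominate a real data set.

Default effect scales {extreme 2.0, strong 1.5, moderate 1.0, weak 0.6}
log2 units were chosen once so that a desk-scale run separates classes
without being trivial: classes overlap at the weak end, potency ordering is
recoverable from centroid distances, and univariate filtering alone does
not suffice. The idiosyncratic programs are deliberately class-symmetric so
that separating the classes genuinely requires the informative subset.

What the generator does **not** emulate: probe-level artifacts, batch and
array-QC effects, correlated gene modules beyond the single shared axis,
heavy-tailed noise, and any real MUTZ-3 biology — the published study gives
no quantitative effect sizes to calibrate against. Passing recovery tests
therefore demonstrate that the algorithms behave as designed under their
own assumptions, not that real data would yield a particular signature.

## Outlier-compound screening

The original analysis removed two compounds after manual quality control
without stating a rule. `flag_outlier_compounds()` supplies an explicit,
advisory one: samples are projected onto the top k = 5 principal
components, distances from the grand centroid are converted to robust z
scores (median/MAD), and a compound's score is the median over its
replicates; scores above 6 are flagged. Removal remains an explicit,
logged `remove_samples()` call, so the 144 → 137 bookkeeping of the study
design is always visible in the log.

## Other fixed conventions

* Heatmap z-scoring uses the population (divide-by-n) standard deviation;
  constant rows become zeros with a warning.
* Hierarchical ordering of signature genes: average linkage on Euclidean
  distances of z-scored rows by default; complete linkage and correlation
  distance available.
* PCA centers genes but does not scale them (the common expression-PCA
  convention; `scale_genes = TRUE` switches), uses SVD, and fixes signs so
  each component's largest-magnitude loading is positive; held-out samples
  are projected with the model's own centering.
* Manifests record the configuration and md5 checksums of every written
  artifact; outputs are plain TSV so reruns can be compared byte-wise.

## Problem sizes

The test suite exercises the exact (chunk = 1) elimination at up to 100
candidate analytes × 114 chemical samples and the validation loop at 5
iterations × 50 candidates — sizes chosen so the full wrapper, which costs
O(N²·S) SVM fits, completes in minutes on a single core while leaving all
qualitative behaviour (trajectory dip, breakpoint, recovery, null AUC)
intact. Full-scale panels (≈10³ candidates) are reachable with `chunk > 1`
at the documented cost of approximating the one-at-a-time elimination
order.

## Known limitations

* The KLD definition and the LOOCV granularity are this package's
  resolutions of ambiguities in the original description; both alternatives
  are implemented, but defaults matter when comparing traces.
* Platt targets bound calibrated probabilities, so KLD values from small
  sample sets have a sample-size-dependent floor; traces from different S
  are not directly comparable.
* The dual coordinate-descent solver converges to the exact SVM solution
  only up to its tolerance; tie-breaking near-equal candidate KLDs can in
  principle depend on it. The tolerance (10⁻³) is fixed and identical
  everywhere, so traces are reproducible bit-for-bit across runs.
* `signature_mode = "fixed"` with a panel size larger than the candidate
  set silently uses the whole candidate set.
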