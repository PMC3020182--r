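---
title: "Layered control-based QC for expression microarrays: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Layered control-based QC for expression microarrays: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(controlqc)
```

## The idea: controls added at different stages localize technical failure

An expression microarray result passes through several wet-lab stages —
sample extraction and storage, amplification and labeling, hybridization
and scanning — and each stage can fail in ways that corrupt the final
intensities. GeneChip-style arrays carry four groups of control probesets
that enter the protocol at different points, and that difference is the
diagnostic lever this package exploits:

* **Spike-in hybridization controls** (biotinylated BioB, BioC, BioDn,
  CreX transcripts) are added to the hybridization cocktail after
  labeling. They only see the hybridization and scanning stages.
* **Spike-in polyA+ controls** (polyadenylated *B. subtilis* Lys, Phe,
  Dap, Thr, Trp transcripts at known, graded concentrations) are spiked
  into total RNA before amplification. They see labeling *and*
  hybridization.
* **RNA degradation controls** (GAPDH and β-Actin probesets targeting the
  5' end, middle and 3' end of the transcript) and
* **endogenous "housekeeping" controls** (a 100-gene invariant panel) are
  part of the sample itself and additionally report on RNA integrity.

A hybridization that is anomalous in the hybridization-control model is
anomalous everywhere downstream, so the earliest class that explains the
observed anomalies names the stage: hybridization-class anomalies →
hybridization/scanning; polyA-only anomalies → amplification/labeling;
degradation/endogenous-only anomalies → sample RNA quality. `aggregate_qc()`
implements exactly this attribution order.

## Pipeline overview

Input is a probeset × hybridization table of log₂ probeset summaries (e.g.
RMA output); the package never touches probe-level data. `run_pipeline()`
chains:

1. **Normalization** (`normalize_matrix()`): either quantile normalization
   onto the per-rank *median* reference distribution, or the
   75th-percentile "brightness-scaled" scheme, which subtracts from the
   control probesets the 75th percentile of each array's non-control
   (background) intensities. The p75 scheme is a per-array affine shift,
   so within-array contrasts are untouched; it is the default because it
   places control intensities from different arrays (even different array
   types) on a directly comparable scale.
2. **Dispersion screen** (`mean_sd_table()`, `background_curve()`):
   per-probeset mean and SD (n − 1 denominator) across hybridizations,
   against a 100-point moving-average background line. In a sound
   experiment the class-wise SDs are ordered by protocol exposure:
   hybridization < polyA+ < endogenous.
3. **Layered PCA** (`layered_fit()`): one mean-centered (never
   variance-scaled) principal component model per control class, with the
   component count chosen by venetian-blinds cross-validation and each
   hybridization scored by its Q residual and Hotelling T².
4. **Scalar metrics** (`compute_qc_metrics()`): per-array concentration
   response R², expected signal ordering Lys > Phe > Dap > Thr > Trp
   (strict; ties count as violations), and per-transcript 3'/5' ratios.
5. **Aggregation** (`aggregate_qc()`): flags plus stage attribution.

## The chemometric core

For a class block $X$ ($N$ hybridizations × $K$ probesets), each column is
centered and the model is $X_c = T P^\top + E$ with orthonormal loadings
$P$ from the SVD. Eigenvalues are score variances
$\lambda_a = d_a^2/(N-1)$; percent variance is reported against the
full-rank total, cumulative at the selected $A$. Two per-sample
diagnostics follow:

$$Q_i = \lVert x_i - x_i P_A P_A^\top \rVert^2, \qquad
T^2_i = \sum_{a \le A} t_{ia}^2 / \lambda_a .$$

$Q$ measures variation *outside* the model plane (unusual probeset
patterns); $T^2$ measures leverage *inside* it (extreme but
model-consistent samples). On calibration data $\sum_i T^2_i = A(N-1)$,
an identity the test suite checks. Loading columns are sign-fixed so the
largest-magnitude element is positive, making score plots reproducible
across platforms.

### Cross-validated component selection

Venetian-blinds assignment puts sample $i$ (0-based) into segment
$i \bmod k$ with $k = 10$ splits by default. Re-hybridizations of one
aliquot are trapped into a single segment (`trap_replicates()`), because a
replicate split across training and test sets leaks information and biases
RMSECV down. For each fold the model is refit on the training rows
(re-centered by the training mean) and held-out rows are reconstructed
from $a$ training components;
$\mathrm{RMSECV}(a) = \sqrt{\sum e^2 / (NK)}$, and RMSEC is the analogous
calibration quantity (no degrees-of-freedom correction; toolbox
conventions vary and the curves are only compared within themselves).

Two held-out reconstruction schemes are provided. Plain row-wise
projection of a held-out sample onto the training loadings has a
residual that can only shrink as components are added, so its RMSECV
curve is monotone and contains no selection signal beyond a flatness
heuristic — we verified this on every class block of the default
scenario. The default is therefore the **element-wise** scheme: each
variable of a held-out sample is predicted from the sample's *other*
variables through the training loadings (missing-data regression). With
orthonormal loadings this has the closed form

$$e_{ij}(a) = \frac{x_{ij} - [x_i P_a P_a^\top]_j}{1 - h_j},
\qquad h_j = \lVert P_a[j,\cdot] \rVert^2,$$

(a Sherman–Morrison downdate), so over-fitted components inflate the
prediction error and the curve attains a genuine minimum. The selected
$A$ is the smallest component count whose RMSECV lies within 1% (relative,
`select_tol`) of the global minimum — a parsimony rule that refuses to pay
for a flat tail. A random-subset assignment repeated 10 times under a
fixed internal seed provides a consistency vote on $A$ that is reported
alongside (`A_random_cv`) but never overrides the venetian-blinds choice.

### Flagging

The paper-style workflow reads ranked $Q$/$T^2$ lists and score plots; the
packaged default flags a hybridization in a class model when its $Q$ or
$T^2$ is **both** within the top `rank_depth` (default 3) ranks **and**
above the 95% control limit ($T^2$: F-distribution limit; $Q$:
Jackson–Mudholkar). The rank condition keeps lists short, the limit
condition keeps an entirely clean experiment from always flagging
`rank_depth` arrays per class. Both limits are also exported (`t2_limit()`,
`q_limit()`) for users who prefer pure limit-based flagging.

## Scalar spike-in metrics

* **Concentration response.** Per-transcript signal is the unweighted mean
  of the transcript's probesets' log₂ values (configurable to 3'-only);
  R² is the squared Pearson correlation against log₂ concentration
  (14.7, 39.1, 108.9, 260.0, 591.1 ng/µL for Trp/Thr/Dap/Phe/Lys). Sound
  samples sit above 0.95; a labeling failure collapses the response and
  the R² with it. A zero-variance signal reports R² = 0 with a degeneracy
  flag rather than NA.
* **3'/5' ratio** $= 2^{\log_2(3') - \log_2(5')}$, flagged above the
  conventional tolerance of 3. Reverse transcription proceeds from the 3'
  poly(A) end, so degraded or poorly processed templates lose 5' signal
  first.
* **Ordering check**: strict inequality along the expected ranking; each
  adjacent violation is reported with both values.

## The synthetic generator

`simulate_experiment()` exists so the full pipeline is testable without
array data. It emulates, on the log₂ scale: a linear polyA+ response
(slope 1.0 per log₂ ng/µL, intercept 2.5), a 5'→3' processivity decay of
0.3 log₂ units per position step (3' = 0, M = 1, 5' = 2) on polyA+ and
degradation controls, per-array brightness offsets (σ = 0.15), Gaussian
class noise ordered hybridization (0.10) ≤ polyA (0.18) ≤ RNAd (0.22) ≤
endogenous (0.25) ≤ background (0.35), and a two-component
expressed/unexpressed background mixture (60% expressed at 8.0 ± 1.5,
rest at 4.0 ± 0.8) so the 75th percentile is a meaningful brightness
proxy. The default scenario (`default_rae230a_scenario()`) has 60
hybridizations over 13 date classes with the full 18/27/12/100 control
complement plus 400 background probesets — a deliberately desk-scale
background block, since only its quantiles enter the method — and plants
one labeling failure (full collapse to the background floor of 4.5), one
bright replicate pair (+1.5 log₂, shared aliquot), and five degraded
arrays (−2.0 log₂ at 5', −1.0 at M, −0.5 across endogenous) forming one
date class.

What the generator does **not** emulate: probe-level effects (RMA
residual structure, NUSE/RLE behaviour), spatial artefacts, intensity-
dependent variance, batch drift across date classes, or real endogenous
gene identities (the packaged 100-gene list is a synthetic placeholder of
the documented size; the class logic is identity-agnostic). Passing the
planted-anomaly tests therefore demonstrates that the machinery localizes
the failure modes it models, not that any particular real dataset is
clean.

## Numerical choices and degenerate inputs

* Percentile convention: linear interpolation between order statistics
  (R's type 7), documented and switchable; the 75th percentile of
  {2, 4, 6, 8} is 6.5.
* Quantile normalization ties: tied values within an array receive the
  mean of the reference values across the ranks the tie block occupies —
  deterministic, rank-preserving.
* Rank-deficient blocks: `fit_pca()` truncates to numerical rank
  (singular values below `1e-12` of the largest) with a warning; RMSEC at
  full rank is exactly 0, and `select_components()` rejects a
  non-monotone RMSEC curve as evidence of a broken fit.
* A training fold smaller than `A_max + 1` rows aborts with the fold
  named; element-wise leverages are clipped at `1 − 1e-8`.
* Seeds: the generator takes an explicit seed; the random-subset CV uses
  a fixed internal seed (20103349) and restores the caller's RNG state.

## Problem sizes

The shipped tests and the acceptance script run the default 60 × 557
scenario (10 seeded repetitions for the stochastic properties) and
complete in a few seconds; the per-class PCA cost is dominated by one SVD
per CV fold and scales linearly in the number of folds. Larger
experiments (hundreds of arrays) change nothing structurally — the
venetian-blinds split count is the only parameter worth revisiting, and
10 splits is standard for ~100–150 hybridizations.

## Known limitations

* Probeset-level input only; nothing here replaces probe-level QC
  (NUSE/RLE, RawQ, detection calls).
* The endogenous panel is treated as one undifferentiated block; no
  per-gene stability weighting.
* Q/T² control limits assume approximately Gaussian residual structure;
  on strongly non-Gaussian data treat them as guides and use the ranked
  lists.
* Stage attribution is rule-based on class membership of the flags; it
  names the earliest stage consistent with the evidence, not a causal
  proof.
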