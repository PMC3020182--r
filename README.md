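# controlqc

Layered, control-based quality assessment for probeset-level expression
microarray data.

## The problem

Every GeneChip-style hybridization carries four groups of control
probesets that enter the wet-lab protocol at different stages: prelabeled
biotinylated spike-ins (BioB/BioC/BioDn/CreX) added to the hybridization
cocktail; polyadenylated *B. subtilis* spike-ins (Lys, Phe, Dap, Thr, Trp)
added to total RNA at known graded concentrations before
amplification/labeling; GAPDH and β-Actin probesets targeting the 5',
middle and 3' segments of the transcript; and a panel of ~100 endogenous
"housekeeping" genes. Because each class reports only on the stages it
passed through, modeling the classes *separately* — a layered analysis —
not only detects a technically aberrant hybridization but localizes the
stage that broke it: hybridization/scanning, amplification/labeling, or
sample RNA quality.

`controlqc` implements that methodology for anyone doing retrospective or
routine QC on probeset-level summaries (e.g. RMA output): core facilities
triaging failed arrays, analysts deciding which hybridizations to drop
before a differential-expression analysis, and methodologists studying
spike-in behaviour.

## The method

For each control class block $X$ ($N$ hybridizations × $K$ probesets,
mean-centered, never variance-scaled) a principal component model
$X_c = T P^\top + E$ is fit by SVD. The component count $A$ is selected by
the joint minimum of RMSEC and cross-validated RMSECV under a
venetian-blinds split (sample $i$ → segment $i \bmod 10$) with replicate
trapping, using element-wise (missing-data) reconstruction of held-out
samples so the RMSECV curve has a true minimum. Each hybridization is then
scored by

* $Q_i = \lVert x_i - x_i P_A P_A^\top \rVert^2$ — variation outside the
  model plane, and
* $T^2_i = \sum_{a \le A} t_{ia}^2/\lambda_a$ — leverage inside it,

with 95% control limits (Jackson–Mudholkar for $Q$, F-distribution for
$T^2$). Scalar metrics complete the picture: the per-array R² between
log₂ spike concentration and log₂ polyA+ signal (≥ 0.95 expected for
sound samples), the expected ordering Lys > Phe > Dap > Thr > Trp, and
3'/5' ratios $2^{\log_2 3' - \log_2 5'}$ against the conventional
tolerance of 3. Two normalizations are built in: quantile (to the
per-rank median) and the 75th-percentile "brightness-scaled" scheme that
subtracts each array's background 75th percentile from its control
intensities. A synthetic-data generator with planted anomalies
(labeling failure, brightness shift, degradation) makes the whole
pipeline testable end to end; see the methods vignette
(`vignettes/control-qc-methods.Rmd`) for the model and every default.

## Worked example

```r
library(controlqc)

sim <- simulate_experiment(default_rae230a_scenario(seed = 1))
res <- run_pipeline(sim$matrix, sim$registry, sim$metadata, sim$design,
                    normalization = "none")
res$report
#> qc_report: 60 hybridizations, 11 flagged
#>  hybridization_id  polya_r2                  stage
#>               E21 0.9999118     sample RNA quality
#>               F26 0.9977780     sample RNA quality
#>               F28 0.9985746 hybridization/scanning
#>               G31 0.9991201     sample RNA quality
#>               G32 0.9993554     sample RNA quality
#>               G33 0.9993250     sample RNA quality
#>               G34 0.9993790     sample RNA quality
#>               G35 0.9974233     sample RNA quality
#>               I43 0.9982788 hybridization/scanning
#>               J47 0.0000000 amplification/labeling
#>               K50 0.9982193 amplification/labeling

sapply(res$fits, function(f) f$model$A)
#>   hybridization           polyA rna_degradation      endogenous
#>               1               1               2               1
```

The scenario plants exactly eight bad arrays, and all eight appear with
the right attribution: the bright replicate pair F28/I43 (a re-hybridized
aliquot, +1.5 log₂ everywhere) is called at the hybridization/scanning
stage; the five degraded date-G arrays (5'-attenuated) are called sample
RNA quality; and J47, whose polyA+ block collapsed to background, is the
labeling failure — its concentration-response R² drops from ~0.998 to 0
while its hybridization controls stay unremarkable, which is what pins
the failure to amplification/labeling. E21, F26 and K50 are false
positives of the 95% control limits (about the rate those limits imply).
Per-hybridization values, thresholds and per-class scores/loadings are in
`res$report$flags`, `res$fits`, or written as TSV/JSON via
`run_pipeline(..., out_dir = "qc_out")`.

Note that the 75th-percentile normalization (the default) removes uniform
brightness shifts by construction — run it when you want QC on
brightness-corrected data, and `normalization = "none"` when a raw
brightness anomaly should itself be caught.

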