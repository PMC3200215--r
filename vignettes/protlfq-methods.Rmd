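---
title: "Models and methods behind protlfq"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind protlfq}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(protlfq)
library(dplyr)
```

This vignette explains the statistical model, the synthetic-data generator,
and the numerical and design choices the package makes where the underlying
methodology leaves them open.

## The per-protein model

Label-free quantification measures each peptide's chromatographic peak area
per injection. After log2 transformation and quantile normalization, the
peptide log2 intensities of a protein are averaged per injection to give a
protein log2 intensity, and each protein is fit separately with a two-level
mixed ANOVA:

$$\log_2(\text{intensity}) = \text{Group} + \text{Sample(Group)} + \varepsilon$$

Group is the fixed case/control effect; Sample(Group) is a random
biological-sample effect nested within group (it also absorbs per-sample
preparation effects); the residual is replicate-level technical noise. Log2
is the working scale because a unit difference equals a two-fold change and
the noise is approximately additive there (lognormal on the raw scale).

`fit_group_sample_model()` implements the balanced expected-mean-squares
analysis: replicates are collapsed to per-sample means, the one-way ANOVA of
those means on group tests the group effect against the sample stratum on
$(1, N_\text{samples}-2)$ degrees of freedom. This is exactly the EMS F test
for balanced replicate counts and degrades gracefully (per-sample means) for
unbalanced ones; full REML is deliberately out of scope. With one replicate
per sample the fit reduces to the two-sample pooled-variance comparison
($F = t^2$, verified in the tests). Variance components come from the mean
squares — $\hat\sigma^2_\text{rep} = MS_\text{rep}$,
$\hat\sigma^2_\text{sample} = \max(0, MS_\text{sample-means} -
MS_\text{rep}/r)$ — with negative estimates truncated at zero. Zero residual
variance (possible on noise-free validation data) yields $p = 0$ with a
warning rather than an error.

The log2 group difference back-transforms to a **signed fold-change**:
$2^d$ when $d \ge 0$, else $-2^{-d}$, so magnitudes are never below 1 and
the sign carries the regulation direction. Multiple testing uses
Benjamini–Hochberg step-up q-values; the significance gate is
$|\text{fc}| \ge 1.3$ (a 30% change) at $q < 0.05$. Both thresholds are
arguments throughout.

%CV summaries are computed on back-transformed (raw-scale) protein
intensities, because a coefficient of variation is a raw-scale quantity:
replicate %CV within samples (technical variation), replicate+sample %CV
within groups (technical plus biological), each averaged over its stratum.

## The synthetic-data generator

`generate_peptide_table()` draws peptide-level log2 intensities as

$$y_{ijsr} = \beta_i + o_{ij} + \delta_i \, \mathbb{1}(s \in \text{case})
           + b_{is} + e_{isr}$$

with protein baseline $\beta_i \sim N(20, 2^2)$ (log2 units, arbitrary
instrument scale), fixed per-peptide ionisation offsets
$o_{ij} \sim N(0, 0.5^2)$ drawn once so roll-up averaging is unbiased,
sample effects $b_{is} \sim N(0, \sigma^2_\text{sample})$ and replicate
noise $e_{isr} \sim N(0, \sigma^2_\text{rep})$. One deliberate
interpretation: the sample effect is drawn **per protein × sample**, shared
by all peptides and replicates of that sample. A sample effect shared by
*all* proteins would be a global column shift — precisely what quantile
normalization removes — so it could never be recovered downstream; the
per-protein draw matches the nested random effect the ANOVA actually
estimates.

Default parameters are the study conditions the package emulates:

* 8 case vs 5 control samples; 3 replicate injections per sample (a typical
  label-free triplicate-injection design; the source design does not state
  its replicate count, only that replicate and replicate+sample variation
  were separable, implying $r \ge 2$).
* $\sigma_\text{rep}$ and $\sigma_\text{sample}$ back-solved from the
  reported median replicate %CV (11.97) and replicate+sample %CV (19.16)
  via the lognormal conversion
  $\sigma_{\log_2} = \sqrt{\ln(1 + (\text{CV}/100)^2)}/\ln 2$
  (`cv_to_log2_sd()`), giving 0.172 and 0.213 log2 units. These are
  peptide-level SDs; protein-level CVs after multi-peptide averaging are
  correspondingly smaller.
* 5% of proteins truly changed, |effect| = log2(1.5), signs alternating —
  fold-changes of ±1.5, the middle of the reported significant range
  (1.29–2.16).
* A spike-in QC protein with 9 peptides and effect exactly 0 is always
  appended (the constant-amount chicken-lysozyme convention); its
  fold-change must stay within the significance gate for QC to pass.
* Missingness is completely at random, default 0. Intensity-dependent
  missingness is not modelled by the source methodology and is out of scope.

What the generator does **not** emulate: isotope envelopes, chromatographic
tailing, interference/co-elution, intensity-dependent variance, shared
peptides between proteins. Passing tests therefore validate the statistical
machinery, not robustness to those real-data phenomena.

`generate_feature_runs()` adds a physical layer for the alignment stage:
each peptide becomes a feature with a precursor m/z (uniform 400–1200 Th),
charge 2 or 3, a retention time (5–55 min), a 6-peak fragment fingerprint,
and per run a symmetric triangular peak trace whose trapezoidal area equals
the intended intensity, plus Gaussian m/z and RT jitter and a per-run global
RT shift.

## Alignment choices

The matching contract is conjunctive: precursor m/z within 0.5 Th
(unit-resolution ion-trap tolerance), equal charge, fragment similarity,
and RT within a 1-minute window after shift correction. Where the
methodology is silent the package chooses:

* **RT correction**: a single global shift per run, the median RT
  difference over mutual-nearest-neighbour m/z+charge anchor pairs against
  the first run. No warping/LOWESS — a global shift satisfies the 1-min
  contract at desk scale and is robust through the median.
* **Fragment similarity**: cosine over presence/absence of 0.5-Th fragment
  bins, threshold 0.7. "Fragments must match" needs a metric; binned cosine
  is the simplest that tolerates small m/z error.
* **Greedy grouping** in descending-area order (ties: ascending m/z, then
  run id), each seed taking at most one observation per other run, nearest
  m/z first. The deterministic sort makes output invariant to input order;
  unmatched observations stay as singleton groups so the output partitions
  the input.

## Normalization

Quantile normalization replaces each column's rank-k value with the
across-column mean of rank k. Ties receive the mean of the tied ranks'
reference values; with missing cells, each column's observed quantiles are
interpolated onto the reference distribution built from complete rows —
preserving the same-distribution contract without imputing. Single-column
input is returned unchanged with a warning. The operation is idempotent,
equalizes column means, and preserves the grand mean on complete matrices
(all property-tested; `limma::normalizeQuantiles` is the independent
cross-check).

One structural caveat, visible in noise-free validation: when some proteins
truly change, the column distributions genuinely differ, and forcing them
equal slightly shrinks those effects. Exact fold-change recovery in the
noise-free limit therefore holds on the log2-only path
(`normalize_peptide_table(quantile = FALSE)`); with realistic noise the
residual bias is far below the estimation error (the simulation tests
verify unbiasedness within Monte-Carlo error on the full path).

## Priority classes and the study summary

Peptides need ≥ 90% identification confidence (inclusive boundary);
proteins keep Priority 1 with ≥ 2 distinct retained peptide sequences,
Priority 2 with exactly 1, otherwise they are filtered. "Unique peptide"
means a distinct amino-acid sequence, ignoring charge; peptides shared
between proteins count for each (no parsimony rule is imposed;
`unique_to_protein = TRUE` switches to unique-only counting). Raising the
threshold can only degrade a protein's class — a tested monotonicity.
`summarize_study()` reports, per priority and overall: protein counts,
significant counts, the maximum |fold-change| over **all** quantified
proteins in the stratum (which is why a stratum's maximum can exceed the
largest *significant* fold-change), and median %CVs.

## Biomarker panel selection

With as many candidate proteins as samples the pooled covariance is
singular, so the Fisher discriminant is ridge-regularized:
$w = (S_p + \lambda I)^{-1}(\bar x_\text{case} - \bar x_\text{control})$
with $\lambda = 10^{-3}\,\mathrm{tr}(S_p)/p$ — small enough to leave
well-conditioned problems essentially unchanged (cross-checked against
`MASS::lda`), large enough to stabilise the singular case. The decision
threshold is the midpoint of the projected class means shifted by the
class-size prior odds (8:5 by default); scores exactly at the threshold
classify as control.

"Best discrimination by the fewest proteins" is operationalized as greedy
forward selection under the leave-one-out misclassification count: stop at
zero error or when no addition improves it; ties prefer the larger
projected class margin, then lexicographically smaller accession. The
procedure is deterministic given the data. With 13 samples LOO counts are
coarse (granularity 1/13), so small panels are favoured by construction.

## MRM assay arithmetic

Precursor m/z uses **average** residue masses by default and fragment m/z
**monoisotopic** masses — the combination that reproduces the packaged
transition table (precursors within 0.06 Th, products within 0.05 Th); both
modes are exposed. Collision energy follows the charge-specific ramps
(0.05·m/z + 8 at 2+, 0.044·m/z + 8 at 3+; other charges are an error), DP
is fixed at 100 V and dwell defaults to 25 ms within the 20–30 ms window.
Cysteine is unmodified by default; a fixed +44.026 Da ethanol adduct
(2-iodoethanol alkylation) is available as `cys_mod` and is required to
reproduce the printed Cys-containing transitions, so those fixture rows are
flagged. In the packaged table the doubly-charged product ions printed as
y10/y15/y16 of the extracellular-matrix-protein-1 peptide only reconcile at
charge 2; the fixture records that charge explicitly.

MRM quantification averages transition AUCs within peptide and sample,
takes the case-control log2 difference per peptide, and averages peptide
**signed fold-changes** (not log2 values) into the protein fold-change —
the reporting convention for multi-peptide MRM panels; the two averaging
scales differ slightly and the choice is deliberate. The p-value comes from
the one-way ANOVA of per-sample protein log2 values. Assayed proteins with
no detected transitions are reported `detected = FALSE`, not an error.

## Problem sizes and determinism

The test-suite and acceptance simulations use 500 proteins for calibration
checks (type-I error, FDR, effect recovery), 60 features × 5 runs for
alignment recovery, 100 random matrices for normalization properties, and
30 proteins with 5 strong effects for panel selection — sizes at which the
Monte-Carlo error of each check is well below its tolerance while a full
run completes in seconds. All randomness flows from a single integer seed
per generated dataset; rerunning any pipeline with the same configuration
is bit-identical.

## Known limitations

* No REML/shrinkage variance estimation; unbalanced replicate counts fall
  back to per-sample means.
* The identification stage (database search, confidence estimation) is out
  of scope; confidences are inputs.
* No warping-based RT alignment, vendor/mzML parsing, or de novo peak
  picking.
* Fixture confidences printed as ">99.99" are stored as 99.99 (a lower
  bound), and the fixture keeps the listed sample ages as printed even
  where the printed cohort mean disagrees with their average.
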