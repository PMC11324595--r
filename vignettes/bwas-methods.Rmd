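---
title: "Brain-wide association of voxel-wise functional connectivity: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Brain-wide association of voxel-wise functional connectivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bwasr)
```

## The statistical model

A brain-wide association study treats every voxel-pair functional
connectivity (FC) link as a test, the way a GWAS treats every SNP. Per
subject, the link value is the Fisher z-transform of the Pearson
correlation between the two voxels' time series; atanh is
variance-stabilizing, so across subjects a link's z-values are
approximately normal with variance ≈ 1/(T−3) for T timepoints. The group
comparison is a per-link GLM,

z ~ intercept + group + age + education + mean FD + ITV,

with the two-tailed t on the group coefficient (df = n − p). With no
covariates this reduces exactly to the pooled-variance two-sample t-test,
which the tests verify. Group is coded control = 0, patient = 1, so a
negative t means weaker connectivity in patients. An alternative
(`method = "residualize"`): residualize z on the covariates first, then a
plain two-sample t with df = n − 2. The GLM is the default because it
accounts for the covariate degrees of freedom; the two agree closely in
practice (their t-values correlate > 0.98 in the test suite's worlds) but
are not identical, which is why both are exposed.

### Family-wise error and the family-size convention

"Strict FWE" is implemented as Bonferroni, the strictest standard choice
and the only one that composes directly with a corrected-scale threshold:
a link is significant iff p < α/N, equivalently corrected p = min(1, pN)
< α. The default α is 3.33×10⁻². Its origin is not an obvious 0.05
variant; it is treated as a plain configuration value.

The family size N follows the printed reporting convention ⌊n²/2⌋
(23,178 voxels → 268,609,842), while the enumerated tests are the
n(n−1)/2 unordered pairs. The convention double-counts by ≈ 2×, making
the correction conservative by the same factor; both conventions are
available (`count_links(n, convention =)`), with `"n2_half"` the default
for fidelity to the published family size.

### The Measure of Association and clusters

MA(i) counts the FWE-significant links incident to voxel i. Two exact
invariants are enforced at run time and tested: MA(i) ≤ n − 1, and
Σ MA = 2 × (significant links). Clusters are connected components of the
strictly-thresholded map MA > ma_min under 26-connectivity (6 available);
components below the minimum size are dropped; the peak is the maximum-MA
member with ties broken by lowest linear index, reported in world
coordinates via the NIfTI affine.

The full-scale thresholds are MA > 40 and cluster ≥ 20 voxels. MA
magnitude scales with the voxel count, so at toy scale these are
configuration parameters. For the 600-voxel recovery world (two 30-voxel
clusters), the tests use ma_min = 10 and cluster min = 10: an affected
voxel has ~30 incident affected links while the null expectation under
Bonferroni is ~0, so 10 separates the two regimes with wide margin. This
choice was made from the design arithmetic, not tuned on outcomes.

### ROIs, FDR, cognition, reliability

ROI membership is the significant voxels inside an atlas region (not the
whole region), regions qualifying with ≥ 20 such voxels (configurable);
the ROI series is the unweighted mean BOLD of those voxels. ROI-pair FC
reuses the link GLM; the FDR family is all ROI pairs (the narrower
"matched subsets" reading is ambiguous in the source analyses; all-pairs
is the conservative, reproducible choice), adjusted with
Benjamini–Hochberg — BH rather than BY, since plain "FDR" conventionally
means BH.

Composite cognitive scores z-score each raw test against the pooled
mean/SD of all included participants and average within domain; a
control-referenced variant (`norms = "cn"`) is provided since published
tables rarely state the reference population. The circuit-cognition
screen residualizes both the circuit z and the composite on age, gender
(0/1) and education within the patient group, reports Pearson r with a
percentile bootstrap CI (paired resampling of subjects, default 10,000
reps), and leaves p-values unadjusted by default — the screen is
exploratory, and the optional BH column is clearly labeled.

Half-split reliability splits each scan into its first ⌊T/2⌋ and
remaining timepoints, recomputes the whole MA stack on each half with the
same thresholds (scaled thresholds available: halves have noisier
z-estimates, variance ≈ 1/(T/2−3)), and quantifies agreement by the Dice
coefficient of the MA-thresholded voxel sets and the Spearman correlation
of the MA maps over their union. The source analyses report only
qualitative consistency; Dice and rank correlation are this package's
chosen quantifications. When both significant sets are empty, Dice is NA
(undefined), never 1. Cross-validation defines ROIs on one half and
re-tests their circuits on the other, in both directions.

## The synthetic cohort generator

The generator is a stated world, not a tuning knob. Each declared cluster
carries one latent, unit-variance, band-limited (0.01–0.1 Hz) Gaussian
time course; latents are mixed through the Cholesky factor of a target
correlation matrix. A cluster voxel observes its latent plus independent
noise (sd 0.5 by default, so within-cluster voxel correlation is 0.8;
optionally AR(1)); background voxels are unit noise. The correlation
between two cluster *means* is attenuated by voxel noise by the known
factor 1/√((1+σ²/m_a)(1+σ²/m_b)), so the latent correlations are inflated
analytically to make the expected cluster-mean correlation equal the
declared group value; infeasible declarations (inflated |r| ≥ 1 or a
non-positive-definite matrix) are configuration errors. This closed-form
control is what lets the acceptance tests assert calibration (|bias| <
0.02 at T = 500) rather than merely direction.

Defaults emulate the motivating cohort: 74 controls vs 56 patients; age
63.3 (6.5) vs 65.6 (7.5) years; education 12.5 (2.6) vs 12.0 (2.6);
ITV 1416 (109) vs 1365 (102) ml with the group difference retained;
male proportion 31/74 vs 12/56; T = 200 at TR = 2 s (the scan length is
not published; 200 volumes at 2 s is a typical resting-state protocol).
Motion is a 6-parameter random walk with step sd 0.04 mm / 5×10⁻⁴ rad,
giving mean FD_Power ≈ 0.16 mm, matching the published 0.17–0.19 range.
Cognition couples a named domain to a circuit as
score = slope × z_subject + noise; the default noise sd 0.06 is matched
so the generated brain-behavior correlation is ≈ 0.5 at T = 200
(sd(z) ≈ 1/√197, so matched noise = 0.5·0.071·√3).

What the generator does **not** emulate: hemodynamic (balloon) dynamics,
realistic spatial autocorrelation, scanner drift or artifacts,
physiological noise structure, or registration error. A green
recovery test therefore establishes that the statistics are implemented
correctly and calibrated under their own assumptions — not that the
pipeline would detect effects of any particular size in real data.

The toy atlas tiles the mask into contiguous, near-equal runs of
ascending linear index (consecutive runs on a full grid are
26-connected). It is deterministic; the seed argument exists only for
interface symmetry with the other generators.

## Preprocessing conventions

Only the deterministic tail of a standard pipeline is implemented:
nuisance regression (intercept, linear trend, Friston-24 motion
expansion [p, p², p_lag1, p_lag1²], optional WM/CSF means), Gaussian
smoothing, then band-pass filtering — fixed in that order, matching the
upstream listing; the order is tested for determinism, not
commutativity (regression and filtering only approximately commute).
Slice timing, realignment and spatial normalization are out of scope
(performed by standard packages upstream).

Numerical choices:

* **Band-pass** is frequency-domain hard masking (components with folded
  frequency in [low, high] kept, DC removed). It is exactly linear and
  deterministic; the tolerance contract (passband ≥ 90% amplitude,
  stopband at 2× high ≤ 10%) is sized for T ≥ 100, where passband edges
  fall close to FFT bins.
* **Smoothing** uses a separable sampled-Gaussian kernel, σ =
  FWHM/(2√(2 ln 2)) per axis in voxel units, radius 4σ, reflect boundary
  (avoids edge dimming on small grids). FWHM 0 is the identity.
* **FD** follows the Power convention: Σ|Δtranslation| + 50 mm ×
  Σ|Δrotation|, FD₁ = 0. The Jenkinson and Van Dijk variants are not
  implemented: the pipeline uses one motion covariate, and the source
  tables name the Power variant alongside the others without choosing;
  mean FD_Power is the covariate.
* **ITV** is the plain GM + WM + CSF sum.
* **Zero-variance voxels** are a hard error, not a silent exclusion:
  dropping voxels per subject would desynchronize voxel indexing across
  the cohort.
* **Link retention**: only links with p below a retention cutoff need be
  materialized (`retain_p`); the family size is tracked separately, and
  retention below the FWE cutoff is an explicit undercount error. At toy
  scale the default retains everything.
* Voxel indices are 0-based in coordinates and reports; world
  coordinates come from the NIfTI sform affine.

## Known limitations

* The full 23,178-voxel problem (2.7×10⁸ links) is out of scope by
  design; the implementation is dense per subject and targets toy-to-
  moderate grids (≤ a few thousand voxels).
* NIfTI support covers the single-file NIfTI-1 subset this pipeline
  writes and reads (five datatypes, sform geometry); qform-only files
  fall back to pixdim spacing.
* The residualize-then-t variant and the choose-2 family convention are
  provided but not the defaults; switching them changes df and the
  effective α, respectively.
* Bootstrap CIs use the percentile method only (no BCa).
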