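---
title: "Methods: slice-aware salivary-gland texture radiomics and toxicity models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: slice-aware salivary-gland texture radiomics and toxicity models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The analysis this package implements

`radsaliva` implements a replication-style radiomics analysis for late
radiation-induced salivary toxicity in head-and-neck cancer. The clinical
question is whether CT texture features of the salivary glands -- beyond
mean gland dose and baseline symptoms -- predict moderate-to-severe
xerostomia (`Xer12m`) and sticky saliva (`SS12m`) twelve months after
radiotherapy, both defined as EORTC QLQ-HN35 grade >= 3. Two candidate
imaging predictors are carried through the whole pipeline:

* **Short Run Emphasis (SRE)**, a grey-level run-length feature of the
  contra-lateral parotid, high for fine/heterogeneous texture;
* **maximum CT intensity (maxHU)** of the submandibular glands.

The package provides the full chain: artifact-aware feature extraction,
across-patient normalisation, univariate association tests, nested logistic
endpoint models with likelihood-ratio tests and rank-based AUC, subgroup
analyses, a 2D-versus-3D feature agreement study, and a synthetic cohort
generator with known ground truth that makes every stage testable without
clinical data.

## Feature extraction

### Discretisation

In-mask voxel intensities are clamped to $[-200, 200]$ HU and binned at a
fixed width of 25 HU, giving 16 grey levels. Bins are left-closed and
right-open, with the top bin right-closed so that 200 HU maps to bin 16;
this convention is stated explicitly because width and range alone do not
determine the edges. Out-of-range intensities are clamped into the boundary
bins rather than dropped: the resampling is a range restriction, not a
voxel filter. `maxHU`, in contrast, is deliberately computed on *raw*
(unclamped) HU over the retained slices -- clamped, it would saturate at
200 HU and carry almost no inter-patient signal, contradicting its role as
a predictor.

### Metal-artifact slice exclusion

Dental implants produce streak artifacts whose intensities do not
correspond to tissue density. Rather than excluding affected patients
(which in an implant-rich cohort removes nearly everyone), whole axial
slices are excluded: a slice is dropped when *any* voxel on it exceeds the
artifact threshold, anywhere in-plane, because streaks corrupt the whole
plane and not only the masked gland. The threshold defaults to 2000 HU --
well above compact bone (~1000-1900 HU) and below metal -- and is
configurable. If every mask-bearing slice of a gland is artifacted, the
gland's features are *missing* for that patient (a classed condition, never
a zero fill).

### Texture matrices in 2D with slice exclusion

Because excluded slices leave disjointed voxel runs along the
superior-inferior axis, run- and co-occurrence statistics are not computed
across slices. Instead, for each retained slice and each of the four
in-plane directions $(1,0), (1,1), (0,1), (-1,1)$:

* the **GLCM** counts ordered pairs of labelled voxels at the direction
  offset, accumulated symmetrically (both orderings -- the
  IBSI-benchmarked convention; the source analysis did not state its
  choice);
* the **GLRLM** counts maximal collinear runs of equal grey level; runs
  break at the mask boundary, at the slice boundary, and at label changes,
  so every labelled voxel lies in exactly one run per direction.

Scalar features are
$$\mathrm{SRE} = \frac{1}{N_r}\sum_{i,j} \frac{r(i,j)}{j^2}, \qquad
  \mathrm{IDM} = \sum_{i,j} \frac{p(i,j)}{1+(i-j)^2},$$
with $r(i,j)$ the count of runs of level $i$ and length $j$, $N_r$ the
total run count, and $p(i,j)$ the normalised co-occurrence probabilities.
Both lie in $(0, 1]$; SRE is 1 exactly when all runs are singletons, and a
homogeneous region of width $w$ along the run direction gives $1/w^2$.

Per-patient values are the *unweighted arithmetic mean over all non-empty
(slice, direction) fragments* (per-slice, per-direction computation
followed by a single average). Unweighted averaging matches the referenced
aggregation identifier's definition; area-weighted averaging is a
deliberate non-default. Empty fragments -- a slice with fewer than two
labelled voxels, or a direction along which no two labelled voxels are
collinear-adjacent -- are skipped in both numerator and denominator, never
imputed as zero. The adjacency rule is what makes the 3D mode reduce
cleanly: on a single-slice region the nine out-of-plane directions carry
no run information and are skipped rather than contributing artificial
all-singleton runs.

### The reference 3D mode

For artifact-free glands the package also computes the 13-direction 3D
mode (the unique directions of the 26-connected neighbourhood): one matrix
per direction accumulated over the whole gland, the scalar feature per
direction, then the same skip-empty average over directions. 3D mode is
only defined without slice exclusion, since 3D runs must not jump
artifacted gaps. The 2D/3D comparison (`compare_2d_3d()`) reports the
Pearson correlation of the two SRE variants over artifact-free parotids,
mirroring the methodological question of whether the slice-wise 2D
computation preserves the 3D feature's ordering of patients: the expected
behaviour, which the test suite verifies on generated glands, is high
correlation with occasional rank inversions.

## Statistical models

Radiomics features are z-score normalised across the analysed patients
(mean 0, sd 1, denominator $n-1$); missing values stay missing, and a
zero-variance feature is an error naming the offending feature. Subgroup
analyses re-normalise within the subgroup -- the feature scale is then
defined by the patients actually modelled.

For each endpoint the *reference* model is a logistic regression on
baseline toxicity grade and mean gland dose (contra-lateral parotid for
xerostomia; bilateral submandibular for sticky saliva), and the *extended*
model adds the radiomics feature (SRE for `Xer12m`, maxHU for `SS12m`).
Baseline toxicity enters as the numeric 1-4 grade by default -- one degree
of freedom, matching the single-coefficient dose and feature terms -- with
the binary grade >= 3 encoding available via
`replication_config(baseline_binary = TRUE)`. Fitting is maximum
likelihood via iteratively reweighted least squares (relative tolerance
$10^{-8}$, at most 100 iterations), and is deterministic. Perfect
separation is flagged but the fit is returned, so the likelihood-ratio
statistic remains computable.

The added value of the feature is tested by the likelihood-ratio test
$\Lambda = 2(\ell_{\text{ext}} - \ell_{\text{ref}})$ against
$\chi^2_{df}$, with $df$ the difference in estimable parameters (1 for one
added feature; an aliased column contributes 0). Univariate associations
use the Wald p-value of the feature's coefficient in a single-predictor
logistic model, which is the glm-based choice the replicated analysis made
where the original univariate test was not documented. Model performance
is the rank-based (Mann-Whitney, midranks for ties) AUC of the fitted
probabilities, evaluated on the whole analysed dataset -- *apparent*
performance, deliberately without cross-validation or optimism correction,
to maximise power in a replication setting. No multiplicity correction is
applied; the significance level is two-sided 0.05.

Patients with any missing model input are dropped listwise per analysis,
with counts reported in each fragment. Subgroups below the configurable
floor (default 20) or with a single outcome class are reported as
"not evaluable" with the reason, never silently skipped. The analysed
subgroups are: everyone; both submandibular glands intact; under half of
the contra-lateral parotid slices excluded; and the modal fractionation
schedule (65 Gy in 30 fractions).

## The synthetic cohort generator

The generator defines the study conditions under which the pipeline is
exercised and validated; its defaults are fixed, not tuning knobs.

* **Cohort size and grid.** 109 patients; voxels of
  $1.074 \times 1.074 \times 3.0$ mm; per-patient volumes of
  $56 \times 56 \times 16$ voxels holding an ellipsoidal contra-lateral
  parotid (~20-30 mm diameters) and two smaller submandibular glands.
* **Doses.** Mean contra-lateral parotid dose targets median 29.2 Gy with
  quartiles 14.6-34.9; bilateral submandibular mean dose targets 56.4
  (47.2-59.5) Gy. These marginals are strongly left-skewed, so doses are
  drawn from a bounded distribution defined by a monotone (Hyman) cubic
  quantile function anchored at the target quartiles, with tails extended
  by three inter-quartile ranges and clipped to [0, 70] Gy: the population
  quartiles equal the targets exactly by construction. (A symmetric
  truncated normal cannot match these quartiles, and even a two-piece
  normal truncated at 0 Gy misses the parotid targets by over 2 Gy -- the
  quantile-anchored form is the package's design choice.)
* **Texture.** In-gland HU are a stationary correlated Gaussian field
  (mean ~30 HU, sd ~20 HU): white noise smoothed by a separable Gaussian
  kernel whose in-plane sd is the *correlation length* (voxels); the axial
  sd is scaled by the spacing ratio so correlation is near-isotropic in
  mm while 2D and 3D features still differ realistically across 3 mm
  slices. A per-patient standard-normal latent texture score maps
  monotonically to correlation length (short correlation = fine texture =
  high SRE), giving a known ground-truth ordering; the test suite checks
  that mean extracted SRE decreases monotonically across a grid of
  correlation lengths.
* **Artifacts.** With probability 0.95 a patient carries implant slices;
  affected gland-bearing slices are hit independently at rate 0.35 (at
  least one), and each planted slice gets an in-plane streak overwritten
  at 3000 HU. The streak model is deliberately not a physical
  beam-hardening simulation -- triggering slice exclusion is all the
  pipeline consumes. The per-slice rate is chosen so that roughly
  three-quarters to four-fifths of patients lose under half of their
  parotid slices, matching the emulated cohort's published subgroup sizes.
* **Outcomes.** $P(\text{endpoint}) = \operatorname{logit}^{-1}(\beta_0 +
  \beta_{\text{dose}} \cdot \text{dose} + \beta_{\text{tex}} \cdot z +
  \beta_{\text{base}} \cdot \text{grade})$ with defaults
  $\beta_{\text{dose}} = 0.08/\text{Gy}$ (a typical logistic NTCP slope
  for salivary endpoints), $\beta_{\text{tex}} = 0.6$ per SD,
  $\beta_{\text{base}} = 0.5$ per grade. $\beta_0$ is calibrated on the
  realised linear predictors so that expected prevalence hits the targets
  (48 % for `Xer12m`, 33 % for `SS12m`). Baseline grades are drawn with
  ~6 % moderate-to-severe. Twelve-month grades are then drawn consistently
  with the binary indicator (grade >= 3 iff the endpoint fired).
* **Resections.** Each submandibular gland is absent with probability
  0.12 and the ipsilateral parotid with 0.04, reproducing the emulated
  cohort's mix of intact-gland subgroups; the contra-lateral parotid is an
  inclusion criterion and always present.
* **Reproducibility.** A single master seed drives every draw; per-patient
  volume seeds are derived from it, so any one patient is reproducible in
  isolation and the whole pipeline is byte-identical across reruns.

Two modes share one generative core and therefore identical doses,
baselines, latents and outcomes: `generate_cohort()` builds full CT
volumes for the imaging chain, while `generate_cohort_records()` replaces
extraction with noisy monotone transforms of the same latent scores -- the
fast path for statistical calibration studies (null rejection rates,
parameter recovery, prevalence checks) where the imaging chain is not
under test.

**What the generator does not emulate:** real anatomy (glands are
ellipsoids), beam-hardening physics, questionnaire measurement error, and
-- most importantly -- the true joint distribution of dose, texture and
outcome in any clinical cohort: marginals are matched, effect sizes are
user-set. Passing tests therefore demonstrate that the pipeline measures
what it claims to measure and that its tests are statistically calibrated;
they cannot demonstrate that SRE or maxHU predict toxicity in patients.

## Numerical and design notes

* Bin-edge ties: left-closed/right-open with a right-closed top bin;
  label arithmetic is integer after clamping, so there are no float
  boundary surprises at the printed HU values.
* GLCM symmetry: both orderings accumulated; probabilities normalised on
  demand; empty matrices propagate an explicit flag (`n_pairs = 0`,
  features `NA`), never silent zeros.
* GLRLM storage grows its run-length axis dynamically to the longest
  observed run.
* Degenerate directions (no collinear-adjacent labelled pair) are flagged
  empty -- see the aggregation section.
* The logistic fit delegates to R's `glm` (binomial IRLS); the
  likelihood-ratio test and the midrank AUC are computed by this package
  and are cross-checked in the test suite against independent
  implementations (`lmtest::lrtest`, `pROC::auc`) on the same fits.
* Submandibular pooling: with both glands intact, per-gland features are
  averaged; with one, that gland's value is used. The pooling rule for
  bilateral glands is not documented in the replicated analysis; averaging
  is this package's choice and is configurable in principle by supplying a
  different feature column to `replication_config()`.
* Intercept calibration solves a one-dimensional root (`uniroot`,
  tolerance $10^{-10}$) on the realised linear predictor; dose quantile
  anchoring is exact, not fitted.

## Problem sizes used by the test suite

The suite validates the texture code against exhaustive brute-force
oracles on 200 random masked 8x8 slices (exact count equality; features to
$10^{-12}$ or better) and a 6x6x6 volume in all 13 directions; calibration
properties use 1000 simulated tabular cohorts of n = 109 for the null
rejection rate and Kolmogorov-Smirnov uniformity of univariate p-values,
500 replicates of n = 2000 for coefficient recovery, 100 000 scores for
the binormal AUC limit ($\Phi(1/\sqrt{2}) \approx 0.760$), and 50
generated glands spanning correlation lengths 0.3-3.5 voxels for the 2D/3D
agreement property. These sizes keep every check well-powered while the
whole suite runs in about a minute on one CPU.

## Known limitations

* Only the named features (SRE, IDM, maxHU) ship; the registry accepts new
  matrix/summary pairs but wavelet, shape, and the wider first-order panel
  are out of scope.
* No DICOM RT-STRUCT parsing, resampling, registration, or metal-artifact
  reduction: volumes and masks must already share one voxel grid (NIfTI).
* Doses are scalar inputs; no dose-grid or DVH computation.
* Apparent AUCs are optimistic by construction; the package reports them
  as such and offers no optimism correction by design.
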