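# radsaliva

Slice-aware CT texture radiomics and toxicity models for salivary glands.

`radsaliva` is an R package for testing whether CT texture features of the
salivary glands add predictive value for late radiation-induced toxicity in
head-and-neck cancer, over and above mean gland dose and baseline symptoms.
It implements the full analysis chain used in replication studies of this
question, for cohorts where dental implants make whole-patient exclusion
impossible and force artifact-aware, slice-wise 2D feature computation:

* **Imaging core** — CT volumes and gland masks (NIfTI-1), metal-artifact
  slice exclusion (a slice is dropped when any in-plane voxel exceeds a
  configurable threshold, default 2000 HU), and intensity discretisation
  into 16 bins of 25 HU over [−200, 200] HU.
* **Texture features** — grey-level co-occurrence (GLCM) and run-length
  (GLRLM) matrices per retained slice in the four in-plane directions,
  averaged over all non-empty (slice, direction) pairs; a reference
  13-direction 3D mode for artifact-free glands. Features:

  $$\mathrm{SRE} = \frac{1}{N_r}\sum_{i,j}\frac{r(i,j)}{j^2}
    \in (0,1], \qquad
    \mathrm{IDM} = \sum_{i,j}\frac{p(i,j)}{1+(i-j)^2} \in (0,1],$$

  plus the raw-HU maximum (maxHU) over the retained region of interest.
* **Modelling** — z-score feature normalisation across patients; nested
  logistic models per endpoint (reference: baseline grade + mean dose;
  extended: + radiomics feature), compared by likelihood-ratio test
  `2(ℓ_ext − ℓ_ref) ~ χ²`; rank-based (midrank) AUC on the analysed data.
  Endpoints are moderate-to-severe xerostomia and sticky saliva at
  12 months (EORTC QLQ-HN35 grade ≥ 3), paired with the parotid SRE and
  the submandibular maxHU respectively.
* **Synthetic cohort generator** — complete synthetic patients (textured
  ellipsoidal glands in CT volumes, planted artifact streaks, calibrated
  dose marginals, logistic outcome model with known coefficients) so every
  pipeline stage is testable against ground truth.
* **Replication pipeline** — extraction, univariate table, per-subgroup
  model comparisons, 2D-vs-3D SRE agreement, and JSON/CSV reports.

## Worked example

```r
library(radsaliva)

spec   <- cohort_spec(n_patients = 60, seed = 42)
cohort <- generate_cohort(spec)          # CT volumes + masks + clinical table
report <- run_replication(cohort)        # extraction, models, subgroups
report
```

```
<analysis_report> 60 patients, config 1f6a70da
  xer12m  all                    n= 59  AUC 0.735 -> 0.732  LRT p = 0.845
  xer12m  smgs_intact            n= 42  AUC 0.727 -> 0.727  LRT p = 0.715
  xer12m  parotid_low_exclusion  n= 40  AUC 0.812 -> 0.823  LRT p = 0.516
  xer12m  fx_65gy_30             n= 41  AUC 0.703 -> 0.709  LRT p = 0.492
  ss12m   all                    n= 58  AUC 0.781 -> 0.870  LRT p = 0.004
  ss12m   smgs_intact            n= 43  AUC 0.762 -> 0.810  LRT p = 0.068
  ss12m   parotid_low_exclusion  n= 38  AUC 0.735 -> 0.868  LRT p = 0.004
  ss12m   fx_65gy_30             n= 40  AUC 0.745 -> 0.898  LRT p = 0.000
```

Each line is one endpoint × subgroup analysis: `n` patients with complete
model inputs, the apparent AUC of the reference model (baseline grade +
mean dose) versus the extended model (+ radiomics feature), and the
likelihood-ratio p-value for the added feature. In this generated cohort
the submandibular maxHU carries real signal into sticky-saliva prediction
while the extracted parotid SRE, diluted by binning and artifact
exclusion, does not reach significance for xerostomia at n = 60 — the
kind of pattern the pipeline is built to quantify.

The univariate table for the same run:

```r
uni <- report$univariate
uni[uni$endpoint == "xer12m", ]
```

```
 endpoint               predictor  n coefficient       p
   xer12m mean_dose_cl_parotid_gy 60      0.0496 0.00638
   xer12m      baseline_xer_grade 60     -0.0120 0.98047
   xer12m       cl_parotid_sre_2d 59     -0.1030 0.70573
   xer12m       cl_parotid_idm_2d 59      0.1054 0.70064
   xer12m        cl_parotid_maxhu 59     -0.0251 0.92649
```

Mean parotid dose is univariately associated with xerostomia (p = 0.006);
the z-scored texture features are not. `emit_report(report, "out/")`
writes `report.json`, `univariate.csv`, `model_comparisons.csv` and
`features.csv`; `write_cohort()`/`read_cohort()` round-trip cohorts
through the on-disk contract (per-patient NIfTI volumes and masks plus
`clinical.csv`).

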