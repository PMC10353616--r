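# dalff

Temporal dynamics of spontaneous brain activity in resting-state fMRI:
sliding-window **dynamic ALFF** (amplitude of low-frequency fluctuation)
analysis as a reusable, tested R pipeline.

Static ALFF summarises a voxel's low-frequency power once for a whole run,
discarding how local activity waxes and wanes. Clinical resting-state
studies — for example of motor-pathway reorganisation after basal ganglia
stroke — instead compare the *variability* of windowed ALFF between a
patient group and controls, and then ask whether that variability tracks
bedside scores (NIHSS, Barthel Index, Fugl-Meyer). This package implements
that full analysis for researchers who want it scripted, seeded and
testable end to end:

- **Preprocessing**: initial-volume removal, per-voxel linear detrending,
  nuisance regression (Friston-24 motion expansion, WM/CSF series),
  Gaussian spatial smoothing.
- **dALFF-CV maps**: windowed one-sided DFT amplitude, per-window
  global-mean normalisation, and the coefficient of variation
  CV = SD/mean across windows — for a run of `T` volumes, window length
  `L` and step `s` there are `floor((T - L)/s) + 1` windows
  (127 for `T = 176`, `L = 50`, `s = 1`).
- **Group inference**: voxelwise OLS with age/sex/education covariates
  (exactly the pooled two-sample t without covariates), Gaussian random
  field cluster correction (expected Euler characteristic at threshold
  `u`, exponential cluster-extent tail `P(n >= k) = exp(-beta k^(2/3))`),
  and a Freedman–Lane max-cluster-size permutation test as the
  nonparametric reference.
- **Clinical association**: ROI means, Spearman correlations
  (t-approximation p), ROC/AUC (Mann–Whitney with tie half-credit),
  pooled t and Pearson chi-square demographics tables.
- **Synthetic cohorts**: a seeded generator planting group- and
  region-dependent slow amplitude modulation on band-limited, spatially
  coherent oscillations with AR(1) noise and nuisance structure, plus
  clinical scores monotonically coupled to the planted severity — so
  every stage can be validated against known ground truth.

## Worked example

Simulate a 15 + 15 cohort at the default geometry (20 × 24 × 18 grid,
3 mm voxels, 186 volumes at TR 2 s, one planted 9 mm "rectus_R" sphere
with envelope depth 0.6 in patients) and run the whole pipeline:

```r
library(dalff)

cfg <- load_config(list(
  paths    = list(out_dir = "dalff_out"),
  simulate = list(n_patients = 15, n_controls = 15),
  seed     = 11))
res <- run_pipeline(cfg)

res$clusters
#>      label size_voxels peak_stat peak_x peak_y peak_z   cluster_p tail
#> 1 rectus_R         141  9.019698     39     27     18 0.001989563  pos

res$correlations
#>     region  scale        rho          p
#> 1 rectus_R  NIHSS -0.4285714 0.11096021
#> 2 rectus_R WE_FMA  0.5392857 0.03802166
#> 3 rectus_R UE_FMA  0.5928571 0.01984642
#> 4 rectus_R LE_FMA  0.4607143 0.08393338
#> 5 rectus_R     BI  0.5071429 0.05366366

res$roc$rectus_R$auc
#> [1] 1
```

Reading the output: group inference finds exactly one significant cluster
(GRF-corrected, voxel p < 0.05, cluster p < 0.05), a 141-voxel region
whose peak t of 9.0 sits at world coordinates (39, 27, 18) mm — inside the
planted sphere, which the report labels by maximal ROI overlap. Patients'
mean CV in that region correlates negatively with the generated stroke
severity score (NIHSS, rho = −0.43) and positively with the function
scales (rho = 0.46–0.59), matching the signs of the planted couplings, and
separates patients from controls with AUC = 1.0. The output directory
holds per-subject CV maps, t/z maps (NIfTI), the cluster and correlation
tables (TSV), a demographics table, a run log with every convention in
force, and a manifest with config snapshot and product checksums.

A thin command-line wrapper over the same functions lives in
`inst/cli/dalff.R` with verbs `simulate`, `preprocess`, `cv`, `group`,
`clinical` and `run`.

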