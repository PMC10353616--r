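---
title: "Methods: windowed ALFF variability, cluster inference, and the synthetic cohort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: windowed ALFF variability, cluster inference, and the synthetic cohort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The statistic

The amplitude of low-frequency fluctuation (ALFF) of a BOLD voxel series
$y_0,\dots,y_{N-1}$ sampled at interval $TR$ is the mean one-sided discrete
Fourier amplitude

$$\mathrm{ALFF} = \frac{1}{|K|}\sum_{k\in K} \frac{2\,|X_k|}{N},
\qquad K = \{k : f_{\mathrm{lo}} \le k/(N\cdot TR) \le f_{\mathrm{hi}}\},$$

with the band defaulting to 0.01–0.08 Hz. With this amplitude convention a
unit sinusoid sitting exactly on a DFT bin contributes amplitude 1 at its
bin, which makes worked examples exact; any fixed convention cancels in the
normalised quantities below. The low edge of the conventional band and the
frequency resolution of a 50-volume window at $TR = 2$ s coincide at
0.01 Hz, so the default band spans DFT bins 1–8 of a window.

Dynamic ALFF (dALFF) computes ALFF inside a sliding window of $L$ volumes
advanced by $s$ volumes, giving $\lfloor (T-L)/s\rfloor + 1$ windows (127
for $T=176$, $L=50$, $s=1$). Each window's map is divided by its own
in-mask mean (mALFF normalisation), removing global amplitude effects
window by window; a configuration switch (`normalize_by = "run"`) divides
by the static whole-run mean instead, and the windowed maps are otherwise
untapered (a rectangular window) because the series is already detrended.
Each voxel's across-window variability is summarised as the coefficient of
variation

$$\mathrm{CV} = \mathrm{SD}_{\text{windows}} / \mathrm{mean}_{\text{windows}},$$

with the $n-1$ SD denominator. CV is invariant to global rescaling of the
run (per-window normalisation cancels scale), nonnegative, and zero for any
oscillation whose windowed amplitude is window-invariant. Voxels whose
window-mean ALFF is nonpositive (possible only off-mask or in degenerate
input) are set to 0 and counted in the map's `n_nonpositive` attribute.

## Preprocessing

Four desk-scale steps, applied in a fixed order by `preprocess_run()`:

1. **Initial-volume removal** (default 10 volumes) for magnetisation
   equilibration.
2. **Linear detrending** per voxel (exact OLS line removal).
3. **Nuisance regression** on `[intercept | regressors]` — typically 24
   Friston-style motion columns plus white-matter and CSF series. The
   linear trend is removed once in step 2, and step 3's design carries
   only an intercept beyond the supplied regressors, so the same trend is
   never fitted twice.
4. **Gaussian smoothing** with per-axis
   $\sigma = \mathrm{FWHM}/(2\sqrt{2\ln 2})$ in voxel units, kernel
   truncated at $4\sigma$ and normalised to unit sum. Boundary handling is
   zero padding: synthetic brains are interior ellipsoids, so the edge
   policy does not touch in-mask analysis, but a constant field is
   consequently preserved only beyond one kernel radius from the grid
   border. Smoothing operates on the full volume; masks are applied at
   analysis time. A configuration switch (`smooth_stage = "cv"`) smooths
   the CV map instead of the BOLD series for sensitivity analyses, since
   the field's conventions differ on where smoothing belongs relative to
   windowing.

Mean framewise displacement is computed from supplied motion series
(rotations on a 50 mm sphere) for quality reporting; no volume censoring is
applied. Realignment, slice timing and spatial normalisation are out of
scope: inputs are assumed to live in a common grid.

## Group inference

Per voxel, an OLS fit of the subject CV values on
`[intercept, group, age, sex, education]` (covariates mean-centred, sex
coded 0/1) tests the group contrast; with no covariates this is exactly the
pooled-variance two-sample t. The t field maps to z through the probit
transform of the t CDF, evaluated on the log scale in the matching tail for
numerical stability.

**Smoothness** is estimated from the standardised GLM residuals: per axis,
the mean squared first difference between in-mask neighbours of the
unit-normalised residual maps estimates the derivative variance $\lambda$,
giving $\mathrm{FWHM} = v\sqrt{4\ln 2/\lambda}$ (voxel size $v$) and
$\mathrm{resels} = |\Omega| \prod v / \prod \mathrm{FWHM}$. The discrete
difference slightly overestimates FWHM at low smoothness (about +9% at
2 voxels FWHM) and cannot report below $\sqrt{2/\ln 16}$ voxels; both
properties are inherited by every residual-difference estimator of this
family and are covered by simulation tests with 15% tolerance.

**GRF cluster correction** thresholds the z field at
$u = \Phi^{-1}(1 - p_{\mathrm{vox}}/2)$ per tail (two-sided by default;
the implementation requires $u > 1$, where the Euler-characteristic
density is positive), forms clusters under 26-connectivity (6 and 18
available), and assigns each cluster of $k$ voxels the family-wise
p-value

$$p = 1 - \exp\bigl(-E[m]\, P(n \ge k)\bigr), \qquad
P(n \ge k) = \exp(-\beta k^{2/3}),$$

where $E[m]$ is the expected cluster count from the 3D
Euler-characteristic density at $u$ times the resel count (doubled for a
two-sided search), and $\beta$ matches the expected cluster size
$E[N]/E[m]$ through the Gamma moment of the $2/3$-power law. Reports carry
the threshold, FWHM, resel count and the method that produced each
p-value.

**Permutation correction** is the package's calibration reference:
Freedman–Lane residualisation on the nuisance covariates, permutation of
the reduced-model residuals over subjects, refit of the full model, and
the maximum suprathreshold cluster size as the null statistic, with
$p = (1 + \#\{\max_{\mathrm{perm}} \ge k\})/(1 + n_{\mathrm{perm}})$.
Exchangeability makes this exact under the group null, and simulation
places its family-wise error at the nominal level (the acceptance suite
measures it on 400 null cohorts).

A limitation worth knowing: with a lenient cluster-forming threshold
(voxel $p = 0.05$) on smooth fields, the max-*size* statistic has little
power for compact effects, because the cluster extent saturates at the
region's size and strongly unbalanced relabelings recreate it — the
attainable p-value is bounded below by the tail probability of such
imbalance, not by $1/(1+n_{\mathrm{perm}})$. Detection of strong compact
effects therefore favours the GRF path or a stricter cluster-forming
threshold; the permutation path remains the arbiter of error control
under the null.

## Clinical association

ROI summaries are arithmetic means of the CV map over user-supplied masks.
Spearman's rho is the Pearson correlation of average ranks with a
two-sided t-approximation p-value (exact permutation available for
$n \le 10$). ROC/AUC uses the rank-sum (Mann–Whitney) form, crediting ties
0.5, with the curve enumerated at every distinct score threshold. Group
demographics use the pooled-variance two-sample t (which reproduces the
printed group statistic for the published age moments, unlike the Welch
variant) and the Pearson chi-square *without* continuity correction (which
reproduces the printed sex statistic on the published counts; the
corrected version does not). Clinical scales are summarised as median
(Q1, Q3) with type-7 quantiles — published quartiles are not recomputable
without raw data, so the convention is documented rather than fitted. No
multiplicity correction is applied across the region-by-scale table by
default, mirroring common practice for these reports; Benjamini–Hochberg
adjustment is available behind `p_adjust = "BH"` and clearly marked as an
extension.

## The synthetic cohort generator

No public data accompany this analysis setting, so validation rests on a
seeded generator whose defaults are the study conditions: grid
$20 \times 24 \times 18$ at 3 mm isotropic, 186 volumes at $TR = 2$ s, an
ellipsoidal brain mask (semi-axes 0.45 of each extent), and group sizes
configurable down to desk scale. Each voxel series is

$$y(t) = \bigl(1 + d_v\, m(t)\bigr)\, A \sin(2\pi f t + \phi_v)
 + \text{drift}\cdot t + \textstyle\sum_j w_j g_j(t) + \varepsilon(t)$$

with AR(1) noise $\varepsilon$ (coefficient 0.3, marginal SD 0.5), a small
linear drift, and nuisance components $g_j$ (six random-walk motion series
expanded to 24 Friston-style columns, plus white-matter and CSF series)
with fixed loadings. The envelope $m(t) = \sin(2\pi t/P + \psi)$ has a
random per-subject phase; its depth $d_v$ equals the group's modulation
depth inside the effect ROIs (patients default to 0.6, jittered ±30% per
subject to create a severity axis) and the control depth elsewhere.
Clinical scores are monotone affine functions of that per-subject planted
severity plus Gaussian noise, clipped to each scale's admissible range —
negative coupling for severity-type scales, positive for function-type
scales — so zero coupling noise yields Spearman correlations of exactly
±1 and the sign pattern is recoverable end to end.

Four generator choices deserve explanation, because each removes a
variance term that would otherwise mask the planted effect without adding
any group information:

- **Spatially coherent carrier phase.** $\phi_v$ is a smooth random field
  (12 mm FWHM, SD 0.3 rad), not iid per voxel. Spontaneous low-frequency
  fluctuations are regionally coherent; equally important, spatial
  smoothing then preserves the oscillation while attenuating independent
  voxel noise, whereas iid phases would cancel the carrier by the same
  factor as the noise and destroy the signal-to-noise benefit of
  smoothing.
- **Window-commensurate carrier frequencies.** $f$ is drawn uniformly
  from multiples of 0.01 Hz inside the band (configurable back to a
  continuous draw). A constant-amplitude oscillation then has a
  window-invariant amplitude estimate, so amplitude "scalloping" from
  window placement — which survives global-mean normalisation as a
  per-subject spatial pattern — does not masquerade as temporal dynamics.
- **No background envelope by default.** A globally coherent envelope
  shared by both groups cancels only partially under per-window
  normalisation and leaves a rank-one between-subject mode that inflates
  null cluster sizes in both inference paths; the control depth therefore
  defaults to 0, and setting it above 0 deliberately recreates that
  regime.
- **Envelope period 252 s.** At the default geometry the 127 window
  centres span exactly $252$ s, one full envelope cycle, so the
  across-window modulation variance is independent of the random envelope
  phase $\psi$ and the planted per-subject severity maps onto measured CV
  with minimal multiplicative noise. For other run lengths the period is
  a free parameter and the phase dependence returns gradually.

What the generator does **not** emulate: hemodynamic response shapes,
physiological noise spectra, lesions, image-space motion artifacts, or
scanner physics. Passing tests therefore demonstrate that the pipeline
recovers amplitude-modulation effects of realistic size and location from
band-limited, spatially coherent, nuisance-contaminated series — not that
it is robust to every artifact of real patient data.

## Numerical choices

- Window-band bins are matched inclusively with a $10^{-9}$ relative
  tolerance so exact band edges land on their bins.
- The across-window SD uses the two-pass (centred) formula; the one-pass
  moment formula loses half the significand for near-constant windows.
- Cluster labelling is union-find over in-mask voxels in scan order, so
  labels are deterministic.
- All seeds derive deterministically from one master seed (subject index
  and stream offsets), keeping every stage reproducible bit for bit;
  truncated-normal demographics use inverse-CDF draws for the same
  reason.
- Degenerate inputs fail loudly: empty ROIs, rank-deficient designs
  (offending columns named), bands containing no DFT bin, windows longer
  than the series, nonpositive global means.

## Problem sizes used in the test suite

Unit and property tests run on grids between $8^3$ and
$20\times24\times18$ with 40–186 volumes. The family-wise error suite
uses 400 null cohorts of 10+10 subjects on a $12\times12\times10$ grid
with 80 volumes; parameter recovery uses two cohorts of 15+15 subjects at
the full default geometry. These sizes were chosen so the whole suite
exercises every code path at meaningful statistical resolution while
remaining comfortable to run on a laptop.
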