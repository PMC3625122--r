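---
title: "Dissociating pattern reliability from signal amplitude in simulated audiovisual fMRI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissociating pattern reliability from signal amplitude in simulated audiovisual fMRI}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avmvpa)
```

## The question the package addresses

When a visual stimulus is accompanied by a congruent or incongruent sound,
multivoxel decoding of stimulus identity from early visual cortex can change
even though the mean BOLD response does not. `avmvpa` provides a complete,
seeded simulation-and-analysis environment for that phenomenon: it
synthesises event-related fMRI data in which the *trial-to-trial scatter* of
activation patterns depends on audiovisual context while the stimulus
templates and the mean amplitude are held fixed, and it implements the full
analysis chain — run-wise trial GLMs, four-way SVM decoding, split-half
pattern reliability, inter-stimulus pattern similarity, ROI amplitudes,
searchlight mapping with permutation cluster inference, phase-encoded
retinotopy, and the group statistics that compare them.

## The generative model

For ROI $R$ with $V$ voxels, each of the four stimuli $s$ has a fixed
template $\mathbf{t}_s \in \mathbb{R}^V$ with $\|\mathbf{t}_s\| = 1$,
*identical across conditions*. A trial of stimulus $s$ in condition $c$
evokes the pattern

$$\mathbf{x}_{s,c} \;=\; g_c\,(\mathbf{t}_s + \boldsymbol\eta) + \mathbf{b},
\qquad \boldsymbol\eta \sim \mathcal N(0, \sigma_c^2 I),$$

with a common per-voxel intercept $\mathbf{b}$. The gain $g_c$ is equal
across the three visual conditions (AV congruent, AV incongruent, V) and
zero for the auditory-only condition A, whose patterns are intercept plus
noise only (with $g=0$ the pattern noise enters at unit gain, so A patterns
are non-degenerate but carry no stimulus information). Because the noise
sits *inside* the gain, amplitude (controlled by $g_c$) and pattern
stability (controlled by $\sigma_c$) are separate dials: conditions can
differ in decodability and reliability while their mean amplitude is
identical by construction.

Two structural facts make the dissociation sharp:

* **Reliability** correlates the odd-run and even-run mean patterns of the
  *same* stimulus. The two halves have independent noise, so the expected
  correlation is the attenuation factor
  $v_t / (v_t + \sigma_c^2 / n_\text{half})$ — strictly decreasing in
  $\sigma_c$.
* **Similarity** correlates the all-run mean patterns of *different*
  stimuli after mean correction. Mean correction (subtracting the
  across-stimulus mean within each run and condition) imprints a $-1/3$
  correlation on both the template part *and* the shared noise part, so the
  expected inter-stimulus correlation is $-1/3$ *independent of*
  $\sigma_c$. Similarity therefore stays flat across conditions while
  reliability and accuracy move — this is the model's account of why
  reduced decodability can reflect reduced reliability without any change
  in the separation structure of the class centroids or in amplitude.

## Default parameters (the study conditions)

| dial | default | meaning |
|---|---|---|
| subjects | 15 | group size for the repeated-measures statistics |
| runs | 18 | per subject (17–24 supported) |
| trials per run | 16 stimulus + 4 blank | 4 stimuli × 4 conditions, randomised order |
| timing | 3 s stimulus + 2 s ISI, TR 2.72 s, 42 volumes/run (3+2 dummies) | a run spans 114.24 s |
| gains $g_c$ | 1, 1, 1, 0 | AV congruent, AV incongruent, V, A |
| noise SD $\sigma_c$ | 0.7, 1.1, 0.7, 0.7 | pattern perturbation per condition |
| ROI size | 150 voxels | per region (V1/V2/V3 analogues) |
| intercept | $\mathcal N(0.5, 0.1)$ per voxel | common across conditions |

With unit-norm templates the pairwise template separation is $\sqrt 2$, so
$\sigma \in [0.7, 1.1]$ puts four-way decoding well off ceiling and off
floor (roughly 0.30–0.45 observed accuracy), which is what lets a noise
difference express itself as an accuracy difference. The incongruent
condition's larger $\sigma$ is the modelled effect; all other dials are
equal across conditions so any amplitude or similarity difference in the
output would be a bug, not a finding.

## Analysis chain

**GLM.** Each run is modelled separately: one HRF-convolved 3 s boxcar
regressor per trial type (16), one for blanks, one for the response
intervals, optional nuisance columns, and a constant. The HRF is the
canonical double-gamma, $h(t) = \Gamma(6,1)(t) - \Gamma(16,1)(t)/6$ on
\[0, 32\] s, peak-normalised; convolution is done at 16× oversampling and
sampled at acquisition times. Estimation is ordinary least squares with
i.i.d. noise — no prewhitening or temporal filtering, matching the
simulator's white noise. Trial t-maps feed the multivariate analyses;
uncorrected betas feed the amplitude analysis.

**Decoding.** The four-way classifier is six pairwise linear SVMs (cost
$C = 1$, no kernel, no feature scaling — mean correction is the only
normalisation) combined by one-against-one voting. Ties are broken by the
largest sum of signed decision values among the tied labels, then by the
lowest stimulus index; the rule is deterministic. Accuracy is the
unweighted fold mean of a leave-one-run-out jackknife (folds are balanced
by construction, four test patterns each).

**Correlation measures.** Correlations are Fisher z-transformed before any
averaging, with the argument clipped at $1 - 10^{-12}$ so noiseless data
produce large finite values rather than infinities. Odd/even parity is
defined on 1-based acquisition order (run 1 is odd). Mean correction is
per run and condition by default; a pooled-across-runs variant is
available via `mean_correct(..., by_run = FALSE)`.

**Searchlight.** A radius-4 sphere (257 voxel offsets) is centred on every
grey-matter voxel; spheres truncated at the mask edge use the available
voxels, and seeds with fewer than two in-mask voxels are left undefined.
Group inference on accuracy contrast maps uses a one-sample t-map
thresholded at one-sided $p < .001$, connected-component clustering
(6-connectivity by default; 18 available), and family-wise error corrected
cluster p-values from the permutation distribution of the maximum cluster
size under random sign flips of whole subject maps, estimated as
$(b+1)/(m+1)$. This permutation scheme replaces parametric random-field
cluster inference: it is self-contained, exact under exchangeability, and
testable. Simulated subjects share one grid, so no spatial normalisation
is needed.

**Retinotopy.** Mapping runs are 240 timepoints with the wedge completing
12 cycles (20 steps each) and the ring 20 cycles (12 steps each), spanning
8° of eccentricity. Per voxel, the series is converted to percent signal
change, linearly detrended, and Fourier transformed; the phase lag at the
stimulus frequency ($-\arg X_f$, mapped to $[0, 2\pi)$) gives polar angle
(wedge; clockwise from the upper vertical meridian) or eccentricity (ring;
linear in phase, 8° full scale — the ring moves in equal discrete steps,
so no logarithmic mapping is applied). Spectral SNR is the power at the
stimulus bin over the mean power of bins 3..Nyquist excluding the stimulus
bin ±1 and its second harmonic. The mapping SNR dial is the time-domain
amplitude-to-noise ratio. A constant hemodynamic delay offset exists
(`phase_to_coordinates(..., delay=)`) and defaults to 0, since the
simulator injects none.

**Group statistics.** One-sample and paired t-tests (two-sided
throughout), a one-way repeated-measures ANOVA from definitional sums of
squares with Greenhouse–Geisser $\varepsilon$ estimated from the
double-centred covariance ($\varepsilon$ bounded to $[1/(k-1), 1]$, forced
to 1 at $k = 2$ where the F-test reproduces the paired t exactly), and
within-subject SEMs by Cousineau subject-centring with Morey's
$\sqrt{k/(k-1)}$ correction. Zero-variance t-test input follows the
convention $p = 0$ if the mean differs from the null value, else $p = 1$,
and is logged. Post-hoc pairwise tests are reported uncorrected after the
omnibus test, matching common reporting practice.

## Numerical and design choices

* **Trial onsets** sit on a fixed 5 s grid (3 s stimulus + 2 s ISI)
  starting after the dummy period; no jitter scheme is modelled.
* **Scanner noise** is white Gaussian at the time-series level, which is
  consistent with the OLS estimator used downstream; no AR structure,
  drift, or motion is simulated, so passing tests say nothing about
  robustness to physiological confounds in real data.
* **Blank trials** generate no signal; they exist so the design matrix
  contains the blank regressor and the GLM stage is exercised realistically.
* **Smoothing** (a separable Gaussian utility with FWHM parameter) is off
  everywhere by default; whether 5 mm smoothing materially changes the
  synthetic results is left as a user experiment.
* **Detrending** in the spectral analysis is default-on but separable: a
  finite cosine is not exactly orthogonal to a linear trend, so detrending
  perturbs a pure cosine's phase at the $10^{-3}$ rad level; exactness
  checks use `detrend = FALSE` on trend-free input.
* **Degenerate classifier input** (e.g. identical rows across classes)
  never crashes: an unfittable pairwise machine contributes a zero
  decision value and votes for its lower-indexed label.
* **Problem sizes in the test-suite** are scaled to the desk: ROI analyses
  run at the full 18 runs × 150 voxels, searchlight and cluster-inference
  checks use 20×20×10 grids with 200–300 permutations, and the
  cluster-validity simulation uses 200 null datasets. These sizes give the
  Monte-Carlo resolution the assertions need (e.g. ±0.01 on a 0.05 type-I
  rate needs thousands of replicates, which the ANOVA check uses).

## What the simulation does and does not establish

Passing tests establish that the analysis chain is *internally correct*:
the GLM recovers injected amplitudes exactly on noiseless data, decoding
sits at chance without information, reliability tracks the injected noise
monotonically, similarity and amplitude stay flat when only noise varies,
cluster inference holds its family-wise error rate, and retinotopic phases
are recovered without bias. They do not establish anything about real
cortical data: real pattern noise is correlated across voxels and trials,
amplitudes drift, ROIs are delineated on surfaces, and hemodynamic delay
varies — none of which is modelled. The package's claim is that *if* the
data-generating process has condition-dependent pattern noise with fixed
templates and gains, this analysis chain detects it as a
reliability/accuracy deficit without spurious amplitude or similarity
effects.

## A worked run

```{r, eval = FALSE}
cfg <- default_config(n_subjects = 15)
res <- run_pipeline(cfg, quiet = TRUE)

# condition means per metric (V2 analogue shown in the README)
aggregate(value ~ condition + metric,
          subset(res$subject_table, roi == "V2"), mean)

# paired contrasts on decoding accuracy
res$group[["V2.accuracy"]]$pairwise
```

The same computation, scripted end-to-end with derived seeds, is what
`scripts/acceptance.R` runs.

## Known limitations

* Searchlight decoding in pure R is compute-bound: whole-brain maps at
  realistic grids are feasible but slow; the implementation is intended
  for the simulation scales used here.
* The auditory-only condition shares its noise SD dial with the visual
  conditions' scale, but its patterns are baseline noise; modelling
  auditory-cortex responses is out of scope.
* No surface-based analysis, atlas labelling, foveal-confluence handling,
  or realistic preprocessing (motion, distortion, normalisation) is
  provided; simulated subjects share a common grid by construction.
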