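---
title: "Modeling error awareness in event-related fMRI: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modeling error awareness in event-related fMRI: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eatfmri)
```

# The scientific problem

When people commit errors in fast-paced tasks, only some of those errors
reach conscious awareness. The Error Awareness Task (EAT) measures this: a
serial stream of color words is shown, each for 900 ms followed by a 600 ms
blank. When the ink color is incongruent with the word (a Go trial) the
subject presses a left button; when word and color match (a No-Go trial) the
response must be withheld. Crucially, whenever subjects notice that they
failed to withhold, they are trained to replace the next Go response with a
dedicated right-hand "awareness" press. A commission error followed by an
ordinary left press on the next Go trial is therefore an *unaware* error; any
other pattern after a commission error (the awareness press, or any deviation
from the left-left pattern) marks an *aware* error.

`eatfmri` implements the full analysis chain for this paradigm — trial
sequence generation, behavioral metrics, subject-level hemodynamic
deconvolution, group-level cluster-extent inference, and trait association by
sparse regression — together with a synthetic-cohort generator with known
ground truth, so every stage is testable end to end without access to any
scanner data.

# Task design and its constraints

The default task consists of 6 blocks of 175 trials (150 No-Go, 900 Go in
total) with 30 s rests between blocks. No-Go trials are placed
pseudorandomly with between 1 and 12 Go trials separating consecutive No-Go
trials, so that error events are spaced well enough for event-related
analysis. The generator draws inter-No-Go gaps uniformly on `[min_gap,
max_gap]` and then makes random unit adjustments, within bounds, until the
exact Go budget is met; this documents the placement distribution precisely
(any constraint-satisfying sampler would be acceptable). Two further rules
are ours: a No-Go trial never opens a block, so a pre-error Go reaction time
always exists for the post-error statistics, and gap constraints are applied
across block boundaries (counting Go trials only), which is the stricter
reading. Because the gap budget is consumed exactly, the realized mean gap
is close to 6.0; the published task reports a mean gap of 6.23, which cannot
be reconstructed exactly without the original placement script — the package
matches the counts and the gap range, which are the constraints that matter
downstream.

Trial onsets are purely deterministic: trial $k$ of a block starts at
$t_0 + 1.5k$ seconds.

# The synthetic cohort

The generator plants known parameters at three levels.

**Behavior.** Each No-Go trial is withheld with probability `p_inhibit`
(default 0.536) and each commission error is signaled with probability
`p_aware` (default 0.865); Go reaction times are lognormal with mean 518 ms
and SD 81 ms. Error presses are shifted −29 ms (to-be-signaled errors) or
−10 ms (unsignaled), awareness presses are fast (−150 ms), 2% of Go trials
are omissions, and a +19 ms slowing is planted on the third trial after each
unsignaled error — the quantity the post-No-Go adjustment statistic
measures. These defaults correspond to the published cohort profile for this
task. Between-subject trait variability in the response probabilities is not
modeled: subjects differ only by sampling, which is what the binomial
recovery tests assume.

**BOLD.** Voxel time series are built as
$\mathrm{baseline} + \sum_c a_c\, (s_c * h) + \mathrm{drift} + \varepsilon$,
where $s_c$ is the TR-binned event train of condition $c$ (aware error,
unaware error, correct inhibition), $h$ is a ground-truth gamma-variate HRF,
the drift is a low-order Legendre polynomial, and $\varepsilon$ is AR(1)
Gaussian noise smoothed spatially to a target FWHM (default 6 mm on 3 mm
voxels). The baseline is 100 arbitrary units so percent signal is directly
interpretable. Two deliberate choices: the amplitudes $a_c$ are expressed in
*percent-of-baseline-area* units over the response window, so the pipeline's
percent-area estimates are directly comparable to the planted values; and
spatial smoothing is applied to the noise only, keeping the planted signal
confined to its region masks — otherwise amplitude recovery checks would
inherit an arbitrary mask-blurring factor. Region masks must be disjoint and
inside the grid. One consequence of edge-renormalized smoothing is that the
marginal noise variance is somewhat higher at grid edges than in the
interior; the null-cluster simulation uses the same machinery, so the
calibration is self-consistent.

The default grid is 24 × 24 × 18 voxels of 3 mm — a desk-scale volume that
keeps whole-cohort simulations tractable while being large relative to the
smoothing kernel. The generator does not attempt anatomical realism, motion,
physiological noise, or multi-band artifacts; passing recovery tests
demonstrate correctness of the estimators under the stated noise model, not
robustness to real-scanner artifacts.

**Traits.** The 22 questionnaire subscales (BIS-11, AQ, BIS/BAS, HADS,
CAARS) are drawn from a multivariate normal with a block correlation
structure (within-instrument 0.4, between 0.1 by default). A planted effect
$\beta$ for a predictor mixes the standardized outcome into that column as
$x_j \leftarrow \sqrt{1-\beta^2}\,z_j + \beta\,\tilde y$, making $\beta$ the
population predictor–outcome correlation. Whole questionnaire rows go
missing completely at random at rate 20/402 by default.

# Subject-level analysis

The impulse response of each No-Go outcome class is estimated by FIR
deconvolution: 8 lagged indicator regressors per class at TR = 2.46 s
resolution (window 0–19.68 s), alongside regressors of no interest (an
HRF-convolved omission train and a rest boxcar) and Legendre drift up to
order 3, fitted by ordinary least squares per voxel. Events are binned to
the nearest TR; sub-TR timing is not modeled. A fixed-shape basis would also
have been defensible here, but fitting "the best gamma variate to the
estimated IRF" presupposes an unconstrained IRF estimate, so FIR is the
coherent choice. AR(1) noise is tolerated by OLS (no prewhitening); this
inflates coefficient variance slightly but leaves estimates unbiased, and
all downstream calibration is empirical.

A gamma variate $h(t) = A\,t^r e^{-t/b}$ is then fitted to each estimated
IRF by least squares. The amplitude enters linearly, so it is profiled out
analytically and the search runs over $(r, b)$ only: a dense log-spaced grid
(shape $r \in (0.5, 20]$, scale $b \in (0.05, 5]$ s, peak time
$rb \in [2, 10]$ s) followed by a per-voxel coordinate refinement that
halves the log-step eight times. The whole-map fit is fully vectorized; the
single-IRF interface adds a Nelder–Mead polish. An all-zero IRF returns the
flagged $A = 0$ fit. The closed-form area $A\,\Gamma(r{+}1)\,b^{r+1}$ is
checked against quadrature in the tests.

Activation is summarized as the *percent-area* statistic: the area under the
fitted gamma variate expressed as a percentage of the baseline area over the
window, $100 \cdot \mathrm{AUC} / (\beta_0 \cdot T_{\mathrm{win}})$, with
$\beta_0$ the GLM intercept (task baseline). Voxels with non-positive
baseline are masked. Noiseless end-to-end recovery of planted amplitudes is
exact to well under 1%.

# Group inference

The group map is a paired t-test of aware vs unaware percent-area maps
(df = n − 1). Voxels where both conditions are identical give t = 0; zero
variance with a nonzero mean is masked. The cluster-extent threshold is
calibrated by Monte Carlo simulation in the AlphaSim tradition: smooth a
white-noise volume to the estimated FWHM, standardize it empirically,
threshold two-tailed at the voxel-level p, record the maximum cluster size
under face (6-neighbor) connectivity, and repeat (10,000 iterations by
default). The selected extent is the smallest size whose exceedance
frequency is at most the corrected alpha (0.010) — a family-wise reading of
"occurred less than 1% of the time by chance", which is the conservative
interpretation of the two possible ones. Residual smoothness feeds the
simulation through the standard first-difference estimator,
$\mathrm{FWHM} = \Delta\sqrt{2\ln 2 / (-\ln\hat\rho)}$ with
$\hat\rho = 1 - \mathrm{var}(\nabla r) / (2\,\mathrm{var}(r))$ per axis.
Cluster volumes are voxel counts times voxel volume (1 mm³ = 1 µL); a
conventional hard floor (e.g. 250 µL) can be imposed on top of the simulated
threshold. Centers of mass are |t|-weighted world coordinates (RAS+,
0-based indices, grid centered on the origin by default); connectivity is
configurable (6/18/26).

Cluster means per subject and condition (the ROI stage) are unweighted voxel
averages, and brain–behavior associations use Spearman correlations with
Holm adjustment within one family per behavioral index. Pairwise post hoc
contrasts elsewhere in the behavioral module also use Holm rather than
Tukey's method: Holm is already required for the correlation tables, is
conservative for three conditions, and keeps the package to one adjustment
procedure (the published real-data post hoc values are not targets here).
The repeated-measures F test applies the Greenhouse–Geisser correction
computed from the double-centered condition covariance.

# Trait association

All variables (22 predictors and each outcome) are z-scored; lasso models
minimize $\frac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2 +
\lambda\lVert\beta\rVert_1$ with the penalty chosen by seeded 10-fold
cross-validation over a 100-point log grid from $\lambda_{\max}$ down
(ratio $10^{-3}$), using the minimum-CV rule — the simplest published
convention; the 1-SE rule is a configurable alternative left out of scope.
Stability selection reruns the *entire* procedure (including CV penalty
selection) on 500 bootstrap resamples and reports the percentage of
resamples in which each coefficient is nonzero; freezing the full-sample
penalty instead is available behind a flag, since the original procedure is
ambiguous on this point. Rows with any missing questionnaire value are
excluded and counted. Fits are delegated to coordinate descent at high
precision and verified against the Karush–Kuhn–Tucker conditions
($|x_j^\top r|/n \le \lambda$ for null coefficients, with equality at
$\lambda\,\mathrm{sign}(\beta_j)$ otherwise, tolerance $10^{-6}$); only the
Gaussian family is implemented because every outcome here is continuous.

# Numerical and scale choices

* Events binned with `floor(onset / TR + 0.5)`; FIR windows truncated at the
  run end.
* Null maps are standardized by their own empirical SD after smoothing, so
  the voxel threshold is exact regardless of kernel scale.
* A commission error on the final trial of the run has no following trial;
  it is classified by the error press itself (right press → aware),
  configurable via `final_trial_aware`. A No-Go error followed by a Go
  omission is aware, the literal reading of the classification rule.
* Post-No-Go adjustment events are dropped (not zeroed) when the pre-trial
  or third post-trial lacks a valid left-press RT, when another No-Go falls
  inside the three-trial window, or when the window crosses a block
  boundary.
* Residual smoothness is estimated from 12 evenly spaced residual volumes
  per subject; the volumes share one spatial field, so this loses nothing.
* Test problem sizes are the package's own desk scales: family-wise
  calibration runs the full 10,000-iteration selection on the 24 × 24 × 18
  default grid with 1,000 fresh validation maps; the end-to-end recovery
  suite uses 20 cohorts of 30 subjects on a 14 × 14 × 10 grid (same 3 mm
  voxels, full-length task) with the default planted aware−unaware
  difference of 0.5 percent-area; behavioral recovery uses 500 subjects.

# Known limitations

Percent-area estimates inherit a small nonlinearity from the gamma fit on
noisy IRFs; with the default event counts the resulting bias is an order of
magnitude below the sampling SE and is absorbed by the 3-SE recovery
criteria. The cluster threshold is calibrated on Gaussian fields but applied
to t-maps at the matched voxel-level p, the standard AlphaSim approximation;
with 29 degrees of freedom the difference is negligible at p = 0.001. The
unaware-error class is intrinsically rare (about 9 events per subject at the
default rates), so unaware estimates dominate the variance of the paired
contrast — as in the real paradigm. No attempt is made to reproduce
real-data cluster tables or coefficient values; those depend on the original
cohort.
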