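---
title: "Model-based cerebral hemodynamic indices: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model-based cerebral hemodynamic indices: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hemodyn)
```

## The problem

Dynamic cerebral autoregulation (the buffering of cerebral blood flow
against arterial-pressure fluctuations) and cerebrovascular CO2 reactivity
(the dilation of cerebral vessels when arterial CO2 rises) are candidate
vascular markers of Alzheimer's disease and related dementias. Both can be
probed without any intervention: during ~8 minutes of quiet rest,
spontaneous fluctuations of arterial blood pressure (ABP, finger
plethysmography, beat-to-beat) and end-tidal CO2 (ETCO2, capnography,
breath-to-breath) drive measurable responses in middle-cerebral-artery
blood velocity (CBV, transcranial Doppler) and prefrontal tissue
oxygenation (OXY, near-infrared spectroscopy, expressed as
oxyhemoglobin/total hemoglobin x 100).

`hemodyn` implements the full chain from those four raw signals to five
scalar indices per subject — DVR (dynamic vasomotor reactivity,
CO2 -> CBV), DCA (dynamic cerebral autoregulation, ABP -> CBV), COCR
(CO2 -> OXY), COPR (ABP -> OXY) and composite-COR (both oxygenation
pathways) — and to their covariate-adjusted associations with tabular
neuroimaging outcomes (hippocampal volume, WMH volume, AD-signature
cortical thickness, amyloid SUVR).

## The two-input linear dynamic model

For each output channel $y$ (CBV or OXY) we posit a finite-memory linear
convolution on the two inputs,

$$ y(n) = k_0 + \sum_{m=0}^{M-1} k_{ABP}(m)\, x_{ABP}(n-m)
        + \sum_{m=0}^{M-1} k_{CO2}(m)\, x_{CO2}(n-m) + \varepsilon(n), $$

with kernels $k$ in output units per input unit and memory $M$ samples.
Rather than estimating $2M + 1$ free parameters from a short record, each
kernel is expanded on $L$ discrete orthonormal Laguerre functions
$b_j(m)$ with decay parameter $\alpha$:
$k(m) = \sum_j c_j b_j(m)$. The expansion turns estimation into ordinary
least squares of $y$ on the basis-filtered inputs
$v_j(n) = \sum_m b_j(m) x(n-m)$ — a well-conditioned regression with
$2L + 1$ coefficients. A dedicated test verifies that on long broadband
records the compressed estimate coincides with the unconstrained
impulse-response least squares.

Defaults: $\alpha = 0.5$, $L = 4$ per input, $M = 60$ lags at
$T_s = 1$ s (60 s of memory). These follow common practice for
principal-dynamic-mode modelling of cerebral hemodynamics, where a few
Laguerre functions and one to two minutes of memory suffice; all three are
configuration keys, as is an optional ridge penalty for short or noisy
records (default 0).

## Preprocessing

1. **Outlier removal.** Samples beyond $\pm k$ SD of the channel's
   time-averaged value ($k = 3$) are deleted; mean and SD are computed on
   the original series. The pass runs once, not iteratively.
2. **Synchronization.** All channels are cubic-spline interpolated onto a
   shared uniform grid ($T_s = 1$ s by default) restricted to the common
   overlap window (>= 120 s required); no extrapolation ever occurs.
   $T_s = 1$ s resolves dynamics to 0.5 Hz, far above the < 0.15 Hz band
   that carries autoregulation and reactivity information, and matches the
   information content of breath-to-breath sampling.
3. **High-pass filtering.** Frequencies below $f_{cut} = 0.005$ Hz
   (slow drifts, probe and calibration trends) are removed by a zero-phase
   frequency-domain brick-wall filter together with the mean. A binary
   mask was chosen over a tapered transition because it is exactly
   idempotent; the leakage this leaves near the cut-off is dealt with at
   the estimation stage (below).

### Numerical choices in estimation

Two details make the pipeline numerically exact rather than approximately
right, and both are visible in the estimation design matrix:

- **Stopband drift regressors.** Zeroing a record's sub-cutoff Fourier
  bins perturbs every channel by a combination of exactly those sine and
  cosine terms. On rows with a full regressor memory, a sinusoid
  convolved with a finite kernel is the same sinusoid rescaled, so the
  filter's entire footprint on the regression lies in the span of the
  few stopband sine/cosine pairs. They enter the design as nuisance
  columns (as drift terms do in physiological GLMs), and the filter
  artifact is projected out exactly.
- **Gap-row exclusion.** A deleted outlier leaves a span that the spline
  bridges with imputed values. Regression rows whose input-memory window
  covers such a span (or whose output sample sits on one) carry corrupted
  information and are excluded, unless that would leave fewer than about
  five rows per parameter. The first and last $M$ samples are likewise
  excluded (convolution burn-in and filter edges).

With both in place, the estimator recovers in-basis kernels from
noiseless synthetic recordings with normalized mean-squared error around
$10^{-8}$ through the full irregular-sampling pipeline; the test suite
asserts $< 10^{-4}$.

## Principal dynamic modes and index construction

Estimated kernels for one pathway are stacked into a subjects-by-$M$
matrix and decomposed by SVD; the right singular vectors, ranked by
singular value, are the cohort's principal dynamic modes (PDMs). The SVD
is taken per pathway over the cohort ensemble — the SVD of a single
subject's kernel is degenerate, and the ensemble construction is the
established way to obtain a common dynamic basis. Retention: the smallest
$Q$ reaching 90% cumulative squared singular value, capped at 3. Each
mode's sign is fixed so its largest-magnitude element is positive, since
the SVD sign ambiguity must not flip gains between runs.

A subject's **gains** are inner products of their kernel with each mode.
For each APOE $\varepsilon$4 stratum (carriers and non-carriers are
modelled separately because the allele itself shifts cerebral
hemodynamics) and each mode, Gaussian reference distributions of the gain
are fitted in the cognitively unimpaired (CN) and impaired (MCI +
dementia) training groups; strata cells with fewer than 5 subjects fall
back to the pooled fit with a warning. The **log-likelihood ratio** of a
gain,
$\lambda = \ln N(g;\mu_{CN},\sigma_{CN}) - \ln N(g;\mu_{CI},\sigma_{CI})$,
is positive when the subject's dynamics resemble the unimpaired group.
Each index is a weighted sum of its pathway's per-gain LLRs; the weights
come from a logistic regression of impairment status on the LLR columns
(a linear-probability alternative would serve as well; "regression onto a
binary criterion" motivates the logistic default), rescaled to unit sum
of absolute values, oriented so that higher index means more CN-like, and
frozen. Perfect separation or collinear LLR columns trigger an
equal-weight fallback. Composite-COR uses the concatenated COCR and COPR
LLR columns with its own weight vector. PDMs, reference distributions and
weights are all fitted on a training cohort and never refitted at scoring
time.

The **physiological indices** are the raw counterparts: the steady-state
step response of each pathway, i.e. the kernel's DC gain
$T_s \sum_m k(m)$, in output units per input unit. A time-integrated
step-response reading ($T_s^2 \sum_n s(n)$) is exposed as a
configuration alternative; the DC gain is the default because it is the
asymptotic response to a sustained unit input change and has the natural
units of a reactivity. The LLR indices and the physiological indices can
dissociate by construction: a group difference along a zero-DC-gain mode
moves the former and not the latter, and a scenario test exercises
exactly that.

## Statistics battery

All continuous variables are z-scored (sample SD, within the analyzed
complete-case subsample of each model — the alternative, z-scoring once
on the full sample, changes nothing about tests and only rescales
coefficients; the per-model choice keeps every reported beta exactly
standardized for its own n). The battery mirrors standard cohort
practice:

- one-way ANOVA with Tukey HSD across CN/MCI/dementia;
- OLS of each z-scored outcome on each z-scored index with covariates
  age, sex, site, APOE $\varepsilon$4 and total MoCA score (site and sex
  as categorical contrasts; intracranial volume added for the volumetric
  outcomes); listwise deletion with the analyzed n reported;
- stratified fits (CN vs MCI + dementia), index-by-MoCA interactions,
  index-to-MoCA associations (age- and sex-adjusted), and a generic
  nuisance-covariate screen (e.g. recording hemisphere);
- Bonferroni control across the four primary measures:
  $0.05 / 4 = 0.0125$ per test, with p-values between 0.0125 and 0.05
  labelled "trend".

## The synthetic cohort generator

No human recordings ship with the package; every downstream stage is
exercised against a generator with known ground truth.

- **Inputs.** ABP and ETCO2 fluctuate around physiologic means (90 and
  38 mmHg; SD 4 and 1.5 mmHg) as random-phase harmonic processes with
  mildly red ($1/\sqrt{f}$ amplitude) spectra, band-limited to
  0.018–0.10 Hz (ABP) and 0.018–0.035 Hz (ETCO2). The bands are
  calibration choices: they sit inside the < 0.15 Hz regime the model
  exploits, stay clear of the 0.005 Hz cut-off, and — deliberately — do
  not exceed what beat/breath sampling can represent. The effective
  continuous stimulus is defined as the cubic-spline interpolant through
  the event-time samples (end-tidal CO2 only exists once per breath), so
  the generative model is self-consistent with the measurement process.
- **Timing.** Beat intervals are log-normal, clipped to 0.6–1.3 s;
  breaths to 2.5–7 s. Irregular timing guarantees the resampling stage is
  genuinely exercised.
- **Outputs.** CBV (sampled at beats) and OXY (at a regular 0.5 s device
  rate) are the exact two-input convolutions of the demeaned inputs with
  per-subject true kernels plus offsets, Gaussian noise, and
  Poisson-placed artifact spikes of 4–6 channel-SDs — large enough that
  the ±3 SD rule can remove them, and book-kept in a ground-truth sidecar
  so flagging can be scored.
- **Cohort.** Default sizes 61/45/27 (CN/MCI/dementia), ~41% APOE
  carriers. A latent severity (group-shifted, APOE-shifted) scales each
  subject's pathway kernels; its standardized pathway projections are
  stored as true indices. Neuroimaging outcomes are linear in the true
  indices at configured standardized slopes (defaults 0.26 for
  composite-COR on hippocampal volume, −0.25 on amyloid SUVR, −0.20 for
  DVR on WMH, 0.20 for COPR on cortical thickness) plus a residual scaled
  so the outcome is exactly standardized — a unit-variance residual would
  attenuate a configured 0.26 to about 0.25, so exactness was preferred.

What the generator does **not** emulate: nonlinear or time-varying
physiology, measurement drift and probe artifacts beyond additive spikes,
non-Gaussian outcome tails, site batch effects, or informative
missingness. Passing tests therefore demonstrate correctness of the
estimation and inference machinery under the stated model class, not
robustness to every feature of real recordings.

## Problem sizes and reproducibility

The test suite and the acceptance script run at deliberately modest
sizes: single 480 s recordings for kernel recovery, 1000-subject
kernel-level cohorts for discrimination, 200 Monte-Carlo cohorts at
n = 61/45/27 for the ANOVA/Tukey pattern, n = 2000 for effect recovery,
500 small cohorts for CI coverage, and a 32-subject end-to-end
determinism check. All randomness flows from explicit seeds; two runs of
`run_pipeline()` with the same configuration are byte-identical.

One interpretive note on the group-moment Monte-Carlo: at the reported
group moments and sample sizes, the Tukey significance pattern (CN above
both impaired groups; MCI and dementia not separable) is stable (~94% of
replicates), but the sample-mean ordering of MCI vs dementia is itself
within sampling noise (~84%). The replicate-level acceptance check is
therefore the significance pattern; the ordering is asserted as a
majority property.

## Known limitations

- The Gaussian reference family for gains is the simplest consistent
  with a scalar LLR; heavy-tailed gain distributions would call for a
  kernel-density extension (config-ready but not implemented).
- Training and scoring on the same cohort (as done in the end-to-end
  pipeline) gives optimistically biased in-sample discrimination; the
  package supports, but does not enforce, a held-out split.
- The linear two-input model deliberately omits nonlinear Volterra terms
  and classic transfer-function analysis; both are out of scope.
- Site enters as a fixed categorical covariate, not a random effect.
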