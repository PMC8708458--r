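---
title: "Methods: eNose breathprints and the PCA–LDA discriminant pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: eNose breathprints and the PCA-LDA discriminant pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathprint)
```

## The problem

Electronic noses (eNoses) measure exhaled volatile organic compounds with an
array of cross-reactive metal-oxide sensors. Rather than identifying
individual molecules, the array produces a composite response pattern — a
*breathprint* — that can be compared between clinical groups. `breathprint`
implements a complete analysis pipeline for one such design: discriminating
asthma patients who recently had an exacerbation (defined as oral
corticosteroid use for acute worsening of respiratory symptoms within the
preceding three months) from those who did not, using a SpiroNose-type
device with seven sensor types duplicated across breath-sampling and
ambient-air arrays.

Because the underlying patient data are private, the package pairs the
analysis pipeline with a first-class synthetic-data module that generates
whole studies — raw sensor maneuvers plus clinical cohort tables — with the
statistical structure the analysis assumes. Every stage is therefore
testable end to end, and the calibration between the simulated class
separation and the achievable AUC is available in closed form.

## The measurement and its conditioning

One maneuver consists of five tidal breaths, a single full inspiration, a
5 s breath hold and a slow maximal expiration. Each `SensorFrame` holds the
seven breath-channel and seven ambient-channel series on a shared uniform
time axis with phase annotations. Conditioning runs in one canonical order,
enforced by `conditionFrame()`:

1. **Resonance removal** (`removeResonances()`): zero-phase order-2
   Butterworth band-stop at the configured eigenfrequencies. The device's
   actual eigenfrequencies are not public, so the default notch list is
   empty for real data; for synthetic data the generator's injected
   resonance frequency (2.5 Hz by default) is used.
2. **Low-pass** (`lowpassFilter()`): Butterworth, order 2, 0.5 Hz cutoff,
   applied forward and backward. Zero-phase filtering is essential here:
   landmark *times* must not shift. Two passes square the magnitude
   response, so a single-pass half-power cutoff attenuates to 1/2 at the
   cutoff; tests check the closed form
   $|H(f)|^2 = 1/(1 + (f/f_c)^{2\,\mathrm{order}})$.
3. **Linear detrend** (`detrendLinear()`): the least-squares line over the
   whole maneuver is subtracted per channel, removing sensor drift.
4. **Ambient correction** (`ambientCorrect()`): per sensor, the ambient
   series is shifted by the lag maximizing its cross-correlation with the
   breath series (default search window ±2 s) and subtracted. The result —
   breath minus aligned ambient — is the working *alveolar gradient*: the
   response attributable to exhaled rather than inspired air. Two
   implementation details matter numerically. First, lag scoring uses
   copies of both series passed through a zero-phase 0.15 Hz high-pass
   (`alignHighpass`): the slow maneuver waveform carries no alignment
   information about the shared ambient component and would otherwise bias
   the correlation peak; this is standard prewhitening for time-delay
   estimation. Second, shifting a detrended series reintroduces a linear
   component, so the corrected signal is re-detrended with the line fitted
   on the interior of the record (excluding one lag window at each end,
   where shift padding and filter transients live). At lag 0 the correction
   reduces exactly to `breath - ambient`. Zero-variance channels fall back
   to lag 0 and are flagged.

`findLandmarks()` then takes, per sensor, the maximum of the conditioned
signal within the expiration phase (the *peak*) and the minimum within the
breath-hold phase (the *trough*), ties broken by earliest time. A
non-positive trough leaves the peak/trough ratio undefined; such subjects
are excluded with a logged reason rather than imputed.

## The 13-variable breathprint

Sensor peaks are normalized to sensor 2 (the most stable sensor), which
makes sensor 2's own normalized peak identically 1 and uninformative. The
feature vector is therefore 6 normalized peaks (sensors 1, 3–7) plus 7
peak/breath-hold-trough ratios (sensors 1–7) — 13 variables. This 6 + 7
decomposition is the only one consistent with both the normalization rule
and a per-sensor ratio; it is a reasoned convention of this package, since
the source description gives only the total count. Both feature families
are computed from the same conditioned (ambient-corrected) signals, and
both are invariant to a common rescaling of all channels.

## The discriminant engine

`runDiscriminantPipeline()` executes, on a `BreathFeatureSet` (a
`SummarizedExperiment` with the 13 × n feature matrix and the clinical
covariates in `colData`):

- **Split** — simple random 70/30 into training and validation
  (`splitCohort()`, `floor` convention: 361 subjects → 252 + 109). The
  split is *unstratified* by default because the emulated study's observed
  prevalences differ between parts (16.3% vs 10.1%), which is consistent
  with no stratification; a stratified option exists.
- **PCA** — correlation-scale (z-scored by training means/sds), via
  `prcomp`. The "standardization parameters" required for validation
  projection mandate the correlation scale. Components with eigenvalue
  ≥ 1.0 (Kaiser criterion, threshold inclusive) are retained. Eigenvector
  signs follow the largest-loading-positive convention so rotation
  matrices are reproducible across runs and platforms.
- **LDA** — two-class Fisher discriminant with pooled within-class
  covariance, written directly (the direction is
  $S_p^{-1}(\mu_1 - \mu_0)$, unit-normalized and oriented so the
  exacerbation class scores higher; `MASS::lda` serves as an independent
  cross-check in the tests, never as the implementation).
- **ROC/AUC** — the AUC is the Mann–Whitney concordance probability with
  ties counted ½; the ROC staircase has one vertex per distinct threshold.
  Tests verify exhaustive pair-counting equivalence and agreement with
  `pROC`.
- **LOO-CV** — each training subject is scored by a model fitted without
  it. Whether the published cross-validation refit the PCA per fold is not
  decidable from the source text; the default scope (`lda_only`) keeps the
  full-training PCA fixed and refits only the LDA stage per fold, matching
  the common `lda(..., CV = TRUE)` idiom in the ecosystem the original
  analysis used, with `full_pipeline` available as a config switch. Both
  scopes are tested against explicit fold loops.
- **Bootstrap CIs** — percentile intervals over stratified resamples
  (within-class, preserving class sizes), 10,000 iterations at study
  scale; neither the stratification nor the interval type is stated in the
  source, so both are documented package conventions.
- **Validation projection** — validation rows are standardized by the
  *training* means/sds, rotated by the *training* rotation, restricted to
  the retained components and scored by the *training* LDA. No validation
  statistic enters the transform; corrupting validation labels provably
  cannot change validation scores.

The cohort layer adds eligibility screening (COPD/lung-cancer diagnosis,
≥ 10 pack-years — inclusive boundary — and current antibiotic use),
dictionary-driven baseline tables (mean (SD) / median (IQR with
linear-interpolation quartiles, `type = 7`) / n (%)) with pooled-variance
t-tests, Wilcoxon rank-sum tests and Pearson chi-squared tests (no
continuity correction by default, Yates optional), and the three
sensitivity-analysis reruns (dropping recent antibiotic users, dropping
current smokers, keeping only maintenance-ICS users). Sensitivity reruns
keep the original train/validation membership and drop rows in place, so
the models stay comparable; test selection is dictionary-driven rather than
normality-tested per run, for reproducibility. A built-in consistency check
(`checkBaselineConsistency()`) recomputes every printed percentage from its
count; it flags, rather than reproduces, the one arithmetically
inconsistent cell in the emulated study's baseline table (the
maintenance-ICS percentage of the training no-exacerbation group).

## The synthetic-data generator

The generative core lives in feature space. Per subject,

$$ f = \mu_0 + s\,(Lz + \varepsilon + y\,\delta), \qquad z \sim N(0, I_4),
\quad \varepsilon \sim N(0, \psi^2 I_{13}), $$

where $L$ loads four latent factors on feature blocks of sizes 4/3/3/3 with
loading 0.9 ($\psi^2 = 0.19$, unit per-feature variance), $s = 0.12$ is the
feature scale, $y$ the class label and $\delta$ a shift of Mahalanobis
length $\Delta$ along the leading eigenvector of the covariance. The factor
structure mimics the cross-reactive, multicollinear sensor responses and
puts exactly four population eigenvalues above 1 (3.43, 2.62, 2.62, 2.62 on
the correlation scale), so Kaiser retention selects four components, and the
class signal lives inside the retained subspace. For two homoscedastic
Gaussian classes the optimal AUC is $\Phi(\Delta/\sqrt2)$;
`separationForTargetAUC()` inverts this, so simulations can be calibrated
to a target AUC (0.76 by default). At the study's sample size (252 training
subjects, 41 cases) the cross-validated AUC sits a little below the
asymptotic value — typically 0.72–0.75 at a 0.76 target — through the
familiar finite-sample attenuation of estimated discriminants, the same
effect that makes cross-validated accuracy lower than resubstitution
accuracy in the emulated study.

Raw maneuvers are then *back-solved* from the drawn features: sensor 2's
peak is anchored at its profile amplitude, the other peaks follow from the
normalized-peak features and the troughs from the ratios, so noise-free
conditioning recovers the drawn features exactly. The clean trace is built
from smooth phase templates (tapered tidal oscillation, half-cosine
inspiration descent, constant hold plateau, raised-cosine expiration rise
with a cosine decay to baseline) and is constructed to be *exactly
orthogonal*, in the discrete least-squares sense, to the span of
$\{1, t\}$ and of the contaminant harmonics — a minimum-intervention
baseline offset confined to the interior of the tidal window enforces the
constraints. Whole-maneuver detrending is therefore a no-op on the clean
component, and cross-correlation alignment is driven by the contaminant
alone. Nuisance components are added on top: linear drift
(0.005 units/s), a resonance sinusoid (2.5 Hz, amplitude 0.05), white
Gaussian noise (sd 0.02), and a shared ambient contaminant (integer-cycle
cosine mixture at 10/14/17 cycles per maneuver, amplitude 0.1) that appears
on the breath channels directly and on the ambient channels with a 0.5 s
lag over a constant baseline (0.2). Integer-cycle cosines are orthogonal to
a linear trend, so detrending does not distort the contaminant; the
harmonics sit just below the low-pass cutoff so that the cross-correlation
peak is sharp.

Sampling rate (10 samples/s), phase durations beyond the 5 s hold
(5 × 4 s tidal, 3 s inspiration, 10 s expiration), amplitude scales and all
nuisance levels are conventions of this generator, chosen once as plausible
for a ~40 s maneuver with sub-Hz artifacts; the maneuver protocol itself
fixes only the phase sequence and the hold duration. Clinical covariates
are drawn class-conditionally (Bernoulli frequencies, normals and
log-normals matched to the emulated study's pooled baseline tables, e.g.
38.5% vs 2.6% recent antibiotic use, no current smokers among cases,
pack-years truncated below the 10 pack-year eligibility cut because the
emulated cohort is the post-eligibility population). Covariates are
independent of the breath features given class: the generator deliberately
does *not* model covariate–feature confounding.

## What passing tests do and do not show

The suite verifies the pipeline against independent oracles (exhaustive
pair counting, explicit fold loops, explicit matrix arithmetic, FFT
spectral zeroing, closed-form filter responses and eigenvalues,
`MASS`/`pROC` cross-checks), reproduces every count and percentage
derivable from the emulated study's printed tables, and demonstrates
parameter recovery on synthetic data: 20-seed mean cross-validated AUC
within ±0.05 of the 0.76 target, null calibration at $\Delta = 0$,
monotonicity in $\Delta$, and 4-component Kaiser retention. Problem sizes
follow the emulated design (361 subjects, 252/109 split) with 10–20 seeds
for simulation averages and 2,000-iteration bootstraps in the tests
(10,000 in the study-scale profile).

None of this validates the *clinical* claim on real data: the generator's
Gaussian latent-factor world contains no covariate–feature confounding, no
device drift between visits, no site effects, and its nuisance components
(linear drift, stationary contaminant, white noise) are idealized. Passing
tests show that the pipeline implements its stated mathematics correctly
and recovers known signal under the stated assumptions — not that a 0.76
AUC is attainable in any particular clinic.

## Numerical choices and degenerate inputs

- Peak/trough ties: earliest time wins; constant hold plateaus therefore
  report the first sample.
- A subject with a non-positive trough or sensor-2 peak is excluded and
  logged, never imputed.
- `kaiserRetain()` errors when no eigenvalue reaches the threshold; LDA
  errors on singular pooled covariance (advising fewer components); the
  split errors when a part would lose a class (suggesting another seed or
  stratification).
- Degenerate group comparisons (identical values in both groups) return
  p = 1; chi-squared validity warnings (expected counts < 5) are attached,
  not silenced.
- All randomness flows through explicit integer seeds (cohort draw, split,
  bootstrap); equal configs and seeds give bit-identical result bundles,
  and every artifact embeds a hash of the resolved configuration.

## Limitations

Single-device, two-class, cross-sectional design only: no multi-class
support, no regularized discriminants, no analytic (DeLong) CIs, no
probability calibration, no humidity/temperature compensation, no modelling
of sensor chemistry, and no attempt to identify individual volatile
compounds. The eigenfrequency list, Butterworth order/cutoff and the exact
quantitative definition of the ambient correction used with the real device
are not recoverable from public sources; the defaults here are explicit,
configurable conventions.
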