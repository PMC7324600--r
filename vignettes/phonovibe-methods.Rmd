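---
title: "Models and methods behind phonovibe"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind phonovibe}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(phonovibe)
```

This vignette documents the scientific and numerical choices inside
`phonovibe`: the synthetic vocal-fold model, the definitions of the 91
vibration parameters, the redundancy and age screens, the boosted-stump
machinery, and the limits of what the synthetic study conditions can show.

## The synthetic glottis

High-speed videoendoscopy yields, after glottis segmentation, the total,
left and right glottal area waveforms (GAW_T/L/R) and the Phonovibrogram
(PVG), the displacement of each fold contour from the glottal midline per
contour position and frame. Since clinical recordings carry no ground
truth, the package generates both signal types from an explicit kinematic
model:

\[
D_s(p, t) = A_{s,k}\; g(p)\; f\!\big(\phi_s(t) - \tau\, h(p)\big)
\]

* `f` is a **piecewise-linear pulse with a flat plateau**: closed segment,
  linear rise, plateau at the peak, linear fall. This makes the shape
  quotients analytically controllable: the speed quotient (closing/opening
  duration) equals `speed_quotient` exactly and the plateau quotient
  (fraction of the open phase at or above 90% of the peak) equals
  `plateau_fraction` (values below 0.1 degenerate to a triangle, whose
  measured plateau quotient is 0.1 because the two 10% ramp tails always
  contribute that much).
* `g(p)` is a **half-sine envelope** along the fold, maximal at mid-fold —
  the simplest shape that lets the fold taper to its anterior and
  posterior tips.
* `h(p)` is linear in the distance from the fold tip, so a positive
  `ap_delay_open`/`ap_delay_close` delays the mid-fold relative to the
  tips by that fraction of a cycle: the "zipper"-like anterior–posterior
  opening that the PVG contour angles quantify.
* The right fold may lag the left by `phase_shift` cycles and carry a
  different peak amplitude (`lr_amplitude_ratio`, per-fold pulse specs).

**Cycle perturbation.** Each pulse is a self-contained unit of fixed
duration `fs/f0` placed at perturbed peak epochs: the peak-to-peak
intervals are `T_k = T_0 (1 + \delta_k)` with i.i.d. Gaussian
`\delta_k`. The generator anchors the *peaks* at the epochs on purpose:
extremum-based cycle estimators measure peak-to-peak intervals, and any
construction that rescales the whole cycle around a fixed start smears
each period over two adjacent peak intervals, halving the extracted
jitter. Amplitudes are i.i.d. lognormal on the dB scale,
`A_k = A_0\,10^{e_k/20}`.

The perturbation scales target the *estimator definitions* directly: for
i.i.d. Gaussian increments, `E|X_k - X_{k-1}| = 2\sigma/\sqrt{\pi}`, so

* `sd(\delta) = (\mathrm{jitter\_pct}/100)\sqrt{\pi}/2` makes the expected
  extracted Jit(%) equal the target, and
* `sd(e) = \mathrm{shimmer\_db}\cdot\sqrt{\pi}/2` makes the expected mean
  absolute dB shimmer (MShim) equal the target exactly (the dB-scale
  lognormal makes `20\log_{10}(A_{k+1}/A_k)` exactly Gaussian).

No claim is made that clinical perturbation is i.i.d. Gaussian — the
clinical process is unknown; the generator is calibrated so that the
*extracted* parameters hit known targets, which is what parameter-recovery
testing needs.

**Noise.** Broadband Gaussian noise is added to the 1-D GAW signals, not
the displacement matrices, because the harmonics-to-noise ratio SNR_K is a
GAW-spectrum measure and segmentation noise manifests in the GAW. The
noise power is set from the AC power of the clean total waveform so that
the harmonics-to-noise energy ratio equals `snr_db_target`; the noise is
split equally between the left and right waveforms so
`gaw_total = gaw_left + gaw_right` remains an exact identity. Noisy GAWs
may dip slightly below zero: clipping at zero would rectify roughly half
the noise mass in the closed phase and destroy the calibration, so they
are left unclipped (the displacement matrices stay nonnegative).

## Cycle detection and sub-frame timing

Cycle boundaries are "sufficiently distinct" local extrema of GAW_T:
topographic prominence at least `prominence_frac` (default 0.10) of the
signal range — the detection is therefore invariant to affine rescaling —
with extrema spaced closer than one period at `f0_bounds[2]` (default
1000 Hz) thinned by dropping the weaker one. Cycles are half-open
`[boundary_k, boundary_{k+1})`, the trailing partial cycle is discarded,
and all indices are 1-based frame indices (R convention). Four parameters
(PhA/PhAI mean and SD) use minimum-based cycles because the oscillation
peak must lie in the cycle interior; everything else uses maximum-based
cycles.

Two numerical choices matter here:

* **Sub-frame refinement.** At 4000 frames/s and 100–300 Hz phonation a
  period spans 13–40 frames. Quantizing peak instants to integer frames
  adds variance of order `2\times\frac{1}{12}` frames² to every period
  difference, which would inflate extracted jitter by roughly 10% at
  typical settings. Periods (and the left–right peak lags behind PhA)
  are therefore measured on refined extremum instants: the midpoint of the
  two linearly interpolated crossings of the 50%-of-peak level. The 50%
  level keeps both bracketing samples on the same monotone flank of the
  piecewise-linear pulse, where linear interpolation is exact. Integer
  boundaries remain the public cycle representation.
* **Detection smoothing.** Broadband noise seeds spurious local maxima
  that pass the prominence rule. `compute_feature_vector()` therefore
  detects cycles on a 7-frame moving-average copy of the signal
  (`detect_smooth` in `feature_config()`); *all measurements are taken on
  the raw signal*, so the noiseless calibration is untouched. Smoothing
  the measurement path as well was evaluated and rejected: it biases the
  shape quotients (SQ by >10% at mid f0, worse at high f0).

## The parameter registry

The registry (`parameter_registry()`) declares all 91 parameters — 41
computed from GAW_T, 18 left–right symmetry parameters from GAW_L/R, 32
from the PVG — with family, statistic, cycle mode, units and valid
domain, and downstream code is driven by it, so a definition can be
corrected in one place. The perturbation families follow the standard
voice-perturbation literature:

* `XP[Mean]`/`XP[Std]`: moments of `|X_k - X_{k-1}|` for X = period (TP),
  peak amplitude (AP), cycle energy (EP);
* `Jit(%) = 100\,\overline{|T_k - T_{k-1}|}/\bar T`; RAP_K is the 3-point
  relative average perturbation; PPQ/APQ/EPQ-k (k = 3, 5, 11) are k-point
  moving-average perturbation quotients; the perturbation factors
  PPF/APF/EPF are `100\,\overline{|X_k - X_{k-1}|}/\bar X` (PPF is
  therefore numerically identical to Jit(%), consistent with both sitting
  in the same redundancy family);
* `MShim = \overline{|20 \log_{10}(A_{k+1}/A_k)|}` in dB.

The 11-point quotients require at least 12 cycles; shorter recordings
yield `NA` with a warning rather than a silently degraded estimate.

**Per-cycle amplitude.** For maximum-based cycles the amplitude `A_k` is
the value at the cycle's defining peak. The naive "max over the cycle"
would mix in the front half of the *next* pulse's plateau (the cycle runs
peak-to-peak), effectively computing a running max of adjacent amplitudes
and halving the extracted shimmer.

**Shape quotients.** SQ is closing/opening duration — note that part of
the literature uses the inverse convention. Landmarks come from the pulse
contained in the cycle: the open phase starts/ends at crossings of
`open_frac` (2%) of the excursion, and the plateau is the contiguous span
at or above `plateau_level` (90%, configurable) of the pulse peak; all
landmark times are linearly interpolated. Cycles with zero opening
duration are skipped with a warning. Shape quotients measured on the
*total* GAW describe the summed area pulse: a left–right phase shift
genuinely broadens it, so SQ/PQ ground-truth recovery is assessed on
phase-symmetric recordings.

**SNR_K.** The harmonics-to-noise energy ratio of the mean-removed,
Hann-windowed GAW_T spectrum. The fundamental is located on the spectrum
itself (strongest bin in the plausible f0 band, then a subharmonic comb
check in case a higher partial dominates) because noisy time-domain
boundaries would corrupt it. Harmonic bands are one bin either side of
the local peak near each multiple of f0 (up to 8 harmonics below
Nyquist); with a Hann window and peak-centred bands the worst-case
scalloping loss is under 0.1 dB. The broadband floor estimated from the
non-harmonic bins is subtracted from the harmonic bands and credited to
the residual, making the estimator unbiased at the clinical ~11 dB level;
the value is capped at ±60 dB, with a flag when the residual vanishes.
Perturbation sidebands fall outside the harmonic bands, so jittered
recordings report less than the injected additive-noise ratio — that is
the intended meaning of a harmonics-to-*noise* measure, and the
calibration checks therefore inject noise into unperturbed pulse trains.

**Symmetry parameters.** Signed measures (PhA, AmS, DyRS, SpA) flip sign
when the folds are swapped; index measures (PhAI, AmSI, DyRSI, SpAI,
CASI) are swap-invariant and bounded by [0, 1]. The phase lag is the
difference of refined peak instants in cycle fractions wrapped to
(−0.5, 0.5]; keeping the signed mean *and* the absolute mean matters
because alternating lags cancel in PhA but not in PhAI. WaSI is the
per-cycle zero-lag Pearson correlation of the two waveforms.

## PVG contour angles

Edges are detected per contour position with a threshold of `eps_frac`
(5%) of **that position's** maximum excursion. A fold-wide threshold was
rejected: with an amplitude envelope along the fold it would turn a
simultaneous opening into position-dependent crossing times, and the
90°-means-simultaneous anchor would not be exact. Positions with
negligible overall excursion (taper tips) are marked absent. In
maximum-based cycles — open at both ends, closed in the middle — the
closing edge is the last frame of the first open run and the opening edge
the first frame of the last open run.

For each cycle, fold, phase and fold half (posterior = first half of the
position axis, anterior = second), the edge frame is regressed on
position by least squares. Coordinates are normalized — position in
half-fold units running from the tip towards the mid-fold, time in cycle
lengths — and the angle is `atan2(\Delta u, \Delta t_{frac})` in degrees.
Zero time spread gives exactly 90°; an opening sweeping tip-to-mid over a
quarter cycle gives `atan2(1, 0.25) \approx 75.96°`. The normalization
itself is a reconstruction (only the 90° anchor is fixed by convention);
it was chosen so that clinically reported angle magnitudes (about
80–100°) are representable. CAS is the signed ratio of paired left/right
angles and CASI the min/max index, which matches reported CAS values
around 1.0 and CASI around 0.88–0.93; swapping folds inverts CAS and
leaves CASI unchanged. Least squares rather than two-point extremes was
chosen for robustness to absent positions; at least 3 valid positions are
required per region and cycle.

## Redundancy pruning and the age screen

Pearson correlations are computed over all subjects pooled — only
relations consistent across healthy and disordered groups register — and
parameters correlated at `|PCC| \ge 0.9` ("very high") are grouped by
connected components of the thresholded graph. Transitive closure is used
because redundancy families have more than two members; the absolute
value is thresholded since the sign is irrelevant to redundancy. One
representative per component is kept, chosen from an explicit priority
list (MShim for the shimmer family, Jit(%) for the jitter family, EPF,
PhAI[Mean], AmSI[Std], PhAI[Std], SpAI[Std], CASI^CA[Std] — the widely
applied or cancellation-safe members), otherwise by registry order. A
`manual_removals` mechanism drops parameters that are only "high"
correlated (0.7–0.9) with kept parameters — by default TP[Std] (F0[Std]
kept), DyRS[Mean] (AmS[Mean] kept) and DyRSI[Mean] (AmSI[Mean] kept) —
rather than lowering the threshold. Every decision lands in a ledger with
its reason, and pruning is idempotent.

The age screen computes each parameter's PCC against subject age with the
two-sided p-value and Fisher-z 95% CI (`stats::cor.test`), flagging
correlations of at most 0.3 as negligible; it reports, but does not
remove. Nonlinear age effects are left to visual review
(`plot_age_relation()`).

## Boosted decision stumps

Depth-1 trees avoid overfitting on cohorts of tens to hundreds of
subjects; shrinkage (`learning_rate = 0.1`) and a uniform class prior
(initial observation weights `1/(2 n_{class})`) address the imbalanced
group sizes. The stump search is exhaustive over features and midpoints
of adjacent distinct values, with ties broken to the lowest feature index
and then the lowest threshold so training is bit-reproducible; degenerate
all-constant inputs yield a single-value stump with zero gain.

* **AdaBoost**: weighted-misclassification stumps, stage weight
  `\alpha = \frac{lr}{2}\log\frac{1-err}{err}` with the error clipped to
  `[10^{-10}, 1-10^{-10}]`, exponential reweighting.
* **LogitBoost**: Newton steps on the binomial log-likelihood — working
  response `z = (y^* - p)/(p(1-p))` clipped at ±4, weights `p(1-p)`,
  probabilities clipped to `[10^{-10}, 1-10^{-10}]` (the canonical
  additive-logistic-regression prescription; constants configurable in
  code), half-step scaled by the learning rate. The training log-loss is
  non-increasing by construction and asserted in the tests.
* **RUSBoost**: AdaBoost fitting each round's stump on a seeded random
  undersample of the majority class down to minority size; the stage
  weight is computed on the full sample.

Feature importance is the per-feature sum of split-criterion reductions
divided by the number of stumps, normalized to a maximum of 1. Scores are
additive stump sums; classification thresholds the score at 0, which
corresponds to probability 0.5 under the uniform prior.

Performance is estimated by stratified k-fold cross-validation repeated
with fresh seeded partitions (stratification is a deliberate choice — it
reduces the variance of fold composition and is what standard tooling
does by default); the AUC is the Mann–Whitney statistic per test fold,
averaged over folds and repeats (fold-averaged rather than pooled — a
documented choice where either is defensible).

## The selection pipeline

The five steps formalize what is often done by eye:

1. **Algorithm choice**: all three algorithms with and without two
   injected random features (one standard normal, one uniform); an
   algorithm is unsuitable if a random feature reaches normalized
   importance above 0.5, and the winner maximizes the mean of AUC and ACC
   over comparisons.
2. **Stump count**: AUC/ACC versus stump count, evaluated as nested
   prefixes of a single boosting run per fold; the chosen size is the
   smallest within 0.005 AUC of the curve maximum (a reproducible rule in
   place of a visual knee; a manual override exists).
3./4. **Per-sex stepwise selection**: features ranked by importance from
   one full-data fit; nested models of sizes 1..p evaluated by repeated
   CV *on one shared partition seed*, so size-to-size differences are
   paired rather than resampled; chosen size as in step 2. Sexes are
   always modeled separately — male and female vocal-fold dynamics differ
   enough that pooled models blur both.
5. **Combination**: the union, each sex's own set, the PVG-only and
   GAW-only members, user-supplied subsets and an optional greedy
   backward pass are all evaluated on the same partitions; the final set
   is the smallest whose minimum-over-sexes AUC is within 0.01 of the
   best. The search space is explicit because exhaustive subset search is
   infeasible.

`run_pipeline()` drives everything from a single config (R list or YAML),
derives every stage seed from one master seed, and writes CSV/JSON
reports that are byte-identical on re-run.

## Study conditions and problem sizes

The package's own test battery runs at desk scale, with sizes chosen to
make the statistical assertions stable:

* parameter recovery: 50 seeded recordings of ~200 cycles each, zero
  noise (10% relative tolerance; ±0.02 absolute for PhA);
* noise calibration: 50 recordings at the clinical 11.2 dB level, ±0.5 dB
  on the mean;
* redundancy: 100 recordings with jitter 0.5–5%, shimmer 0.1–1 dB, f0
  100–300 Hz; within the jitter and shimmer families all pairwise
  correlations exceed 0.9, reproducing the redundancy that motivates
  pruning;
* boosting oracle: AdaBoost within 0.05 test accuracy of an independent
  gradient-boosted-stump implementation (xgboost at depth 1 and matched
  learning rate) on fixed 40×3 tables;
* stepwise recovery: with 1 informative feature among 9 noise features,
  the chosen subset is exactly the informative feature in at least 18 of
  20 seeded runs;
* end-to-end: a 60-subject cohort sampled from the published group
  statistics runs through all five steps and reproduces byte-identically.

## What the synthetic conditions do and do not show

The generator emulates the *features the parameters measure*: controlled
perturbation, asymmetry, pulse shape, zipper motion, additive noise, and
group-structured cohorts matching printed group statistics. It does not
emulate: real video segmentation (no image data is ingested),
vocal-tract acoustics, biomechanical fold dynamics (no mass-spring
model), non-Gaussian or serially correlated clinical perturbation,
correlations *between* parameters within a subject
(`sample_feature_table()` draws independently per parameter because only
marginal group statistics are published — a stated limitation), or the
clinical cohort itself. Consequently the pipeline's selected subsets on
synthetic cohorts validate the machinery, not any clinical claim; the
published clinical performance numbers depend on the unavailable
358-recording cohort and are out of reach by design. Shape quotients
measured under heavy broadband noise are unreliable (threshold crossings
degrade) and are validated on clean signals only.
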