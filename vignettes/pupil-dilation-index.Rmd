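---
title: "Quantifying self-regulation from pupil dilation: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying self-regulation from pupil dilation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pupilcontrol)
```

## The problem and the model

Pupil diameter is a peripheral readout of central (locus-coeruleus /
noradrenergic) arousal. When people reappraise an emotional scene to make
their feelings more neutral, the pupil dilates *beyond* what the emotional
content alone would produce, and the size of this regulation-locked
dilation differs reliably between individuals. `pupilcontrol` implements
the full chain from raw samples to that individual difference measure and
its behavioural correlates.

The measurement model, stage by stage:

1. **Loss handling.** Blinks and tracker dropouts leave invalid samples. A
   binary loss vector is smoothed with a Gaussian window (FWHM 200 ms,
   truncated at ±3σ, σ = FWHM/2.3548), ceiled back to a 0/1 box-car, and
   differenced to obtain widened loss segments; each segment is then
   linearly interpolated between its flanking valid samples (constant fill
   at run boundaries). Widening matters: pupil samples adjacent to a blink
   are attenuated before the tracker reports loss, so interpolating the
   raw loss span alone leaves artefactual notches.
2. **Standardisation.** Each participant's full continuous trace is
   z-scored (mean 0, SD 1 *across the whole run*), giving all participants
   a common amplitude frame without touching the within-run dynamics.
3. **Epoching.** Trials are cut on \[−500, 7000) ms around stimulus onset
   (the 1-s adaptation screen occupies negative time) and each epoch has
   its mean over \[−500, 0) ms subtracted. Because the adaptation screen is
   a phase-scrambled version of the upcoming stimulus, this baseline also
   absorbs the luminance/contrast response of the specific image.
4. **Contrast.** Per participant, the mean reappraise-positive and
   reappraise-negative epochs are averaged and the mean of the two
   emotional view conditions is subtracted ("Reappraise > View"). Stimulus
   sets are arousal- and valence-matched between conditions, so the
   emotional-arousal transient cancels and the residual is
   regulation-locked activity (plus noise). Neutral-view trials are left
   out of the contrast.
5. **Cluster inference.** A one-sample t statistic is computed per time
   bin across participants and maximal runs of bins with t > 3 form
   clusters. The null distribution of the *largest* cluster size is built
   from 1000 sign-flip iterations (whole participant curves flipped, the
   standard construction for a within-participant contrast), and each
   observed cluster's p is the fraction of null maxima at least as large.
   Testing only the largest observed cluster against the max-null is
   deliberately conservative.
6. **PDI.** The Pupil Dilation Index is each participant's mean contrast
   over the significant window — either the data-driven window of the
   current dataset or the fixed replication window 3.4–5.6 s.

Behavioural outcomes: reappraisal success per stimulus is the rating shift
toward neutral (reappraise − view for negative, view − reappraise for
positive stimuli, on the 9-point SAM scale, 1 = most negative), averaged
within valence and then across valences (RS). Affective distance — the mean
absolute deviation of view ratings from the midpoint 5 — proxies task
difficulty. Dietary health-challenge success (HCS) is the percentage of
answered challenge trials with a self-controlled choice (refusing
tasty-unhealthy, accepting healthy-untasty food).

Inference: RS is modelled as
`RS = β0 + β1 PDI + β2 AffectiveDistance + β3 PDI×AffectiveDistance + e`
(optionally + Age + TaskOrder), HCS as `HCS = PDI + TaskOrder + e`, with
continuous predictors mean-centred and SD-scaled. Convergent validity is a
rank correlation between PDI and HCS. Predictive validity is
leave-2-participants-out: for every pair of participants the model is fit
to the other n−2 (predictors re-standardised on the training set only) and
the pair's predicted RS ordering is compared with the truth; the accuracy
over all C(n,2) splits is tested against a permutation null in which half
of each training set's outcomes are sign-flipped.

## Tunable parameters that matter

| Parameter | Unit | Default | Why |
|---|---|---|---|
| `fwhm_ms` (loss widening) | ms | 200 | matches the blink-artefact spread at typical trackers |
| epoch window | ms | \[−500, 7000) | adaptation baseline + full 7-s stimulus |
| baseline | ms | \[−500, 0) | pre-stimulus, image-matched adaptation screen |
| `bin_width_ms` | ms | native (2 ms at 500 Hz) | 1-ms resampling mode exists for replicating analyses that counted 1-ms bins |
| `threshold` | t units | 3 | cluster-forming threshold of the original analysis |
| `n_iter` | — | 1000 | permutation iterations; p resolution 1/1000 |
| `flip_mode` | — | `per_participant` | exchangeability unit for a within-participant contrast; `per_bin` implements the literal "flip each time bin" reading and is exposed for comparison |
| `tail` | — | positive | the hypothesis is *extra* dilation under regulation; two-sided mode forms clusters on \|t\| |
| PDI window | s | data-driven; fixed 3.4–5.6 as replication mode | the fixed window is the published significant window |

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the task's statistical skeleton: 5 block
types (reappraise/view × positive/negative, plus view-neutral) × 20
trials; 1-s adaptation, 7-s stimulus, 4-s rating, ITI uniform on 1–5 s,
15-s block breaks (a ~26-min run); 500-Hz sampling (reducible for speed);
Poisson blinks (15/min, gamma durations with 150-ms mean) interpolated by
the same machinery as real data; SAM ratings discretised to 1..9; 100
dietary trials, half of them challenges.

A single latent capacity `c_i ~ N(0, 1)` drives all three outcomes:

* regulation plateau amplitude `regulation_mean + pdi_loading·c_i`
  (defaults 0.16 z and 0.25 z/SD — the group mean matches the published
  group PDI, and the loading is chosen so that the implied group-level
  max-t at n = 34 lands near the published ≈3.7);
* reappraisal rating shift `rs_base + rs_loading·c_i`
  (defaults 2 SAM points and 0.5 points/SD, matching the observed ~2-point
  group shift toward neutral);
* challenge-success probability `(hcs_base + hcs_loading·c_i)/100`
  (defaults 62% and 12 pp/SD, matching the published HCS intercept and PDI
  coefficient).

The regulation component is a linear ramp from 2.0 s (the regulation onset
consistently reported across studies) to 3.4 s, a flat plateau over
3.4–5.6 s and a linear decay to stimulus offset — the simplest shape
consistent with the published time course. The emotional-arousal transient
(gamma-shaped bump, peak 1.2 s, amplitude 0.5 z) is *identical* in view
and reappraise trials of equal valence, mirroring the arousal-matched
stimulus sets; attenuation of emotional arousal by successful regulation
is off by default (`reg_arousal_reduction = 0`) because the published
measure deliberately does not model it — the contrast is conservative on
this point. Measurement/physiological noise is band-limited AR(1)
(stationary SD 0.5 z, time constant `noise_tau` = 0.3 s) over a slow AR(1)
baseline drift (SD 0.2 z, 20-s time constant). The smoothness of the noise
is not cosmetic: pupil series are low-pass by physiology, real contrasts
produce clusters spanning *seconds* (thousands of 1-ms bins), and a
white-noise world can only ever produce 1–3-bin clusters — which makes the
max-cluster-size statistic so coarsely discrete that no attainable p value
sits near 0.05 and the cluster test's rejection rate whipsaws with the bin
count (measured between 0.3% and 4% across sampling rates). With
band-limited noise, null cluster *durations* are quasi-continuous and the
test's attained level is a stable ≈5% regardless of sampling rate.
`noise_tau = 0` recovers white noise for experiments on this point.

Not emulated: image content and phase-scrambling, gaze position and
saccades (and thus foreshortening artefacts), fMRI signals, and any
dissociation between the latent drivers of the three outcomes. The last
point matters for interpretation: because one latent trait drives pupil,
ratings and choices, cross-domain associations in synthetic cohorts are
*stronger* than typical empirical values (e.g. the PDI–HCS rank
correlation comes out near 0.9 rather than ~0.5). A green recovery test
therefore establishes that the pipeline estimates what the generator put
in — it does not certify empirical effect sizes, which only the deposited
real dataset can.

## Numerical choices

* **Loss-segment detection** exploits that the truncated Gaussian is
  strictly positive on its support: convolve→ceil→diff is equivalent to
  dilating each raw loss span by r = ⌈3σ·fs⌉ samples and merging spans
  whose gap is below the kernel support. The test suite checks exact
  agreement with a brute-force convolution oracle. Segment indices are
  half-open `[start, end)`.
* **Native bin grid** (2 ms at 500 Hz) by default; the optional 1-ms mode
  linearly interpolates the trace. No trial-exclusion threshold for
  interpolated fraction is applied by default (none was used in the
  original analysis); the interpolated fraction is reported per run.
* **Z-scoring before vs after interpolation**: interpolation first, then
  z-scoring, so interpolated samples participate in the run moments. The
  original order is not documented; with a few percent interpolated
  samples the difference is negligible.
* **Zero-variance bins** in the t curve get ±Inf (sign of the mean), 0 if
  the mean is zero too; cluster logic treats ±Inf like any other value.
* **Ties for "largest cluster"** break by earliest start bin; secondary
  clusters receive p values against the same max-null and are flagged
  exploratory.
* **Flat-prior posterior in closed form.** With the uninformative priors
  this package contracts, the linear-model posterior is the
  normal–inverse-gamma limit: β | data is multivariate-t around the OLS
  solution with scale s²(XᵀX)⁻¹ and n−p degrees of freedom. The "bayes"
  engine therefore reports analytic posterior summaries (posterior SD
  inflates the OLS standard error by √(ν/(ν−2))); no sampler, hence no
  convergence diagnostics, and exact agreement of point estimates with the
  OLS engine. Bayes factors use the Zellner–Siow (JZS) mixture-of-g
  one-dimensional integral; a labelled BIC approximation is available.
* **Rank-correlation posterior** uses the Fisher-z approximation with the
  1.06/(n−3) variance inflation appropriate for Spearman's rho; the Bayes
  factor is the Savage–Dickey ratio under a uniform(−1, 1) prior on rho.
  A nonparametric bootstrap engine is the fallback. Ties are mid-ranked.
* **Paired shift test**: the flat-prior posterior of a mean paired
  difference is a scaled t; the posterior probability of a positive shift
  equals one minus the one-sided frequentist p, which the tests verify.
* **Leave-2-out details**: the training model is fit by OLS inside the
  loop (the analytic agreement with the bayes engine makes this exact for
  point predictions); ties in predicted or true RS count as *incorrect*.
  The permutation null flips exactly ⌊n/2⌋ raw success scores per
  iteration with **one sign assignment shared by all 561 splits**
  (`flip_unit = "cohort"`). This choice is load-bearing: redrawing signs
  independently per split makes split outcomes independent within an
  iteration and collapses the null accuracy SD to ≈√(0.25/561) ≈ 0.02,
  while the observed accuracy — 561 overlapping splits sharing one
  outcome vector — disperses at ≈0.05–0.10 under the null; the per-split
  scheme is therefore strongly anticonservative (p ≈ 0 on null data). It
  remains available as `flip_unit = "split"` for comparison. A
  mean-centred flip variant also exists, because sign-flipping raw
  all-positive scores produces a deliberately pathological outcome
  distribution; the default follows the original raw-score construction.
* **Degenerate inputs**: all-lost runs, zero-variance runs, collinear
  designs (condition number > 1e8), missing condition cells, and
  unanswered challenge trials all raise typed errors (`pc_config_error` /
  `pc_data_error`) that the CLI maps to exit codes 1 / 2.

## Open design points, resolved

* The exchangeability unit of the published permutation ("flipping the
  sign of each time bin") is ambiguous; `per_participant` is the default
  because the participant is the exchangeable unit of a within-participant
  contrast, and `per_bin` is provided for the literal reading. On smooth
  contrasts the per-bin null destroys temporal autocorrelation and is
  anticonservative for cluster sizes.
* RS averages per-valence means rather than pooling stimuli, so unequal
  missing ratings cannot tilt the score toward one valence.
* RS and affective distance are computed from the *same* view ratings, so
  they are mechanically correlated (≈0.7 in synthetic cohorts even when
  the latent capacity does not drive ratings at all): a stimulus rated
  further from neutral leaves more room for a measured shift. This is a
  property of the measure — it is exactly why the success model controls
  for affective distance — and it means "no effect" benchmarks for the
  prediction analysis must break the RS–predictor link at the score level
  (e.g. permuting RS across participants), not merely zero out the latent
  loading.
* Missed dietary responses leave the HCS denominator (count logged).
* Whether published bin counts reflect 1-ms resampling is untestable
  without the deposited data; both grids are available
  (`bin_width_ms = 1`).

## Known limitations

* The analytic flat-prior engine cannot express genuinely informative
  priors; exact numeric parity with specific Bayesian software (sampler
  defaults, prior scales) is not contracted.
* The Fisher-z rank-correlation posterior is an approximation; for very
  small n (< 10) prefer the bootstrap engine.
* The generator's single-latent design overstates cross-domain coupling
  (see above) and does not model gaze-dependent artefacts.
* Acceptance-grade simulations run at reduced sampling rates (50–100 Hz)
  to fit a single-CPU budget; all asserted properties are invariant to the
  sampling rate, and the task structure is never reduced.
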