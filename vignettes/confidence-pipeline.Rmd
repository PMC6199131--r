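---
title: "Modelling and decoding perceptual decision confidence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling and decoding perceptual decision confidence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neuroconf)
```

neuroconf implements a complete analysis chain for studying the neural
basis of perceptual decision confidence: a race model of the decision
process whose balance of evidence serves as latent confidence, a
single-trial EEG discriminant that extracts an endogenous confidence
component, behavioural and mediation statistics connecting the two, and an
EEG-informed fMRI GLM with nonparametric cluster-extent correction. Every
stage can be exercised on synthetic data with known ground truth, which is
how the package's test suite validates it. This vignette explains the
models, the tunable parameters, the numerical choices, and what the
synthetic-data results do and do not establish.

## The race model and balance-of-evidence confidence

Two accumulators integrate evidence in 1 ms steps towards a shared
threshold $\theta$. Per step each adds an independent Gaussian increment;
the accumulator congruent with the stimulus has mean $\mu_c = 0.1$ (a.u.
per ms, a fixed scale convention), the incongruent one $\mu_c / r$ with
mean ratio $r > 1$, and both share the increment SD $\sigma$. The first
accumulator to reach $\theta$ determines the choice; response time is the
crossing time plus a non-decision time $nDT$ accounting for sensory
encoding and motor execution. Confidence is read out as the balance of
evidence $\Delta e = \theta - (\text{losing accumulator at decision})$:
decisions where the loser lagged far behind are (correctly) high-confidence
ones.

With $\sigma = 0$ the model is deterministic and closed forms hold exactly
— decision time $\theta / \mu_c$, $\Delta e = \theta (1 - 1/r)$ — which the
tests use as exact anchors. Trials not reaching threshold within the
accumulation limit (default 1500 ms) are flagged and excluded from fitting,
mirroring discarded missed responses.

Fitting is by grid-search maximum likelihood. Observed and simulated RTs
are pooled into one signed distribution by mirroring error RTs to negative
values, and compared by a two-sample Kolmogorov–Smirnov test; the
log-likelihood is $\log p_{KS}$ minus a Gaussian penalty on the accuracy
mismatch with SD 0.1. The default grid is $\sigma = 0.6(0.1)1.0$,
$\theta = 55(7)97$, $nDT = 250(50)450$, $r = 1.2(0.05)1.6$, with 500
simulated trials per point. Numerical choices worth knowing:

* **Common random numbers.** One increment array is drawn per fit and
  reused at every grid point, so likelihood differences between points
  reflect parameters rather than simulation noise. This materially reduces
  the replicate-to-replicate variance of the argmax.
* **Asymptotic KS p-value** (two-sample; exact small-sample computation is
  not attempted), and ties in the likelihood resolve to the earlier row in
  sigma-major grid order.
* **Quantile summaries** of the fit (defective RT quantiles at 10/30/50/
  70/90%) use type-7 linear interpolation.

At the study-scale configuration the tests use — data simulated at a grid
point ($\sigma = 0.8$, $\theta = 76$, $nDT = 350$, $r = 1.4$), 2000 trials,
500 simulations per point — the fit recovers $\theta$ and $r$ within one
grid step in at least 80% of 20 replicates. $\sigma$ and $r$ trade off
along a soft identifiability ridge (both scale the accuracy), so joint
recovery of all four parameters to the exact grid point is not expected and
not asserted.

## The single-trial EEG confidence discriminant

Trials are first grouped by the 9-point confidence rating: Low pools
ratings 1–3, High pools 7–9, Medium is the rest. Each of Low and High must
hold at least 50 trials; if not, the nearest Medium rating bin is folded in
(4, 5, ... for Low; 6, 5, ... for High), each bin claimable once. The
expansion order is a package choice — the rule in the literature says only
that neighbouring bins are included.

A linear discriminator is then trained in 60 ms windows centred every
10 ms from −100 to 1000 ms (centres whose full window would leave the
epoch are skipped; for a −100...1000 ms epoch the first usable centre is
−70 ms and the last 970 ms). Features are per-channel means over the
window samples — the method is framed as a spatial filter, and averaging
within the short window keeps one weight per channel. Epochs are baseline
corrected by the mean of the 100 ms prestimulus interval first. The
discriminator is a penalised logistic regression fit by iteratively
reweighted least squares, with High-confidence trials mapped to positive
decision values (the spatial weights are sign-flipped if a window comes out
inverted).

Two numerical choices here deviate from the naive IRLS and deserve
explanation:

* **Step halving.** Each Newton step is accepted only if it does not lower
  the penalised likelihood, halving otherwise. Near-separable windows
  otherwise produce diverging weights, and the leave-one-out machinery
  inherits the instability.
* **Shrinkage-scale ridge.** The default penalty is
  $\lambda = 3 \times \overline{\mathrm{var}}(\text{features})$ on the
  weights (never the intercept). At 64 channels and ~100–200 trials per
  class an essentially unregularised fit (say $\lambda$ four orders of
  magnitude smaller) routinely separates the training data: training Az
  saturates at 1, weights explode, the forward model reflects the overfit
  filter rather than the underlying component, and held-out and training
  component amplitudes decorrelate. With the shrinkage-scale default the
  leave-one-out Az is unchanged or slightly better, and training and
  held-out amplitudes at the peak window correlate above 0.9, the regime
  reported for this family of analyses. The penalty scale is exposed as
  `lambda_scale` everywhere.

Discrimination performance per window is the leave-one-out
cross-validated Az — every trial is scored by a model trained on the
others (warm-started from the full fit, which is safe because the
penalised optimum is unique) — and the ROC area is computed by trapezoidal
integration with ties counted half, making it exactly the Mann–Whitney
statistic. Significance uses a permutation null: labels are shuffled 500
times, the identical LOO procedure is rerun, and the p < 0.01 threshold is
the 99th percentile of the null Az distribution.

The peak window for downstream use is the Az-maximal window among those
ending at least 100 ms before the mean response time, keeping the selected
component clear of motor-execution activity. The component's scalp map is
its forward model $a = X y / (y^\top y)$, computed at the peak window on
mean-centred data (the centring isolates trial-to-trial fluctuation; the
raw algebraic form is available too). Trial-specific confidence amplitudes
`y_CONF` come from projecting *all* trials — including Medium and excluded
ones — through the peak-window weights.

## Prestimulus alpha power

The attention control computes 8–12 Hz power in the 400 ms window starting
at −500 ms, using two DPSS (Slepian) tapers with ±4 Hz smoothing. The
tapers are computed from the standard symmetric tridiagonal eigenproblem
(no external dependency provides them); they are unit-energy, so white
noise of variance $s^2$ has expected band power $s^2$, which the tests use
as a flat-spectrum oracle. Single-trial power is taken from the
occipitoparietal electrode (labels `P*`, `PO*`, `O*` by default) with the
highest mean power and converted to decibels relative to that electrode's
across-trial mean power — the dB reference in the source methods is
ambiguous, and this within-electrode normalisation is the package's
documented reading. The High/Low alpha split is a per-subject median split
(odd counts: the median trial goes to Low), compared by a paired t-test
across subjects.

## Behavioural and cross-measure statistics

* `groupwise_correlation()`: Pearson R per subject, one-sample t-test on
  the coefficients — the random-effects summary used for, e.g.,
  rating–accuracy coupling.
* `serial_autocorrelation()`: R² of regressing a trial series on its five
  predecessors, never crossing run boundaries. On i.i.d. data
  $E[R^2] \approx k/(n-1)$, the calibration anchor.
* `repetition_bias()`: probability of repeating the previous choice, by
  tertile of the previous trial's confidence component and by whether the
  stimulus direction repeats. Correct and error trials are equalised
  within each tertile by random removal (averaged over many draws) so the
  effect cannot be an accuracy artifact; tertiles are computed before
  equalisation, following the order of operations in the source text.
  Group inference is a one-way repeated-measures ANOVA with
  Bonferroni-corrected paired post-hocs.
* `percentage_bend_correlation()`: Wilcox's robust correlation with bend
  constant 0.2; deviations beyond the $\lfloor (1-\beta) n + 0.5 \rfloor$-th
  ordered absolute deviation from the median are winsorised.
* `mediation()`: the three-variable path model $M = aX$,
  $Y = c'X + bM$ (with intercepts) on per-subject correct-minus-error
  contrasts; the indirect effect is $ab$ and $c = c' + ab$ holds to
  numerical precision for every OLS fit. Inference is a percentile
  bootstrap over subjects (the toolbox the field uses does not pin down
  the flavour; percentile is the simplest defensible choice). Percentile
  intervals for a product of coefficients undercover mildly at $n = 24$,
  which is why the test suite accepts 95% CI coverage down to 87.5%.

## The EEG-informed fMRI GLM

Event regressors are amplitude-weighted stick functions (duration 0.1 s)
on a 0.1 s grid, convolved with the canonical double-gamma HRF (response
gamma shape 6, undershoot shape 16, ratio 1/6, unit peak) and sampled at
the TR = 2 s frame times. Parametric amplitudes — e.g. the trial-wise
`y_CONF` component — are mean-centred before convolution (the convention of
the major fMRI packages; the source is silent). High-pass filtering is
available as a discrete-cosine confound basis (cutoff 100 s). Collinearity
is diagnosed with variance inflation factors, $1/(1-R^2_j)$.

Voxelwise OLS yields t statistics converted to Z by matching tail
probabilities at the residual degrees of freedom (computed on the log
scale so large statistics do not overflow). Statistical maps are
thresholded at $|Z| \ge 2.57$ and clustered with 26-neighbour
connectivity (vertex-touching; common fMRI practice — the source does not
state its connectivity), positive and negative excursions separately, with
a 5-voxel minimum extent.

Cluster-extent correction follows the amplitude-permutation scheme: the
amplitude sequence of the parametric regressor of interest is shuffled,
the design rebuilt, the GLM refit, and the sizes of all positive
suprathreshold clusters pooled across 200 (default) iterations; the
corrected extent threshold is the 95th percentile of the pooled sizes.
Pooling all cluster sizes (rather than taking each iteration's maximum) is
what the source procedure describes; it is more liberal than max-statistic
familywise control, and the calibration test accepts familywise positive
rates up to 13% on that account.

The PPI design contains the four standard regressors — task sticks,
demeaned seed time course (unconvolved), a convolved boxcar train with
per-trial decision-time durations (zero-centred), and their elementwise
product — computed at BOLD resolution without deconvolution. Percent
signal change is the deviation from a 4 s pre-onset baseline scaled by the
run-mean signal, trial-averaged within condition bins over a −4...10 s
peristimulus window aligned to the nearest volume.

## What the synthetic data emulate — and what they do not

The generators provide ground truth for every stage:

* **Behaviour**: choices, RTs and latent confidence from the race model at
  the grid-centre parameters (producing ~75% accuracy, matching the
  staircased difficulty of the modelled task); 9-point ratings are a
  rounded affine map of $\Delta e$ spanning the scale, plus Gaussian noise
  (SD 1 rating point by default) and 4% missingness, the discarded-trial
  rate of the modelled experiment. Sessions default to two 160-trial runs.
* **EEG**: 64-channel, 1000 Hz epochs (−100...1000 ms; extend the
  prestimulus span to 500 ms for spectral work) containing a planted
  component: standardised latent confidence × a fixed unit-norm
  centroparietal topography × a Gaussian temporal kernel centred at 700 ms
  (SD 80 ms, matching the mean peak discrimination latency of ~708 ms
  reported for such components; no generative form is on record, so the
  Gaussian bump is a stand-in). Noise is per-channel 1/f-shaped Gaussian
  noise, unit SD, scaled by 1/snr; an optional 10 Hz prestimulus sinusoid
  with per-trial amplitude emulates occipitoparietal alpha. The default
  component amplitude (`component_scale = 1.6`, in noise-SD units at the
  spatiotemporal peak) puts peak single-trial discrimination in the
  Az ≈ 0.9 range: strong enough that the forward model is estimable from
  300 trials, weak enough that the Az timecourse does not saturate and
  peak latency remains identifiable.
* **BOLD**: 20×20×20 voxel volumes, 200 volumes at TR 2 s, as
  design × betas + white noise, with the effect confined to a known voxel
  set. For cluster-level calibration the noise can be spatially smoothed
  (FWHM in voxels; 2.7 voxels ≈ the 8 mm kernel of standard preprocessing
  at 3 mm voxels) — strictly white noise essentially never forms a 5-voxel
  cluster, which would make extent thresholds vacuous.

Passing tests on these data show that the algorithms are implemented
correctly and are calibrated under their own assumptions. They do not show
robustness to what real recordings add: MR gradient and ballistocardiogram
artifacts, eye movements, head motion, spatially correlated EEG noise and
volume-conducted source mixing, physiological BOLD noise and
autocorrelation, or subject heterogeneity. Those stages are explicitly out
of scope.

## Problem sizes used by the test suite

The acceptance-style tests run at desk scale, sized as follows: the Az
oracle equivalence on 1000 random instances; null calibration of the
500-shuffle Az threshold on 200 datasets of 100 trials × 8 Gaussian
features (the feature count is a package choice; the calibration property
does not depend on it); planted-component recovery on one 300-trial,
64-channel fixture at snr 1; race recovery over 20 replicate fits of the
full 2205-point grid at 500 simulations per point; mediation calibration
on 200 null and 150 effect replicates of 24 subjects; GLM tail calibration
on a 20³ white-noise volume; cluster-permutation calibration on 100
smoothed-noise datasets at 100 permutations each plus one planted
200-voxel effect; and null calibrations of the serial-autocorrelation,
repetition-bias and alpha-split analyses (400, 150 and 200 simulations).

## A worked example

```{r example, eval = FALSE}
library(neuroconf)

beh <- gen_behaviour(n_trials = 300, seed = 11)
epochs <- gen_eeg_epochs(beh$trials, beh$truth, snr = 1, seed = 21)

bins <- bin_confidence(beh$trials$rating)
decode <- sliding_discriminate(epochs, bins)
autoplot(decode)

peak <- select_peak_window(decode$az, decode$window_centres_ms,
                           mean_rt_ms = 1000)
k <- match(as.numeric(peak), decode$window_centres_ms)
y_conf <- apply_weights(epochs, decode$weights[, k], decode$bias[k],
                        centre_ms = as.numeric(peak))

fit <- race_fit_grid(beh$trials[beh$trials$valid, ], n_sim = 500, seed = 3)
tidy(fit)
```

## Known limitations

* The race model has no collapsing bounds, urgency, post-decisional
  accumulation or trial-history terms, so it cannot produce
  confidence-driven sequential dependencies by construction.
* The mediation is across subjects, not multilevel; with two dozen
  subjects its power and calibration are what the bootstrap gives at that
  n. Note also that in the synthetic world the ratings and the planted
  EEG component both derive from the same latent balance of evidence with
  independent noises, so there is no planted indirect path from model
  confidence through the neural signal to the report: across-subject
  mediation on fully pipeline-generated data is expected to be null, and
  the mediation calibration tests therefore use directly simulated
  per-subject measures with known path coefficients.
* The pooled-size cluster rule is anti-conservative relative to
  max-statistic control; treat its thresholds accordingly.
* The EEG generator's channel-independent noise flatters multichannel
  integration relative to real, spatially correlated EEG noise; absolute
  Az values on synthetic data are not forecasts for real recordings.
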