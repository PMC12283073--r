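---
title: "Methods: EFR spectral estimation, pupillometry growth curves, and the association stage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EFR spectral estimation, pupillometry growth curves, and the association stage}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

earpipe implements a complete analysis chain for cross-species studies of
cochlear neural degeneration (CND) and listening effort: envelope following
response (EFR) amplitude estimation from event-marked electrophysiological
recordings, pupillometry preprocessing and growth-curve analysis (GCA) of
task-evoked dilation, QuickSIN keyword scoring, and an association stage
combining mixed-design ANOVA, outlier-screened correlations and elastic-net
regression. A synthetic-cohort generator with known ground truth backs every
stage, so the whole chain is verifiable by parameter recovery. This vignette
documents the models, the tunable parameters, the numerical choices, and the
limits of what the synthetic world can establish.

## EFR estimation

The EFR is a scalp- or ear-canal-recorded neural ensemble response
phase-locked to the amplitude envelope of a modulated tone. High modulation
rates near 1 kHz exceed the phase-locking limits of midbrain and cortex, so
the 1024 Hz AM response indexes auditory-nerve integrity, while 40 and 110 Hz
responses emphasize central generators.

The estimation chain is: zero-phase band-pass filter, epoching with artifact
rejection, cross-polarity averaging, windowed amplitude spectrum, 3-bin peak
and flanking noise floor.

**Filtering.** A 4th-order Butterworth low-pass at 3000 Hz cascaded with a
4th-order high-pass whose cutoff tracks the AM rate (40 -> 5 Hz, 110 -> 80 Hz,
512 -> 200 Hz, 1024 -> 300 Hz). Both stages are applied zero-phase; because
the forward-backward response of an IIR filter is the real gain
$|H(f)|^2$, the package realizes it by spectral multiplication with the
exact digital response of the designs (1 s zero padding prevents circular
wrap-around). This is numerically identical to forward-backward time-domain
filtering away from the record edges and about three times faster.

**Epoching and rejection.** Epochs are one stimulus period long (1/3.1 s)
and time-locked to the stimulus events. Any epoch whose absolute amplitude
exceeds 200 uV at any sample is discarded; an epoch peaking at exactly
200 uV is kept (the rule is "exceeded"). In gerbil mode the first 250
artifact-free sweeps per polarity enter the average. Averaging the two
polarity means cancels carrier-locked components while envelope-locked
components persist.

**Spectrum.** The averaged waveform is windowed from 10 ms after stimulus
onset to 10 ms after offset (human mode) or to offset (gerbil mode); the
10 ms skip excludes the auditory brainstem onset response, and the matching
10 ms tail captures the neural latency of the envelope response. The
amplitude spectrum uses the native bin width $\Delta f = 1/T_{window}$
(4 Hz for the human 250 ms window) with no zero padding, scaled so a
bin-centred sinusoid of amplitude $A$ peaks at $A$. One deliberate choice
needs flagging: the evaluation grid is anchored so that a bin falls exactly
on the modulation frequency (an FFT of the window after mixing with a single
complex exponential - a one-step chirp-z evaluation). On a DC-anchored FFT
grid, 110 Hz sits exactly midway between 4 Hz bins and scallops by 36%, and
no gerbil rate is bin-centred in the 240 ms gerbil window; anchoring removes
that scalloping at the target while preserving the bin width on which the
3-bin peak rule and the 5+5-bin noise floor are defined.

**Amplitude, noise floor, significance.** The EFR amplitude is the maximum
over the bin at the modulation frequency and its two neighbours; the noise
floor is the mean of the five bins immediately above and below that central
triplet; the response is significant when the amplitude is at least 6 dB
above the floor. Two deterministic corrections make the estimate unbiased:
the spectrum is equalized by the known filter gain $|H(f)|^2$ (skipped deep
in the stopband, where equalization would only amplify rounding noise), and
the estimate is divided by the chain's measured response to a
unit-amplitude gated calibration tone, which absorbs the ~1% bias the
zero-phase high-pass introduces by ringing at the gated response's onset and
offset. Both corrections are fixed properties of the measurement chain,
computed without reference to data. With them, noiseless synthetic
recordings are recovered within 0.05% at every AM rate in both species
modes; without them the bias ranges from 4% to 36% depending on the rate.

At 16 Hz in gerbil mode the spectrum has fewer than five bins below the
central triplet; the noise floor then uses the bins that exist (with a
warning). The significance call at that rate is correspondingly optimistic —
a documented limitation.

## Pupillometry preprocessing

Raw traces are 1000 Hz samples with eye-tracker blink and saccade flags.
Two windows of interest are analyzed: the *listening window* (masker onset
through 5.8 s, covering the 3 s babble lead and the first 2.8 s of the
target sentence) and the *integration window* (target offset through 3 s).
Processing order is fixed and tested: trial rejection, artifact
interpolation, downsampling, baseline normalization, window cutting,
condition averaging.

- A trial is discarded when more than 15% of its window-of-interest samples
  are flagged (exactly 15% is kept).
- Blinks are linearly interpolated from 60 ms before to 160 ms after each
  run; saccades from 60 ms before to 60 ms after. Overlapping pads merge.
  A run whose pad touches the trace boundary has no anchor; the trial is
  rejected rather than extrapolated.
- Downsampling to 50 Hz is by non-overlapping 20-sample block means (block
  averaging doubles as the anti-alias step); timestamps are block-mean
  times.
- The baseline is the mean of the interpolated, downsampled signal over the
  1000 ms before the window start - after interpolation so blink zeros
  cannot corrupt it - and values become percent change,
  $(p - B)/B \times 100$. This makes the output invariant to the overall
  scale of a participant's pupil (dynamic-range differences), which the
  test suite asserts exactly.
- Surviving trials are averaged pointwise per participant x SNR x window
  across the four test lists.

The integration window's end is set to 3.0 s after target offset: the
response prompt follows the 2 s masker tail plus a 2 s gap, and stopping
1 s before the prompt gives 4 - 1 = 3 s. It is configurable.

## Growth-curve analysis

Windowed, averaged pupil traces are modelled with a second-order orthogonal
polynomial GCA:

$$\text{Pupil} \sim (ot1 + ot2) \cdot \text{SNR} \cdot \text{Group}
 + (0 + ot1 + ot2 \,\|\, \text{participant})
 + (ot1 + ot2 \,|\, \text{participant{:}SNR})$$

fit by maximum likelihood (`REML = FALSE`) with treatment coding
(reference SNR 25 dB, reference group the younger adults). `ot1` and `ot2`
are the orthonormalized linear and quadratic time vectors on the realized
50 Hz grid; the intercept captures overall dilation, `ot1` the rate of
dilation (slope), `ot2` the curvature. The listening-window random
structure excludes the participant-level intercept and the correlations
between participant-level slopes; the integration window uses correlated
participant-level terms. Single-level factors are dropped automatically so
degenerate designs (one group, one SNR) remain fittable.

Numerical choices: the default optimizer is lme4's `nloptwrap`, which
reaches the same maximum as `bobyqa` on this model class (asserted to
1e-6 in the tests) in about a third of the time; `bobyqa` remains available
via the `optimizer` argument. Singular fits are reported, not errored.
Wald p-values use the large-sample normal approximation of the t-ratio;
small-sample p-values from degrees-of-freedom approximations will differ
slightly.

Per-participant slope indices come in two flavours: `"blup"` (fixed-effect
cell total plus the conditional modes of the participant and
participant-by-SNR `ot1` effects; the default) and `"ols"` (per-cell
ordinary least squares, bypassing the mixed model). Which of the two a
study should correlate with behavior is a genuinely open choice; both are
exposed, and the package's own end-to-end runs use the OLS route where
hundreds of fits would otherwise be needed.

## QuickSIN scoring

Keyword tables (4 lists x 6 SNRs x 5 keywords) are scored two ways:
per-SNR proportion correct over the pooled 20 keywords, and the clinical dB
SNR loss per list, $25.5 - \sum \text{keywords correct}$, averaged over
lists. A perfect list scores -4.5 dB, an empty one 25.5 dB. For the
association stage the 0 dB proportion is scaled to 0-100.

## Association stage

- **ANOVA.** Sequential (Type I) sums of squares via `aov` with treatment
  contrasts; mixed designs use an `Error(id/within)` stratum. For repeated
  factors with more than two levels the Greenhouse-Geisser epsilon is
  estimated from the pooled within-group covariance and applied to the
  degrees of freedom of every effect involving the repeated factor (the
  source of fractional df in sphericity-corrected tables; cross-checked
  against `car::Anova` in the tests). Per-level follow-up contrasts are
  Bonferroni-adjusted.
- **Correlations.** Tukey's fence with $k = 1.5$ screens each variable
  (quartiles by linear interpolation of order statistics, R's type 7 -
  the convention is documented because the fence's worked examples depend
  on it); Pearson's r is reported with df $= n - 2$.
- **Elastic net.** Minimizes
  $\tfrac{1}{2n}\lVert y - \beta_0 - X\beta\rVert^2 +
  \lambda(\alpha\lVert\beta\rVert_1 + \tfrac{1-\alpha}{2}\lVert\beta\rVert_2^2)$
  over $\alpha \in \{0, 0.1, \dots, 1\}$ and, per $\alpha$, 100 log-spaced
  $\lambda$ values spanning four decades down from the smallest
  coefficient-zeroing penalty; the pair minimizing 10-fold cross-validated
  RMSE wins. Predictors are standardized internally and coefficients
  reported on the original scale; fold assignment is seeded and stored.
  One convention note: the reference coordinate-descent implementation
  standardizes the response internally, which rescales the ridge component
  of its penalty by sd(y); at $\alpha = 0$ the package converts the penalty
  so the documented objective holds exactly (matching the closed-form ridge
  solution to 1e-7 in the tests). Both the training $R^2$ of the selected
  model and the cross-validated predicted-vs-observed r (with $r^2$ as a
  pseudo-$R^2$) are reported; they answer different questions and both are
  quoted in this literature.

## The synthetic cohort: what it emulates, and what it does not

`simulate_cohort()` draws, per participant, a latent synapse-survival
fraction (group means 1.0 for younger and 0.8 for middle-aged adults by
default, SD 0.10, clipped to (0, 1]), subclinical audiometric covariates,
and latent per-condition effort slopes. Ground truth lives in `.latent_*`
columns that no analysis stage reads.

- **EFR recordings** embed an envelope-locked sinusoid at exactly the AM
  rate, with amplitude `efr_amp_by_rate[rate]` plus `efr_gain * survival`
  at 1024 Hz only - the CND-sensitivity hypothesis in generative form - and
  a carrier-locked component that flips with stimulus polarity. Noise is
  Gaussian with a 1/f power spectrum up to 3 kHz; artifacts are >200 uV
  bursts in a Bernoulli-chosen subset of epochs. The phase-locked response
  lags the stimulus by 10 ms.
- **Pupil traces** follow the acquisition timeline (alert beep, 2 s gap,
  masker onset, 3 s lead, 3 s target sentence, 2 s tail, 2 s gap, response
  prompt). The evoked response is a linear-plus-quadratic trend per window -
  the GCA's own basis, so recovery is exact in expectation - with the
  quadratic centred on the window so the programmed slope *is* the
  window's least-squares slope. Blinks are Poisson-placed zero-dropout
  segments; saccades are flagged without altering the pupil; noise is
  AR(1) (phi = 0.98 at 1000 Hz, marginal SD 2% of baseline).
- **Keyword outcomes** are independent Bernoulli draws from a logistic
  psychometric function whose midpoint combines the group base, the
  participant's PTA4k, their synapse survival, and their
  condition-specific 10 dB listening-effort deviation. That construction
  makes PTA4k, the 1024 Hz EFR amplitude and the 10 dB listening slope the
  three true drivers of 0 dB accuracy - the recovery target for the
  elastic net - while slopes at other SNRs share only a trait component
  that does not touch behavior.
- **Gerbils** get synapse counts per inner hair cell at the 3 kHz place
  (young mean 14, middle-aged 20% lower, SD 1.5) and EFR amplitudes from a
  linear link with Gaussian residuals.

**Choice of effect sizes.** The default conditions fix the middle-aged
survival mean at 0.8, i.e. a 1024 Hz group amplitude ratio of 1.25 - milder
than the ~1.6x ratio implied by group-average SNRs reported in comparable
human cohorts (8 vs 4 dB). The
noise and coefficient defaults are therefore set so the generator
reproduces the emulated study's *inferential* outcomes at realistic
sample sizes: a
group contrast of standardized size ~1.4 at 1024 Hz (strongly significant
at ~30 participants per group), biological EFR spread above
measurement noise so the EFR correlates with behavior across subjects, and
threshold, CND and effort contributions to intelligibility of comparable
magnitude (so that all three domains survive penalized model selection,
as observed in such cohorts). The trade-off is
explicit: the implied young-adult 1024 Hz SNR at 500 sweeps is ~17 dB,
higher than the ~8 dB group averages reported for such recordings.
Matching the reported SNR instead
would make the group contrast undetectable under the milder survival ratio -
the two constraints cannot both hold, and the package resolves the conflict
in favour of the inferential structure.

**What passing tests do not show.** The generator's evoked pupil response
is exactly polynomial, its EFR noise is stationary and Gaussian, keyword
outcomes are independent within sentences, and blink timing is independent
of the stimulus. Real data violate all four (pupil responses have
impulse-like components, EEG noise is nonstationary, keywords within a
sentence are correlated, blinks cluster at sentence boundaries). Parameter
recovery here validates the *implementation* of the chain, not the adequacy
of these models for any particular dataset.

## Problem sizes in the shipped checks

The test suite and `scripts/acceptance.R` run the chain at sizes chosen to
keep a complete run on one CPU comfortable: EFR recordings are synthesized
at 8192 Hz (the 3 kHz carrier stays well below Nyquist; 16384 Hz is the
default elsewhere) with 50 sweeps per recording, with per-sample noise
scaled by sqrt(50/500) so the averaged waveform's noise level equals the
500-sweep study condition in distribution; end-to-end pattern checks use 20
cohorts of 30 participants per group with per-cell OLS slopes; growth-curve
coverage uses 100 simulated datasets of 20 participants per group on a
12-point time grid. Each of these is a stated, reproducible choice - the
statistical structure, not the sample-rate bookkeeping, is what the checks
exercise.

## Known limitations

- The 6 dB significance criterion and flanking-bin noise floor are defined
  for the gerbil acquisition protocol; the package applies the same
  definitions in human mode (flagged, not guessed different).
- Whether "response amplitude" for the 200 uV rule means peak absolute
  value or peak-to-peak is unstated; peak absolute value is implemented
  (configurable via `reject_uv` relative scaling).
- p-values from the GCA use the normal approximation; df-approximation
  p-values (e.g. Satterthwaite) may differ in small samples.
- The blink/saccade detector shipped for unflagged traces
  (`flag_artifacts()`) is a convenience extension; recorded eye-tracker
  flags are always preferred.
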