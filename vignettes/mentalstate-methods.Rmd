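---
title: "Methods: personalized biometric models and their validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: personalized biometric models and their validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of its models, the choices
behind them, and what the synthetic-data tests do and do not establish.

## The decoding problem

Three latent mental states — fatigue, stress, attention — are decoded from
EEG and ECG using two calibration tasks. Breath counting induces low
fatigue and low stress while demanding sustained attention; the visual
N-back task induces graded cognitive load (1-back moderate, 3-back heavy).
The core assumptions are:

* **Fatigue accumulates with time on task.** Training therefore labels the
  breath-count task *low* and only the second half of the 3-back task
  *high*: the first half is discarded so the high class reflects
  accumulated load, not merely task identity.
* **Stress follows load on a fast time scale.** The whole 3-back task is
  the *high*-stress class, and breath-count *low*.
* **Attention is labeled event-wise.** Each self-caught mind-wandering
  button press at time $e$ yields an inattentive window $[e-8, e-2]$ s
  (the bout precedes self-detection) and an attentive window $[e+2, e+8]$
  s. Attentive windows overlapping another event's inattentive window are
  relabeled inattentive — the press evidently did not open a sustained
  attentive period. Subjects with fewer than three usable events are
  excluded from the attention analysis.

## Features

EEG features are integrated periodogram band powers (delta 1–3, theta
4–8, alpha 8–12, beta 13–30, gamma 30–50, high-gamma 50–100 Hz) of 10 s
non-overlapping training bins (6 s for attention), computed per channel.
The default taper is Hann with power normalization — a pure tone whose
spectral smear lies inside a band still integrates to $A^2/2$, and
broadband power is preserved; a rectangular mode exists and makes band
powers over a partition of $(0, \mathrm{Nyquist}]$ sum exactly to the
segment variance (Parseval), which the tests exploit. Band membership of
a DFT bin is half-open, $lo \le f < hi$, with the Nyquist bin closing the
last band.

Powers are transformed $\log_{10}(x + 10^{-12})$ and z-scored with
statistics from the training split only. Raw band powers are heavy-tailed
(a band integral of a stochastic signal is approximately a scaled
chi-square), and the log transform is what keeps the IRLS fits stable;
a `raw` mode is provided. Whether band powers are absolute or per-window
normalized is configurable (`relative`); absolute is the default.

HRV features come from the RR tachogram: R peaks are detected by a
Pan-Tompkins-style detector (5–30 Hz band-pass, squared derivative,
150 ms integration, adaptive threshold, 300 ms refractory period, peak
refinement on the band-passed signal), and the RR series is linearly
interpolated to a uniform 4 Hz grid, detrended, and integrated over VLF
(0.01–0.04), LF (0.04–0.15) and HF (0.15–0.4 Hz). A frequency of
0.01 Hz is not resolvable inside a 10 s bin, so each bin receives
features from a longer **context window** (default 120 s, clipped at
recording edges) centered on it: the bin timeline of the EEG features is
preserved while the spectral estimate is physically meaningful. This is
a deliberate design decision and is flagged in the function
documentation; shorter contexts sacrifice VLF resolution.

## Preprocessing

The cleaning chain is: order-4 zero-phase Butterworth 59–61 Hz band-stop
and 0.1 Hz high-pass (forward-backward filtering avoids group delay that
would smear event-locked attention windows), DC removal, average
re-referencing of the EEG channels only; single-pass channel rejection
flagging channels whose log median-normalized total 1–250 Hz power
exceeds mean + 3 SD; FastICA (symmetric fixed point, logcosh contrast,
component count = rank of the re-referenced data); component ranking by
maximum absolute correlation with nuisance channels (EOG, ECG,
accelerometer if present); iterative component rejection under a quality
index; spherical-spline interpolation of rejected channels (order
$m = 4$, 20 Legendre terms, regularization $10^{-5}$, inverse-distance
fallback below 3 positioned neighbors); and centered moving-average
subtraction (1000 samples EEG, 50 samples ECG, edges shrinking).

The quality index is a pluggable contract `recording -> score` with
*lower = better*: a candidate component stays rejected iff removing it
changes the score by less than −0.001, and the loop stops once every
component has been tried or only 25% of components remain unrejected.
The default index is the fraction of spectral power that is
non-physiological (59–61 Hz plus everything above 100 Hz); it is a
self-contained proxy with the documented sign convention, and any
external quality measure can be substituted through the contract.
Channel rejection is single-pass and non-iterative, and the
"normalized spectral power" is median-normalized then log-transformed
before the outlier rule — both are configurable interpretation points
the protocol leaves open.

## The committee GLM

Each electrode gets its own binomial-logit GLM fit by IRLS (convergence
when the largest coefficient step is below $10^{-8}$, at most 100
iterations) with ridge $10^{-4}$ on the slopes only. The penalty exists
for one reason: plain maximum likelihood diverges on separable data,
which high-SNR training windows routinely are; $10^{-4}$ bounds the
coefficients without moving non-degenerate fits appreciably.
Non-convergent electrodes are dropped from the committee with a warning.
Committee output is the unweighted mean of member sigmoids — order
invariant, and in $[0,1]$ by construction. ECG-only feature sets have a
single member. For `Ps4` the three HRV features are appended identically
to every electrode's design matrix (the alternative — HRV as an extra
committee member — is a config choice, `hrv_as_member`-style, not the
default).

Label polarity is attentive = 1, inattentive = 0, and high fatigue/stress
= 1, so every trace reads "probability of the high state". The class
prior is made uniform by the balanced partitioning below rather than by
any weighting inside the GLM.

Wald p-values from the penalized information matrix drive the
cross-subject consistency screen: a (channel, band) coefficient is
reported when significant (p < 0.05) with the same sign in more than
half of the subjects.

## Validation

**Level 1.** Balanced k-fold CV: every fold holds an equal number of
windows per class; surplus windows are discarded at random under a
recorded seed (the protocol states balance but not the mechanism).
k = 10 for fatigue/stress; k = 3 for attention because usable
mind-wandering events are scarce. Accuracy is threshold-0.5, averaged
over electrodes and folds.

**Level 2.** Leave-one-out scoring of the training windows gives a lower
bound (mean committee score of low-class windows) and an upper bound
(high-class mean). The held-out 1-back trace must average strictly
between them; two *directional* paired t-tests across subjects are each
read at 0.025 (correcting for the two comparisons). The protocol text
mentions both one- and two-tailed variants in different places; the
default here is one-tailed since the hypothesis is directional, and
`tails = "two"` is exposed. A one-way repeated-measures ANOVA over
time-binned trace values probes a time-on-task effect — expected for
fatigue (its latent ramps) and absent for stress (its latent is flat
within a task).

**Level 3.** Per-trial biometric means (trace samples within each 2 s
trial extent) are smoothed with a trailing moving average of $w = 1..10$
trials and correlated (Pearson; Spearman by flag) with the equally
smoothed accuracy and reaction-time series. The permutation null
shuffles the *raw* per-trial performance and re-applies the smoothing,
so the null respects the autocorrelation the averaging induces; p =
$(1 + \#\{|r_0| \ge |r|\})/(n_{iter}+1)$ with 3,000 iterations,
two-sided because both positive and negative couplings are meaningful.
Whether the original smoothing was trailing or centered is not
documented anywhere; trailing with matched-span averaging on the
biometric side is implemented and noted here. Subjects score 1 / 0.5 / 0
according to whether both / one / neither threat type reaches p < 0.05.

## The synthetic generator

The generator is first-class, tested code; it defines the study
conditions the validation levels are exercised under.

* **Latents**: fatigue ramps linearly from 0 to a load-dependent cap
  (0.1 breath-count, 0.7 1-back, 1.0 3-back); stress steps at task onset
  to 0.1 / 0.5 / 0.9 for breath-count / 1-back / 3-back, making the
  intermediate task genuinely midway by construction; attention
  alternates attentive runs (20 + Exp(40) s) with mind-wandering bouts
  (10 + Exp(10) s, press at bout end) only during breath counting. No
  bout statistics are documented for the original task; these values
  were chosen once so a bout comfortably contains the 8-to-2 s labeling
  window and a 5-minute session yields about three events, and are not
  revisited per test.
* **EEG**: per channel, a 1/f background (exponent fixed at 1) plus six
  band-limited Gaussian carriers (FFT-masked white noise) whose
  amplitude is `baseline * (1 + effect * latent(t))` for each matching
  row of a signed effect table. The default table encodes the
  directions the models are meant to find: fatigue raises frontal gamma
  and lowers fronto-central alpha; stress raises pre-frontal, central
  and centro-parietal theta and frontal gamma, and lowers fronto-central
  delta, frontal beta and widespread alpha; mind-wandering raises
  theta/delta and lowers alpha/beta scalp-wide. Optional artifacts (60 Hz
  line tone, blink transients, one high-power channel) have their
  ground-truth locations exported.
* **ECG**: beat-to-beat intervals
  $RR(t) = \bar{RR} + a_{LF}\sin(2\pi\,0.1\,t+\phi) + a_{HF}\sin(2\pi\,0.3\,t+\psi) + \varepsilon$,
  with $a_{LF}$ increasing and $a_{HF}$ decreasing in the stress latent;
  a QRS-like template (R spike, Q/S dips, T wave) is placed at each beat
  and true beat times are exported.
* **Behavior**: trial correctness is Bernoulli with a logit link to the
  latents and reaction time is linear in the latents plus Gaussian
  noise truncated to (0, 2] s; a null mode zeroes the links for
  calibration experiments.

What the generator does **not** emulate: dipolar scalp topographies and
volume conduction, realistic EEG morphology, non-stationary artifacts
beyond the three injected kinds, respiratory sinus arrhythmia coupling,
or learning effects in behavior. Passing parameter-recovery tests
therefore shows the pipeline implements its own contracts faithfully and
recovers known structure at realistic SNR — not that the same accuracies
would be achieved on real recordings.

## Numerical choices and problem sizes

Windows are half-open $[start, end)$ in seconds with 0-based sample
indexing; the Parseval-closing Nyquist rule is described above. The
ratio feature guards its denominator at $10^{-12}$. Zero-variance
features z-score to zero (SD clamped to 1). IRLS weights are floored at
$10^{-10}$. The test suite and the acceptance script run sessions of
300–900 s at 250 Hz on montage subsets of 5–10 channels covering the
regions the effect tables act on, with cohorts of 2–10 subjects — sizes
chosen so the full suite completes in a few minutes while every check
retains clear margins; the configuration defaults (500 Hz, 30/21/21 min
sessions, the full 29-channel montage) reflect the original protocol and
are used when `pipeline_config()` is left untouched.

## Known limitations

* The attention biometric is data-starved by design (few mind-wandering
  events per session); short synthetic sessions are frequently excluded,
  matching the original protocol's exclusions.
* Within a 10 s bin, VLF HRV power is only as local as its 120 s
  context; VLF-driven stress features are accordingly smooth in time.
* The intermediate regression test assumes the 1-back latent truly sits
  between the calibration extremes; with saturated committees the
  intermediate score is sensitive to where each subject's decision
  boundary falls, which widens its between-subject variance.
* File I/O is CSV plus a JSON sidecar; EDF is not read or written.
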