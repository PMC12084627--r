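---
title: "Analyzing pupil-biofeedback arousal experiments with pupilarousal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analyzing pupil-biofeedback arousal experiments with pupilarousal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem this package addresses

Pupil-based biofeedback trains participants to volitionally increase
("upregulate") or decrease ("downregulate") their own pupil diameter, a
peripheral readout tightly coupled to the brain's arousal-regulating
nuclei, most prominently the noradrenergic locus coeruleus. A study built
on this technique asks whether self-regulated pupil size moves *central*
arousal markers as well, and measures three of them in three experiment
layouts:

* **Cortical excitability** (experiment 1): single-pulse TMS over motor
  cortex during self-regulation; the outcome is the motor evoked potential
  (MEP), the peak-to-peak EMG deflection 15-60 ms after the pulse,
  normalized to a resting control condition.
* **Cortical arousal** (experiment 2): EEG during self-regulation; the
  outcome is the aperiodic exponent of the power spectrum (the "spectral
  slope"), fit in 30-45 Hz. A flatter spectrum (smaller exponent) is read
  as a higher excitation/inhibition ratio, i.e. higher cortical arousal.
* **Phasic arousal responses** (experiment 3): EEG during a two-tone
  auditory oddball task embedded in self-regulation; the outcomes are the
  spectral slope around tone onset and the target-evoked P300 (mean
  amplitude 252-600 ms over a 24-channel centroparietal set), analyzed with
  spatiotemporal cluster-based permutation tests.

Heart rate and RMSSD (the root mean square of successive R-R interval
differences, a time-domain parasympathetic marker) accompany all layouts.

`pupilarousal` implements the full analysis chain for these designs, plus a
seeded synthetic cohort generator that reproduces the trial structure and
condition effects, so the pipeline can be exercised and validated end to
end without access to human raw data (which the original study cannot
share).

## The analysis chain and its defaults

Every default below is the value used by the study design the package
models; all are arguments that can be overridden.

**Online feedback** (`validate_sample()`, `compute_feedback()`,
`relative_luminance()`). Samples are rejected outside 1.5-9 mm, on tracker
blink flags, and when the diameter changes faster than the velocity
threshold. The study prints this threshold as 0.0027 mm/s, which cannot be
a literal mm-per-second limit — pupillary light-reflex peak velocities,
the cited justification, are on the order of several mm/s, and a
0.0027 mm/s limit would reject essentially every real sample. We read the
printed digits as mm/ms (2.7 mm/s) by default and expose both readings via
`velocity_units`. Post-trial feedback compares the mean of the valid
modulation-phase samples to the mean of the valid baseline samples;
success (a green circle) requires a strict inequality in the instructed
direction, so an exactly-zero change is unsuccessful for both directions.

**Pupil preprocessing** (`preprocess_pupil()`, `baseline_correct()`,
`pupil_modulation_index()`, `pre_pulse_pupil()`). Per eye: dilation-speed
outliers (median + 12 x MAD of the per-sample speed, where the speed is the
larger of the backward/forward difference magnitudes), four passes of
trend-line deviation removal (residuals against a 4 Hz zero-phase trend,
same median + 12 x MAD rule), and removal of isolated valid islands up to
50 ms wide bordered by gaps wider than 40 ms. Eyes are averaged on the
common grid, the missing fraction is recorded *before* interpolation,
traces are linearly interpolated to 1000 Hz (gaps longer than 2 s stay
missing — unbounded interpolation would fabricate data), and smoothed with
a zero-phase order-3 Butterworth low-pass at 4 Hz. Trials with more than
50% missing samples are rejected. Two numerical guards matter only for
synthetic data: the MAD entering both thresholds has a floor
(`speed_mad_floor` 1e-4 mm/ms, `dev_mad_floor` 1e-3 mm, both far below
eye-tracker resolution) because on noise-free traces the MAD is exactly
zero and the thresholds would otherwise reject arbitrarily small
fluctuations; and all zero-phase filters use odd-reflection edge padding so
constants pass through exactly. Baseline correction subtracts the mean of
the last 1000 ms before modulation onset. The modulation index is the
per-millisecond mean difference of baseline-corrected traces, upregulation
minus downregulation, averaged over the 15 s modulation window (15,000
points at 1000 Hz).

**Spectral slope** (`welch_psd()`, `fit_aperiodic()`, `slope_for_bins()`,
`slope_modulation_index()`). Welch spectra use 1 s segments with 50%
overlap on a 1-45 Hz grid at 1 Hz resolution; 500 ms analysis bins are
zero-padded to one 1 s segment so the grid is preserved (averaging then
happens across trials, not within the bin). The window defaults to Hann
rather than the more traditional Hamming: the synthetic signals are exact
power laws down to very low frequency, and Hamming's flat -43 dB sidelobes
leak enough low-frequency power into 30-45 Hz to bias a true exponent of 3
down to about 2.4, while Hann's 18 dB/octave sidelobe falloff leaves the
recovery accurate to within about 0.01 (Hamming remains selectable; on
high-pass-filtered real EEG the difference is much smaller). The aperiodic
fit follows the standard spectral parameterization algorithm in fixed
(no-knee) mode: initial log-log line fit, robust refit on the points at or
below the 2.5th percentile of the zero-clipped flattened spectrum,
iterative extraction of up to 3 Gaussian peaks from the flattened spectrum
(relative threshold 2 population SDs, minimum height 0, FWHM limits
0.5-12 Hz), joint Levenberg-Marquardt refit of all peaks, and a final line
fit on the peak-removed spectrum. Exponents are fit per channel on
trial-averaged cell spectra and reported as the whole-head channel mean.
Fit ranges: 30-45 Hz (primary) and 2-40 Hz (secondary).

A note on sign conventions: the fitted exponent chi is positive and larger
for steeper spectra. `slope_modulation_index()` returns the exponent
difference up - down (negative when downregulation steepens the spectrum).
The study's figures work in signed-slope units (-chi), where the analogous
index is positive; `run_exp2()` reports that form as `steepening_index`
(chi_down - chi_up) and `run_exp3()` correlates the *signed* pre-tone slope
with the P300, so the directions printed by the pipelines match the
study's: a positive pupil-slope coupling and a negative slope-P300
repeated-measures correlation.

**ERP statistics** (`build_epochs()`, `mean_amplitude()`,
`cluster_permutation_test()`). Epochs span -100 to 800 ms around tone
onset at 250 Hz and are baseline-corrected to -100 to 0 ms; artifact
epochs and behaviorally invalid trials (false alarms, misses) are dropped.
Windowed amplitudes use half-open `[from, to)` windows on the sample grid.
The cluster test forms point-wise paired t maps across participants,
thresholds them at the two-sided point-wise t critical value (p = .05,
df = n-1), groups suprathreshold points into clusters contiguous in time
and across neighboring channels (neighbors = electrodes within 0.3 head
units on the idealized grid montage, giving a median of 4-8 neighbors),
and compares each cluster's mass (summed t values) against the maximum
absolute cluster mass over sign-flip permutations of the participant
difference maps — all 2^n assignments when that count does not exceed
`n_perm` (5000 by default), otherwise Monte-Carlo draws. The observed
assignment counts in its own null, so p is never zero, and the
max-statistic over both signs makes the test two-sided and family-wise
error controlling. The permutation loop is compiled (C++) because it is the
computational bottleneck of the calibration experiments. The N100 control
window is 52-200 ms, the value stated in the study's Methods (its figure
caption says 50-200 ms; the Methods value is used).

**Cardiac indices** (`heart_rate()`, `rmssd()`, `cardiac_indices()`).
R-peak detection is out of scope (peak times are an input); an R-R
interval counts toward a phase only when both bounding peaks fall inside
it. Heart rate is 60 divided by each interval, averaged per phase; RMSSD
is reported in ms. Indices: experiment-2 style is up - down for heart rate
and down - up for RMSSD (larger = stronger modulation in both);
experiment-1 style divides each condition by rest first.

**MEP extraction** (`filter_emg()`, `extract_mep()`,
`apply_exclusions()`, `normalize_to_rest()`). EMG is band-passed 30-800 Hz
(order-4 Butterworth, zero phase) with a 50 Hz biquad notch (Q = 30),
applied separately to the pre-pulse and post-pulse windows so the MEP
cannot smear into the background estimate. Peak-to-peak amplitude is
max - min over (15, 60] ms post-pulse; background RMS covers
(-105, -5] ms. The exclusion ledger runs exactly three ordered stages:
records with background RMS above 0.01 mV; then, per participant, records
above the pooled mean + 2.5 sample SDs of the survivors; then whole
participants whose up/down background means differ by more than 0.001 mV.
The stage order is load-bearing (stage 2's statistics are computed on
stage-1 survivors) and the test suite pins it with a permuted-order
counterexample.

**Statistics layer** (`paired_location_test()`,
`holm_sequential_bonferroni()`, `rm_anova()`, `rm_correlation()`,
`meng_dependent_correlation_z()`, `correlation()`). Paired/one-sample t
tests report Cohen's d for paired data (mean difference / SD of
differences); the Wilcoxon option uses the exact distribution up to
n = 25. The within-subject ANOVA decomposes 1-3 crossed factors with each
effect tested against its own effect-by-subject interaction;
Greenhouse-Geisser epsilon comes from the covariance of orthonormal
contrast scores and is applied whenever an effect has more than one
numerator df and epsilon < 1 (the original analysis gated this on
Mauchly's test, which is out of scope; the unconditional policy is
conservative and configurable). The repeated-measures correlation is the
ANCOVA estimator (subject intercepts, common slope) with
df = N - n_subjects - 1. Sphericity diagnostics, Bayes factors, and
noncentral effect-size intervals are out of scope.

## What the synthetic cohorts emulate

`cohort_config()` fixes the experiment layouts exactly: 20 trials per
condition with two TMS pulses each (the first jittered 3-4 s, the second
at 11 s after modulation onset; 40 MEPs per condition), 30 + 30 trials
with 15 s modulation, and 117 oddball trials in 9 blocks of 13 with 8
tones each (first always a standard, inter-tone onsets uniform on
1.8-2.2 s, at least two standards between targets — hence at least 5.4 s
between target onsets, 186 targets and 750 standards in total; the 69/48
split of two-/one-target trials is the unique integer solution and tone
sequences are congruent across conditions). Block orders are
counterbalanced with a seeded Latin square.

Signals: pupil traces are two correlated 60 Hz eyes ramping (half-cosine,
1 s) from a participant-specific baseline toward baseline + delta, with
binocular blink gaps and spike artifacts at configurable rates and the
ground-truth artifact indices attached; EEG channels are frequency-domain
shaped Gaussian noise with power proportional to f^(-chi) (DC zeroed,
scaled to 10 uV sample SD), plus Gaussian-windowed evoked components
(negative, sigma 40 ms, peaking 100 ms; positive, sigma 80 ms, peaking
350 ms on the centroparietal subset, amplitude = the condition's true P300
for targets); R-peak series use an alternating +/-d interval construction
solved so the expected sample RMSSD equals its target
(RMSSD^2 = 4 d^2 + 2 sigma_jitter^2); EMG segments carry band-limited
background noise at a controlled RMS plus a 150 Hz Gabor-like deflection
(envelope sigma 4 ms at 30 ms post-pulse) whose noise-free peak-to-peak
equals the true MEP and whose energy stays inside the 15-60 ms window and
the 30-800 Hz band.

Condition effects default to a strong-modulation regime: pupil index
0.5 mm, exponent index 0.3 (down steeper), heart rate 3 bpm, RMSSD 5 ms,
MEP up/down = 115%/85% of rest, target P300 6 uV in downregulation versus
4 uV in the other conditions. Between-participant index SDs (0.33 mm, 0.2,
2 bpm, 3.3 ms, 0.2, 1.34 uV for the respective indices) were chosen once,
before any detection experiment was run, so that each headline paired
effect has a standardized size near 1.5 — the upper end of the effects the
design is meant to produce — giving near-unit power at the cohort sizes
used in the validation runs (a paired test at dz = 1.5 and n = 12-14 has
power above 0.99 at alpha = .05). A latent arousal factor, drawn once per
participant, loads on both the pupil and the steepening index with weight
`latent_arousal_sd` (default sqrt(0.5)), inducing a cross-measure
correlation of about 0.5, matching in sign and order the association the
study reports between pupil and slope modulation; setting it to 0 removes
the coupling.

What the generator deliberately does *not* emulate: real EEG morphology
(oscillatory richness, non-stationarity, a spectral knee), ocular/muscle
artifact physics (artifacts are explicit flags, standing in for the ICA
cleaning chain that is out of scope), respiratory sinus arrhythmia beyond
the alternating-interval construction, tone-evoked slope changes, and any
relation between behavioral errors and arousal state. Passing tests
therefore certify the *analysis chain* — that each stage recovers what the
generative model put in, at realistic noise levels — not that the science
of the original data would replicate.

## Validation problem sizes

The test suite runs at desk scale, with sizes chosen — before the
detection experiments were run — by power analysis against the generator's
effect regime: cluster-test calibration uses 500 null cohorts and 100
injected-effect cohorts of 12 participants, 24 channels and 225 time
points with 600 and 500 Monte-Carlo permutations (p resolution ~0.002,
far below alpha); end-to-end detection uses 20 seeded cohorts per
experiment at close to the study's own sample sizes (18 participants for
the EEG biofeedback layout, 19 for the oddball layout, 10 for the TMS
direction checks), plus 12 all-null cohorts for false-alarm rates. One
estimation fact drives these sizes: a single-channel 30-45 Hz exponent
from a 3-s-bin trial average has a standard deviation near 0.3 (the fit
spans only 0.18 decades of log-frequency), so accurate slope statements
need the whole-head channel average — the recovery checks therefore use
the full 64-channel montage, while the pipeline runs use 4-14 channels and
lean on per-participant bin averaging. Channel counts scale the whole-head
average and the cluster space, not the per-channel physics, so smaller
montages leave the logic under test unchanged.

## A worked example

```{r, eval = FALSE}
library(pupilarousal)

cfg <- cohort_config("exp2", n_participants = 12, seed = 7,
                     channels = c("Fz", "Cz", "Pz", "Oz"))
res <- run_exp2(cfg)

res$tests$slope_up_vs_down$statistic  # negative: upregulation is flatter
res$tests$pupil_index$p               # pupil modulation index > 0
head(res$indices)
```

See the README for a worked example with the numbers it prints.

## Known limitations

* The aperiodic fit implements only the fixed (no-knee) mode the study
  uses; spectra with a visible knee in the fit range will bias the
  exponent.
* The cluster test assumes a paired (within-subject) design; independent
  groups are not supported.
* `rm_anova()` requires complete balanced tables; listwise deletion is the
  caller's responsibility.
* The generator's artifact flags are independent Bernoulli draws; real
  artifact structure (runs of bad epochs, condition-correlated artifacts)
  is not modeled, so exclusion-rate statistics generalize only loosely.
* Smoothing makes the pupil pipeline idempotent only for in-band signal
  content; broadband sensor noise is (intentionally) attenuated again on a
  second pass.
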