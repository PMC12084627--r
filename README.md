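# pupilarousal

Multimodal analysis of pupil-based biofeedback experiments on central
arousal, for researchers who combine pupillometry with TMS, EEG, ECG, and
auditory oddball paradigms.

Pupil-based biofeedback lets participants volitionally upregulate or
downregulate their own pupil diameter, a peripheral proxy of the brain's
arousal-regulating (locus coeruleus-noradrenergic) system. This package
implements the complete analysis chain used to ask whether such
self-regulation moves central arousal markers:

* **online feedback scoring** — per-sample validity (1.5-9 mm range,
  velocity limit, blink flags), baseline-referenced average/maximum change,
  strict success classification, and the isoluminance helper
  Y = 0.2126 R + 0.7152 G + 0.0722 B;
* **pupillometry preprocessing** — dilation-speed and trend-line outlier
  removal with a median + 12 x MAD criterion, isolated-island removal,
  eye averaging, 1000 Hz interpolation, 4 Hz zero-phase smoothing,
  last-second baseline correction, and the pupil modulation index
  (mean up-down difference over the 15 s modulation window);
* **EEG spectral slope** — Welch spectra (1 Hz resolution, 1-45 Hz, 50%
  overlap) and an aperiodic ("1/f") parameterization in fixed mode: a
  log-log line plus up to 3 Gaussian peaks, fit 30-45 Hz (or 2-40 Hz),
  with the exponent chi as the arousal marker (flatter = more aroused);
* **ERP statistics** — epoching (-100..800 ms, baseline -100..0 ms),
  windowed mean amplitudes (P300: 252-600 ms over a 24-channel
  centroparietal set; N100: 52-200 ms), and a paired spatiotemporal
  cluster-based permutation test (point-wise paired t maps, cluster mass,
  sign-flip max-statistic null, exhaustive when 2^n fits the permutation
  budget);
* **cardiac indices** — heart rate (60/RR) and RMSSD per phase, with the
  both-peaks-inside-the-phase rule and up-down / rest-normalized indices;
* **TMS-MEP extraction** — 30-800 Hz band-pass + 50 Hz notch applied
  separately pre/post pulse, peak-to-peak over (15, 60] ms, background-EMG
  RMS over (-105, -5] ms, and the three-stage exclusion ledger
  (> 0.01 mV absolute; > pooled mean + 2.5 SD; participant out when the
  up/down background means differ by > 0.001 mV);
* **a repeated-measures statistical layer** — paired t / Wilcoxon with
  Cohen's d, Holm sequential Bonferroni, within-subject ANOVA (1-3
  factors) with Greenhouse-Geisser correction, repeated-measures
  correlation, Pearson/Spearman, and the Meng-Rosenthal-Rubin z test for
  dependent correlations;
* **a seeded synthetic cohort generator** that reproduces the three
  experiment layouts (20 trials x 3 conditions with 2 TMS pulses; 30 + 30
  trials of 15 s modulation; 117 oddball trials in 9 blocks of 13 with 8
  tones each, 186 targets / 750 standards, >= 2 standards between targets)
  with configurable condition effects, a latent arousal factor coupling the
  pupil and spectral-slope effects, and stored ground truth for
  parameter-recovery testing.

The experiment-level drivers `run_exp1()`, `run_exp2()`, and `run_exp3()`
push a generated cohort through every stage and return tidy
per-participant tables plus the group-level tests.

## Worked example

```r
library(pupilarousal)

cfg <- cohort_config("exp2", n_participants = 12, seed = 7,
                     channels = c("Fz", "Cz", "Pz", "Oz"))
res <- run_exp2(cfg)

round(c(pupil_index = mean(res$indices$pupil_index),
        slope_index = mean(res$indices$slope_index),
        hr_index    = mean(res$indices$hr_index),
        rmssd_index = mean(res$indices$rmssd_index)), 3)
#> pupil_index slope_index    hr_index rmssd_index
#>       0.351      -0.284       2.350       5.396

res$tests$slope_up_vs_down[c("statistic", "df", "p")]
#> $statistic
#> [1] -4.797743
#> $df
#> [1] 11
#> $p
#> [1] 0.0005553552
```

The cohort was generated with a true pupil modulation index of 0.5 mm and
a true exponent difference of 0.3 (downregulation steeper). The analysis
recovers both within cohort sampling noise: the mean pupil index is
~0.35 mm for this 12-participant draw (the 1 s onset ramp also dilutes the
15 s average slightly), the slope index (exponent up - down) is ~-0.28,
and the paired test detects the flatter spectrum under upregulation
(negative t on 11 df). Heart rate is ~2.4 bpm higher and RMSSD ~5.4 ms
lower during upregulation, matching the generator's cardiac truth.

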