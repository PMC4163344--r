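---
title: "Spectral estimation of chest compression rate and depth from sternal acceleration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral estimation of chest compression rate and depth from sternal acceleration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Feedback devices that guide cardiopulmonary resuscitation (CPR) need the
mean chest compression rate (min^-1^) and depth (mm) every few seconds.
Most accelerometer-based devices obtain depth by integrating the sternal
acceleration twice. Double integration is exquisitely sensitive to
low-frequency noise: a constant acceleration offset $b$ grows into a
displacement drift of $1000\,b\,t^2/2$ mm, so every practical device
bolts on drift compensation — extra sensors or per-cycle resets.

`cprspectral` implements the alternative this package is built around:
during continuous compressions, short intervals (2–5 s) of the
acceleration are almost periodic, so the signal can be represented by a
truncated Fourier series and the displacement recovered *algebraically*,
harmonic by harmonic, with no integration at all.

## The model

Within one analysis interval of duration $T_w$, with fundamental
(compression) frequency $f_{cc}$ in Hz,

$$a(t) = \sum_{k=1}^{N} A_k \cos(2\pi k f_{cc} t + \theta_k)
  \quad [\mathrm{m/s^2}],$$
$$s(t) = \sum_{k=1}^{N} S_k \cos(2\pi k f_{cc} t + \phi_k)
  \quad [\mathrm{mm}].$$

Because $a(t) = \mathrm{d}^2 s(t)/\mathrm{d}t^2$, each displacement
harmonic follows from the corresponding acceleration harmonic:

$$S_k = \frac{1000\,A_k}{(2\pi k f_{cc})^2}, \qquad
  \phi_k = \theta_k + \pi .$$

One cycle of $s(t)$ is reconstructed on a fine grid and the feedback pair
is read off as

$$\text{rate} = 60 f_{cc} \ \ [\mathrm{min^{-1}}], \qquad
  \text{depth} = \max s(t) - \min s(t) \ \ [\mathrm{mm}].$$

Because the window's mean is removed before the transform, any constant
acceleration (gravity, sensor bias) is invisible to the estimate — the
drift problem never arises. Each window is processed independently, so
an error in one window cannot propagate.

## The estimation pipeline

`feedback_from_window()` composes four steps, each exported separately:

1. **`project_axes()`** – the method operates on a scalar signal, but
   the sensor records three axes and the combination is a genuine design
   choice. The default projects the mean-removed window onto its
   principal-variance direction, which is invariant under rigid
   rotations of the sensor frame: an 18° tilt between the device and the
   chest normal needs no special handling. Fixed-axis and
   vector-magnitude modes exist for comparison. The projection sign is
   fixed deterministically (the earliest sample reaching half the
   segment maximum is made positive); the spectrum is sign-invariant, so
   this matters only for reproducibility of the waveform itself.
2. **`window_and_spectrum()`** – mean removal, Hamming taper, 2048-point
   zero-padded FFT. The taper's coherent gain $\sum_n w_n$ is recorded:
   a unit-amplitude cosine produces a mainlobe peak of magnitude
   $\sum_n w_n / 2$, so amplitudes are read off as
   $A_k = 2\,|X|/\sum_n w_n$. Without this correction all depths would
   be biased low by the mean taper value (≈ 0.54). Zero padding samples
   the continuous spectrum of the short window densely, which makes the
   scalloping loss of reading the lobe maximum negligible.
3. **`estimate_fundamental()`** – largest-magnitude bin inside the
   search band (default 0.6–3.5 Hz, i.e. 36–210 min^-1^, guideline
   rates with margin), followed by a subharmonic check: pulse-like
   compression waveforms can put more energy into the second harmonic
   than into the fundamental, in which case the largest bin sits at
   $2f_{cc}$. A candidate at half the winning frequency is accepted if
   it is a genuine interior local maximum, reaches
   `subharmonic_ratio` (default 0.3) of the main peak, *and* is
   separated from it by a real spectral valley (minimum between the two
   below half the candidate). The valley condition exists because at
   $T_w = 2$ s the mainlobe of a 1.3 Hz fundamental is ±1 Hz wide: its
   skirt reaches $f_{cc}/2$ without being a peak, and accepting it
   halves the rate and quadruples the depth.
4. **`estimate_harmonics()` / `reconstruct_cycle()`** – for
   $k = 1 \dots N$ (default $N = 3$) the local magnitude maximum within
   $\pm\max(1.5\,\mathrm{bins},\ 0.1 f_{cc})$ of $k f_{cc}$ is read off;
   harmonics at or above Nyquist, or below the noise floor, are zeroed.
   Measured phases are re-referenced to the window centre: a symmetric
   taper carries linear phase $-2\pi f (n-1)/(2 f_s)$, and at
   bin-quantized frequencies that term would skew the *relative*
   harmonic phases and distort the reconstructed cycle shape.

### Periodicity detection and degenerate inputs

A window is only accepted as periodic if the winning peak exceeds
`noise_floor_mult` (default 5) times a noise-floor estimate. The floor
is the median magnitude *above three times the band top* — beyond the
highest possible harmonic — because inside the band the mainlobes of a
short window can cover most bins and an in-band median is then not a
noise floor at all. White-noise windows fail the test (their peak/floor
ratio is ≈ 3); windows with zero variance raise a distinct
"no compression activity" condition. `analyze_session()` converts both
conditions into gap rows (`NA` with a reason), never fabricated values.

### Fundamental refinement

`refine_peak` (default `TRUE`) applies three-point parabolic
interpolation around the winning bin. Two considerations set the
default. First, the bin error enters the depth *quadratically* through
the $1/f_{cc}^2$ conversion: a half-bin error (0.024 Hz) at
100 min^-1^ moves the depth by ±3%. Second, the synthetic benchmark
(below) jitters cycle periods independently per cycle, which makes the
spectral estimate and the interval-based reference disagree by an
irreducible weighting term; stacking bin quantization on top of that
term would push the window-level limits of agreement past what the
method achieves on real, slowly-varying human compressions.
Bin-resolution read-off (`refine_peak = FALSE`) remains available and is
what the closed-form recovery tests exercise: a noiseless sinusoid at
any guideline rate/depth is then recovered within one FFT bin in rate
(60·100/2048 ≈ 2.93 min^-1^) and 3% in depth.

## Signal conditioning

`preprocess_record()` applies a third-order Butterworth low-pass at
15 Hz and resamples to 100 Hz. Filtering is zero-phase by default
(forward–backward, so method and reference windows stay aligned in
offline evaluation); a causal single pass is available for real-time
fidelity studies. The implementation pads both ends with an odd
reflection before filtering so that the gravity step at the record
boundary does not ring into the first and last windows. Resampling
assumes the signal is already band-limited below the target Nyquist (the
15 Hz filter guarantees it): integer factors reduce to exact
subsampling, other ratios use Hann-windowed sinc interpolation. Note
that a third-order 15 Hz Butterworth inherently sheds several percent of
energy at 9–10 Hz; the compression band that matters here (fundamental
plus three harmonics, at most ≈ 7 Hz at 140 min^-1^) passes within 2%.

## The gold-standard reference

`detect_compressions()` finds local maxima of the displacement record
above a fixed 15 mm threshold, with a 0.25 s refractory period (taller
peak wins) to suppress double detections — a 240 min^-1^ ceiling, well
above any plausible compression rate. Per window,
`reference_feedback()` aggregates the peaks whose maxima fall in the
half-open window: rate is 60 over the mean inter-peak interval and depth
is the mean peak depth (median aggregation available). At least two
peaks are required; windows with fewer become gap rows. The peak sample
value is the depth, which assumes the displacement signal is referenced
to the resting chest position — exactly what a manikin distance sensor
provides and what the simulator generates.

## The synthetic benchmark

`benchmark_design()` + `evaluate_benchmark()` emulate a 20-rescuer
manikin study: every rescuer delivers 60 s of continuous compressions at
each combination of target rates {80, 100, 120, 140} min^-1^ and depths
{30, 50} mm, once with the sensor aligned and once tilted 18° — 320
records, ≈ 35,000 compressions, sampled at 500 Hz and conditioned to
100 Hz.

Each cycle's period and depth are drawn independently around the targets
(`rate_jitter_cv = 0.03`, `depth_jitter_cv = 0.05`); the within-cycle
waveform is a raised-sine (sin²) pulse occupying `duty_cycle = 0.9` of
the period, with a hold at full recoil for the remainder. The duty value
was chosen on waveform grounds: it yields a realistic brief recoil hold
and a clearly multi-harmonic acceleration (second harmonic ≈ 0.32 of the
fundamental), while a three-harmonic model still captures the
peak-to-peak within about 1% — consistent with the modelling premise
that three harmonics suffice for real compression waveforms. The
compression-axis acceleration is the exact second central difference of
the displacement, rotated into the (possibly tilted) sensor frame, with
gravity (9.81 m/s², rotated likewise, so offset-invariance is exercised
realistically), optional per-axis bias, and white noise
(`noise_std = 0.3` m/s²) added per axis.

Rescuers differ reproducibly: per-rescuer jitter CVs and small
systematic multiplicative rate/depth biases (sd 2% and 5%) are drawn
once per rescuer from seeded distributions, so the spread of per-record
means across the benchmark resembles the 5–95 percentile spans a real
volunteer cohort produces. All draws derive from one master seed;
identical configuration and seed give bit-identical datasets.

**What the simulator does not emulate.** Rescuer leaning (incomplete
recoil), soft/mattress surfaces, pauses in compressions, and the
autocorrelated, slowly-drifting variability of real humans — the
generator's white per-cycle jitter is *harder* on window-level
method-versus-reference agreement than real data in that one respect,
because the spectral estimate and the interval-based reference weight
the cycles inside a window differently. Passing the benchmark therefore
shows correctness of the pipeline under controlled, known-truth
variability, not clinical performance.

## Evaluation protocol

Method and reference estimates are paired per window
(`pair_windows()`), with gapped windows excluded and counted. Pooled
per session kind (regular/tilt):

- `rmse_vs_tw()` — root-mean-square error of rate and depth feedback as
  a function of $T_w$ (the package's tests sweep 2–5 s);
- `bland_altman()` — mean difference (method − reference) and 95%
  limits of agreement, bias ± 1.96·sd with the n−1 denominator;
- `summarize_by_condition()` — per targeted condition, the median and
  5–95 percentiles (linear interpolation, `quantile` type 7) of the
  per-*record* mean rate and depth for both sources, with a
  Mann–Whitney U comparison. Records, not windows, are the unit here.

`mann_whitney_u()` uses midranks for ties and reports the pair-count
statistic $U$. The two-sided p-value is exact — full enumeration of all
$\binom{n+m}{n}$ assignments of the observed ranks — whenever
$\min(n,m) \le 8$ (and the enumeration is affordable); otherwise a
normal approximation with tie and continuity corrections is used. The
split matters: at those sample sizes the normal approximation can be off
by several hundredths, so the exact path is not an optimisation but a
correctness requirement.

`naive_double_integration()` is deliberately included as the
conventional baseline: cumulative trapezoidal integration twice, zero
initial conditions, no compensation. On an offset of 0.05 m/s² it
drifts by 2.5 m (!) in 10 s while the spectral estimate on the same
window moves by less than 0.1% — the motivating contrast, made
quantitative in the test suite.

## Numerical choices and tie-breaks

- Windows are positioned by sample index (`floor(start · fs)`),
  half-open $[t, t + T_w)$; trailing partial windows are discarded.
- The parabolic offset is clamped to ±0.5 bin; a degenerate (flat)
  three-point neighbourhood yields offset 0.
- Harmonic read-off tolerates jitter-broadened peaks by searching a
  neighbourhood of $k f_{cc}$ and falls back to the in-range maximum if
  no interior local maximum exists; the subharmonic check never falls
  back (see above).
- Harmonic acceptance threshold: above 3× the noise floor *and* above
  1% of the strongest component (the Hamming sidelobe level is ≈ 0.7%),
  so a pure tone reports exactly zero higher harmonics.
- Empty records, zero-variance windows, windows longer than `n_fft`,
  and sampling rates at or below twice the cut-off all raise typed,
  informative errors rather than producing numbers.

## Problem sizes

The shipped tests run the full 320-record benchmark once (about a
minute) and reuse it across the study-level checks; unit and property
tests use seconds-long analytic signals. The acceptance script
regenerates the benchmark from scratch at a caller-supplied seed and
reports the pooled depth RMSE (maximum over $T_w \in \{2,3,4,5\}$ s and
session kinds) and the largest-magnitude depth limit of agreement at
$T_w = 3$ s.

## Known limitations

- Depth accuracy inherits the accelerometer assumptions: full chest
  recoil and a hard surface. Leaning detection and dual-accelerometer
  soft-surface correction are out of scope.
- The method presumes continuous, quasi-periodic compressions; windows
  containing pauses are reported as gaps, not estimated.
- The reference aggregation rule (mean interval / mean peak depth over
  peaks inside the window) is one of several defensible conventions;
  it is configurable because window-edge handling is a real degree of
  freedom in any such comparison.

```{r example}
library(cprspectral)

cfg <- simulation_config(target_rate = 110, target_depth = 50, seed = 42)
ses <- generate_session(cfg, rescuer_id = "demo")
acc <- preprocess_record(ses$accel)
cd  <- preprocess_record(ses$cd)

method    <- analyze_session(acc, Tw = 3)
reference <- reference_session(detect_compressions(cd),
                               record_duration(cd), Tw = 3)
pairs <- pair_windows(method, reference)

rmse(pairs$method_depth - pairs$ref_depth)
bland_altman(pairs, "depth")
```
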