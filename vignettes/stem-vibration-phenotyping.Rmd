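---
title: "Free-vibration phenotyping of plant stems: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Free-vibration phenotyping of plant stems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stemvib)
```

## The measurement

A freshly harvested *Arabidopsis* inflorescence stem, trimmed to its basal
10 cm and clamped over the lowest 1 cm, is deflected sideways and released.
The free vibration of a red marker painted at the tip is filmed at 240
frames/s against a black background for about 3 s. Two growth traits are
recorded per sample: stem height $H$ (cm) and the fresh weight $FW$ (mg) of
the 10-cm segment. From the video alone the pipeline estimates

* the **damped natural frequency** $\omega_d$ (Hz), the dominant
  oscillation frequency, and
* the **logarithmic decrement** $\delta$, the per-period decay
  $\delta = \frac{1}{r}\ln(A_i/A_{i+r})$ of peak amplitudes $A_i$,

and from $(\omega_d, \delta, FW)$ the spring–mass–damper parameters of the
stem. Because $\omega_d$ is unit-free in time and $\delta$ is a ratio,
displacement can stay in pixels throughout; no spatial calibration is
needed.

## From video to displacement

Each video is a directory of numbered PNG frames plus a small `meta.json`
holding the frame rate. Per frame, pixels are thresholded in HSV space (a
hue window wrapping through red, with saturation and value floors —
`marker_color_config()`), connected components are labelled, and the
intensity-weighted centroid of the largest component at least `min_area`
(default 5 px) is the marker position. Runs of at most `max_gap` (default
5) missed frames are linearly interpolated to keep the sampling uniform for
the FFT; longer losses fail the sample, which is reported in the batch
status column rather than aborting the run. The displacement trace is the
`x` coordinate (stems are pulled sideways; a `"principal"` axis option
serves tilted cameras) minus its mean, cropped by default at the global
absolute maximum — the release point — so the pre-release hold does not
enter the analysis.

## Frequency: Hanning window and FFT

The damped frequency is the argmax of the one-sided FFT power spectrum of
the tapered displacement inside a search band (default 1–60 Hz, rejected if
the upper edge exceeds Nyquist). With the FFT length equal to the record
length, a 3-s, 240-fps capture resolves $240/720 = 1/3$ Hz, and $\omega_d$
is always reported at that native resolution: no zero-padding or peak
interpolation enters the reported value, so ties at equal power break
deterministically toward the lower bin.

One windowing choice deserves explanation. These oscillations decay within
a few tenths of a second, while the record lasts seconds. A taper spanning
the whole record is nearly zero exactly where the signal lives, and once
realistic tracking jitter is present the windowed peak can sink below the
noise floor. `apply_hanning()` therefore offers `span = "active"`, used by
the pipeline: the taper covers the *active vibration span* — from release
until a sliding envelope falls below a noise floor estimated from the
record tail — and the samples beyond are zeroed. The trace keeps its full
length, so the frequency grid and the reported 1/3 Hz resolution are
unchanged; for sustained or noiseless signals the active span is the whole
record and the two settings coincide. A flat or noise-only spectrum is
rejected when the peak fails to exceed 10× the median in-band power.

## Decrement: per-period peaks and the four-point rule

$\delta$ is read from the *raw* (un-windowed) waveform. Candidate maxima
must clear 2% of the maximum excursion and be separated by at least 0.7
periods, and only the active vibration span is searched — local maxima of
tracking noise after the envelope has died are not oscillation peaks. Peaks
are numbered from the first post-release maximum.

Each peak's amplitude is read by quadrature demodulation rather than the
raw sample value: a least-squares fit of $a\cos + b\sin$ at $\omega_d$ over
a two-period window running forward from the sampled maximum, with
amplitude $\sqrt{a^2+b^2}$, followed by a correction of each amplitude to
its crest time using a first-pass decay estimate. At 240 fps a 30-Hz
oscillation has only 8 samples per period: the sampled maximum sits below
the true crest by an alignment-dependent factor that drifts from period to
period, and the demodulated fit both removes that ripple and averages
tracking noise. Biases that are proportional and identical across periods
cancel exactly from the log-decay slope, which is why the window shape is
kept identical for every peak.

The decrement itself follows the four-point selection rule: for every
window of four consecutive peak ordinals starting at 1 through 6 (peaks
1–9 only), regress $\ln A_i$ on $i$; among windows with slope $p < 0.05$
(two-sided $t$, 2 df) take the one with maximum $r^2$ — earliest wins on
ties — and report $\delta = |\text{slope}|$. If no window qualifies (no
decay, non-monotone peaks) the sample is flagged for manual
re-measurement and excluded from mechanics; no interactive fallback is
attempted.

## Mechanics

With $\zeta = \delta/\sqrt{(2\pi)^2+\delta^2}$,
$\omega_n = \omega_d/\sqrt{1-\zeta^2}$ and the uniform-cantilever
equivalent mass $m_{eq} = 0.245 \times 0.9 \times FW$ (modal coefficient
0.245; 9 of the weighed 10 cm vibrate; tip mass 0 by default since the
marker weighs ≲1% of the stem), the damping coefficient and stiffness are

$$c = 4\pi\,\omega_n m_{eq} \zeta \quad\text{[N/(m/s)]},\qquad
  k = (2\pi\omega_n)^2 m_{eq} \quad\text{[N/m]},$$

with frequencies in Hz and masses in kg everywhere (fresh weight is
accepted in mg and converted). For the damping levels seen in stems
($\zeta \le 0.09$), $\omega_n - \omega_d$ stays below the 1/3 Hz bin, so
the frequency correction is essentially free; $k$ inherits twice the
relative error of $\omega_d$, and the 1/6 Hz worst-case bin quantization
therefore bounds the noiseless $k$ error by roughly $2\cdot(1/6)/f_d$ —
about 2% at 20 Hz, approaching 5% only below ~7 Hz.

## Screening

The mutant screen regresses wild-type $\omega_d$ on $H$ and $FW$ by
ordinary least squares and fits a normal distribution to the residuals
(mean retained, unbiased standard deviation — training sets are small). A
new sample's deviation from its predicted frequency yields a two-tailed
p-value under that normal; `p < 0.01` (default) calls a mutant. Both tails
are tested because lesions can soften or stiffen stems. Models are
condition-specific — growth conditions shift trait and frequency
distributions — so applying a model across conditions warns rather than
refuses, and `run_train()` persists models as versioned JSON.

## What the synthetic generators emulate

`generate_trace()` produces
$d(t) = A_0 e^{-2\pi f_n \zeta t}\cos(2\pi f_d t + \phi) + \varepsilon_t$
with $\varepsilon_t \sim N(0, \sigma^2)$, $\sigma = 0.5$ px by default —
a level chosen so that replicate variability reproduces the observed
hierarchy (about 1% for $\omega_d$, above 10% for $\delta$) qualitatively.
`render_frames()` draws the corresponding anti-aliased red disc video, and
`generate_population()` draws growth-trait tables with
$H \sim N(28, 5^2)$ cm, $FW = 3H - 20 + N(0, 8^2)$ mg and
$\omega_d = 8 + 0.2H + 0.15FW + N(0, 1.5^2)$ Hz, chosen once to sit in the
published trait ranges (heights 15–40 cm, fresh weights 20–120 mg,
frequencies 15–35 Hz) with fresh weight the dominant standardized
predictor; the numbers are illustrative, not fitted. Mutant cohorts share
the trait distribution with $\omega_d$ multiplied by a shift factor (0.35
soft, ~1.17 stiff). All generators are pure functions of their parameters
and seed.

What the generators do *not* emulate: non-exponential or multi-mode decay,
the release transient of a held stem, illumination drift, marker
deformation, and rolling-shutter artefacts. Passing the round-trip tests
therefore demonstrates the correctness of the estimators under the stated
model, not robustness to every artefact of real footage.

## Numerical and scale choices

Test and acceptance workloads are sized for a laptop-class single core:
3-s traces at 240 fps, 100-trace recovery sweeps, populations of ≤1000,
and three-video batch round trips at 192×64 px frames. Degenerate inputs
fail loudly and specifically: aliasing guards on generation, Nyquist
guards on band search, flat traces, constant centroids, rank-deficient
training designs, undersized or duplicated training tables, truncated
model files.

## Known limitations

* Frequencies are reported at raw bin resolution; below ~7 Hz the induced
  stiffness quantization error can reach 5%. Longer records, not
  interpolation, are the intended remedy.
* The decrement inherits the four-point rule's sensitivity to which window
  wins; replicate scatter above 10% for noisy, fast-decaying samples is
  expected and matches the method's published precision.
* The screen assumes a linear trait–frequency relation with homoscedastic
  Gaussian residuals within one growth condition; it flags outliers, it
  does not assign genotypes.
* Tracking assumes a single saturated red marker; multi-marker scenes and
  camera calibration are out of scope.
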