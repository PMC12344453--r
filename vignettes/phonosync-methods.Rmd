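---
title: "Methods: coupled-oscillator analysis of irregular phonation"
author: "phonosync"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coupled-oscillator analysis of irregular phonation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phonosync)
```

## The physical picture

Voiced speech and song are produced by self-sustained oscillation of the
vocal folds (VF). Supraglottic structures — the ventricular ("false")
folds, the aryepiglottic folds, the arytenoid mucosa, the epiglottis —
can oscillate as well, either entrained to the VF or independently. A
system of two coupled self-sustained oscillators exhibits the standard
nonlinear-dynamics repertoire: n:1 frequency locking, loss and
re-establishment of locking during a frequency glide, period-doubling
bifurcations (subharmonics at fo/2), discrete frequency jumps when a
limit cycle destabilizes, biphonation (two incommensurate frequencies),
and chaos. The package measures these phenomena in three kinds of
simultaneously acquired channels, all at one sampling rate (nominally
20 kHz):

* an acoustic pressure signal (microphone),
* the electroglottogram, used sign-inverted (iEGG = −EGG) so that its
  maxima align with minimal VF contact, i.e. with the open phase, the
  same orientation as the area waveforms,
* per-frame open areas segmented from grayscale high-speed
  videoendoscopy: the glottal area waveform (GAW) at the VF level and the
  supraglottic area waveform (SAW), which aggregates all supraglottic
  vibrating areas without distinguishing the structures involved.

Two modelling caveats are built into the types. First, area waveforms are
two-dimensional projections: a SAW minimum need not coincide with maximal
supraglottic contact, so `AreaWaveform` carries no contact semantics.
Second, areas are uncalibrated pixel counts; no mm² conversion is
attempted.

## Phase synchrony

For two channels $a, b$ the pointwise phase synchrony is

$$\mathrm{PS}(t) = \cos\bigl(\lvert \angle(a + jHa) - \angle(b + jHb)
\rvert\bigr),$$

with $H$ the Hilbert transform (computed by the frequency-domain analytic
signal method after mean removal). PS is +1 in-phase, −1 anti-phase, and
0 either for equal frequencies at quadrature or when the prominent
frequencies stand in an integer ratio (the phase difference then sweeps
uniformly and its cosine has median zero over whole periods). Because
only phases enter, PS is invariant under positive rescaling of either
input, and the absolute value inside the cosine makes the implementation
exactly symmetric in its arguments.

`windowedPS` reports the median, 25% and 75% quantiles (and their
difference, the IQR) over consecutive windows. The window length follows
the variable-window rule

$$N_\mathrm{win} = \lfloor F_s / f_{o,\min} \rfloor,\qquad
f_{o,\min} = \begin{cases} 0.2\cdot\min(f_{o,\mathrm{iEGG}},
f_{o,\mathrm{audio}}) & \text{quasi-periodic (group 1)}\\
20\ \mathrm{Hz} & \text{irregular (group 2)}\end{cases}$$

so a window spans about five periods of the slower oscillator (group 1)
or 1000 samples at 20 kHz (group 2). $F_s/f_{o,\min}$ is generally not an
integer; we floor it. The per-channel fo entering the rule is the task
mean over voiced frames.

Numerical choices:

* **What is band-pass filtered.** "Band-pass filtered, windowed PS" is
  ambiguous between filtering the inputs and filtering the PS series. We
  filter the *inputs* (zero-phase forward–backward 4th-order Butterworth)
  before the Hilbert transform, because the analytic-phase construction
  is only meaningful for near-monocomponent signals (Bedrosian
  condition); the corner frequencies default to
  $[0.5 f_{o,\min},\ \min(10 f_{o,\mathrm{ref}},\ 0.45 F_s)]$ and are
  configurable, since no canonical values exist. Filtering can be
  disabled (`bandpass = NA`).
* **Edges.** The first and last 2% of samples are excluded from window
  statistics; the analytic signal is computed by FFT and distorts near
  the boundaries.
* **Hop.** Windows are non-overlapping by default (`hop = Nwin`).
* **Silence.** A window where either channel is numerically silent
  (e.g. the SAW is zero because no supraglottic oscillation is visible)
  has no phase; it is reported as `NA`, never as 0, so missing windows
  cannot masquerade as integer-ratio locking.
* Quantiles are type-7 (R default); the bounds $q_{25} \le$ median
  $\le q_{75}$ and PS $\in [-1, 1]$ are enforced by class validity.

## fo tracking

`estimateFo` is a YIN-family estimator: per frame the difference
function is computed via FFT cross-correlation, normalized by its
cumulative mean (CMNDF), and the first dip under an absolute threshold
(default 0.15), refined by parabolic interpolation, gives the period.
Frames whose CMNDF minimum exceeds 0.35 are unvoiced — for a noise-only
frame the CMNDF hovers near 1 with relative fluctuations of a few
percent, so the rule is sharp in practice. Voiced estimates are median
smoothed (5 frames) to suppress octave errors. A fully probabilistic
multi-threshold variant with Viterbi smoothing would present the same
interface; the simpler estimator is used because every accuracy property
we require of it (1% on clean tones, no octave errors at SNR ≥ 30 dB,
full unvoiced decisions on silence) is met and it keeps the per-frame
cost at one FFT.

Note one deliberate semantic: for a period-doubled pulse train (cycle
amplitudes alternating strongly), the *true* period is the doubled one,
and the estimator reports fo/2 — as any period-based method does. The
glottal cycle rate is then read from the GAW channel, which does not
carry the alternation; the pipeline uses GAW (when present) as the
glottal reference for ratio estimation for exactly this reason.

## Spectral detectors

All detectors operate on Hann-window STFT magnitudes (default window
2048 samples ≈ 9.8 Hz bins at 20 kHz — enough to separate 68 from
136 Hz and to localize jumps of a few Hz in time).

* **Subharmonics** (`detectSubharmonics`): a spectral peak near $f_o/k$
  ($k = 2..4$ by default) whose magnitude exceeds 5% of the $f_o$ peak.
  The candidate must be a genuine *local maximum*: the mainlobe skirt of
  a strong neighbouring component rises monotonically and is thereby
  rejected. The 5% threshold detects low-intensity period-doubling
  sidebands while firing on < 5% of clean periodic scenes; it is a
  package decision, configurable.
* **Frequency jumps** (`detectFrequencyJump`): medians of two flanking
  100 ms windows separated by at most 50 ms must differ by ≥ 5 Hz *and*
  both flanks must be plateaus (internal IQR ≤ max(1 Hz, 25% of the
  step)). The plateau condition is what distinguishes a jump from a
  glissando, whose flanking medians also drift apart.
* **Biphonation** (`detectBiphonation`): the peaks of a frame must form
  exactly two harmonic families; their fundamental ratio $r$ is compared
  against all $p/q \le 8$ with tolerance $0.05/q^2$. The $1/q^2$ scaling
  is the natural rational-approximation noise scale: it accepts a noisy
  2:1 as harmonic while keeping the golden ratio (whose best small
  approximant is 8/5, off by 0.018 > 0.05/25) biphonic. Frames with
  more than two families (broadband, chaotic) are deliberately *not*
  flagged: biphonation means two components, not many.
* **Periodicity index** (`periodicityIndex`): per window, the maximum of
  the bias-corrected normalized autocorrelation over lags ≥ one expected
  period. Near 1 for entrained scenes, ≈ 0.04 for white noise at the
  default window, and well below the locked value for chaotic scenes.

## Oscillation ratio and regime

`estimateRatio` forms the mean-fo ratio (orientation: glottal over
supraglottic), takes the nearest integer $n \le 8$, and accepts it when
the relative residual is ≤ 8% — enough to separate 2:1 from 3:2 at
phonatory frequencies. Confidence decreases linearly with the residual
and is damped by the within-track coefficient of variation, so
incommensurate (biphonic) pairs and unstable tracks score low. Swapped
inputs are reported as `orientation = "inverted"` with $n$ computed from
the reciprocal. `trackRatio` applies this per window and reports
change-points, e.g. the 2:1 → 3:1 transition when a glottal glissando
runs against a fixed supraglottic natural frequency.

`classifyGroup` labels a recording group 1 when the mean periodicity
index ≥ 0.7 *and* the ratio confidence ≥ 0.6 (both thresholds are
package decisions calibrated on synthetic scenes, not literature
values); otherwise group 2, split into 2a/2b by the `glottisVisible`
flag. Visibility is an endoscopic judgement, so it is an explicit input,
never inferred from the images.

## The synthetic scene generator

`makeCoupledScene` is first-class, tested code: it is the ground-truth
source for every downstream stage. A scene has a glottal pulse-train
oscillator (raised-cosine pulses, open quotient 0.5 by default —
band-limited and EGG-like), and a supraglottic oscillator that is

* **locked**: phase = glottal phase / n + fixed offset, so entrainment
  survives glissandi and jumps exactly;
* **drifting**: ±3% slow sinusoidal detuning of the derived fo;
* **biphonation**: fo divided by $n + 0.618$, an irrational ratio;
* **chaotic**: cycle lengths jittered ±20% by a logistic map at $r = 4$,
  with per-cycle amplitude (0.2–1.2) and pulse width (open quotient
  0.3–0.7) driven by two further logistic streams. Cycle-length jitter
  alone leaves adjacent raised-cosine pulses with ≈ 0.6 overlap
  correlation; an aperiodic regime is irregular in amplitude and shape
  as well, and with all three driven chaotically the autocorrelation at
  every lag ≥ one period stays below 0.5 (verified by a brute-force
  oracle in the tests).

Channels: GAW = clean glottal train; SAW = supraglottic train; iEGG =
glottal train with pulse amplitudes reduced by `subharmonicDepth` on
cycles not aligned with the supraglottic cycle start (a simple
multiplicative model of the contact-modulated EGG; at ratio 2 this is
exactly period-doubling amplitude alternation); audio = 0.7 × modulated
glottal + 0.3 × d(SAW)/dt, each max-abs normalized before weighting.
The mixing weights are free parameters, not physiological claims; no
published value exists for the relative acoustic contribution of the two
sources. The modulated (not clean) glottal train enters the audio so
that period-doubling reaches the acoustic channel, as observed in real
undertone phonation. Gaussian noise at the configured SNR is added
independently per channel; all randomness flows from the scene seed
through a local RNG, so identical specs give bit-identical channels.

Rendering (`renderFrames`) draws a central glottal ellipse inside an
annular supraglottic region. For a fixed ellipse shape, a pixel is
inside the scaled ellipse iff its elliptical radius is below the scale,
so sorting pixels once by that radius lets every frame realize the
*exact* requested integer pixel area; the centre is offset from the
pixel grid by an irrational-ish amount so radii are generically distinct
and regions grow one pixel at a time. Brightness levels (background <
supraglottic < glottal by default) are configurable but must be
distinct. Frames are rendered at the signal rate (frame = sample),
matching the acquisition convention of 20 000 fps at a 20 kHz channel
rate; tests and examples use small frames (≈ 64–128 px) and short
scenes to keep stacks light, since region geometry is scale-free.

What the generator does **not** emulate: tissue texture, illumination
gradients, specular highlights, motion blur, mucosal-wave phase
structure within a cycle, endoscope motion, or any aerodynamic/mass-
spring physics of the coupling. Passing tests therefore demonstrate the
correctness of the *measurement chain* (segmentation recovers rendered
areas; PS recovers constructed phase relations; detectors fire on
constructed phenomena at calibrated rates) — they do not certify
performance on in vivo imagery, where contrast and artefacts dominate
segmentation quality.

## Segmentation

`segmentArea` applies an affine contrast map (clipped to [0, 1]),
binarizes pixels whose grey value lies in
`[greyThreshold, greyCeiling]` within a ROI, labels 4-connected regions,
discards regions smaller than `minRegionPx` (default 5 px, a despeckle
rule), and sums the remaining areas — by construction the SAW aggregates
multiple vibrating areas. The upper bound `greyCeiling` (default 1, i.e.
inactive) is the mechanism that "suppresses" the glottal level in a
supraglottic profile: with a clipped affine map alone, no monotone
contrast setting can remove a brighter region while keeping a dimmer
one. The bright-is-open polarity of the synthetic fixtures is a
convention; endoscopic images often show the glottis dark, which the
affine map with negative gain accommodates. Areas are integer pixel
counts; no sub-pixel estimation is attempted, consistent with the
uncalibrated nature of the data. Segmented areas are monotone
non-decreasing in a falling threshold (masks are nested, and despeckle
retention is inherited), a property the tests exercise.

In vivo contrast/threshold values are inherently per-recording; profiles
are free parameters, and the package ships no claimed defaults for real
footage.

## Problem sizes and budgets

The test-suite statistics use: ratio recovery over 50 seeds × n ∈ 1..7
at 20 dB SNR on 0.6 s scenes; detector false-positive rates over 100
clean periodic 0.6 s scenes; white-noise periodicity over 1 s windows;
PS anchors on 2 s signals at 20 kHz. These sizes give binomial error
bars comfortably inside the asserted bounds while keeping the full suite
under a minute of compute. The acceptance script uses 2 s, 40 000-sample
signals per anchor.

## Known limitations

* The fo estimator is plain YIN + median smoothing; torturous material
  (rapid alternations of voicing, creak against noise) would benefit
  from the full probabilistic variant behind the same interface.
* `detectBiphonation` reports at most two families per frame; triphonic
  material is treated as broadband.
* The group-1/2 classifier consumes two scalar features; it is a
  decision rule, not a statistical classifier, and its thresholds are
  calibrated on the synthetic regimes only.
* EGG/audio/frame channels are assumed simultaneously triggered
  (t0 = 0); a per-channel offset option exists but no automatic
  synchronization correction is attempted.
* n:1 locking only: rational p:q locking with p, q > 1 is outside the
  ratio estimator's model (the biphonation detector's p/q test is the
  only place such ratios appear).
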