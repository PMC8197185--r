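---
title: "Micro-Doppler gait classification: models, design choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Micro-Doppler gait classification: models, design choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(gaitdoppler)
```

## The measurement and the method

A continuous-wave micro-Doppler radar (24 GHz carrier, 600 Hz baseband
sampling) observes a person walking toward it. After coherent demodulation,
the echo of $N$ point scatterers is the complex baseband signal

$$ s_R(t) = \sum_{i=1}^{N} \eta_i A\, e^{j\phi_i(t)}, \qquad
   \phi_i(t) = -\frac{4\pi R_i(t)}{\lambda}, $$

where $R_i(t)$ is the radial range of scatterer $i$, $\eta_i \le 1$ its
amplitude ratio, and $\lambda = c/f_0$ the carrier wavelength. A scatterer at
radial velocity $v$ shifts the carrier by the Doppler frequency
$f_d = 2v/\lambda$ (160.11 Hz per m/s at 24 GHz), so the short-time Fourier
transform of $s_R$ — a Hamming window of 128 samples, hop 8 samples — is a
time–velocity map after relabelling the frequency axis with
$v = f_d \lambda/2$. The velocity resolution is
$(f_s/L)\,\lambda/2 \approx 0.0293$ m/s and the unambiguous (Nyquist)
velocity $(f_s/2)\,\lambda/2 \approx 1.87$ m/s.

Three per-frame summaries reduce the spectrogram to velocity time series:

* the **mean envelope** $v_m(t)$, the power-weighted mean velocity over the
  full axis — it tracks the torso, the dominant scatterer;
* the **significant peaks**: local maxima of the per-bin amplitude whose
  amplitude exceeds $\rho \cdot \max_v |S_R(t,v)|$ with $\rho = 0.2$;
* the **upper and lower envelopes** $v_u(t), v_l(t)$: the largest and
  smallest significant-peak velocities — the swinging leg and the planted,
  stance-phase leg.

The analysis interval is two steady-state gait cycles, centered in the
recording; with the default hop this yields sequences of roughly 100–220
frames whose length varies with the walker's cadence. The sequences (any of
seven combinations of the three envelopes) feed a sequence-to-label LSTM —
sequence input, LSTM layer, fully connected layer, softmax over
{young, elderly} — trained with Adam, cross-entropy, and per-batch zero
padding to the batch maximum, without masking. A hold-out protocol (7:3
split, repeated trials, per-condition accuracy and pooled confusion
matrices) evaluates each input condition, alongside an RBF-SVM baseline on
twelve summary velocity parameters (mean, population SD, max, min of each
envelope).

## What the simulator emulates

Real cohort recordings of this kind are not publicly available, so the
package ships a parametric simulator whose output stands in for them. A
walker is five point scatterers: torso ($\eta = 1$), two tibiae
($\eta = 0.10$) and two feet ($\eta = 0.22$).

* **Torso** — walking speed $S$ plus a triangular within-cycle oscillation
  (amplitude 0.30 m/s, two oscillations per cycle, phase-locked to the
  footfalls).
* **Feet** — each cycles through stance (slow "tent" profile: 0.03 m/s at
  both ends, rising mid-stance to the class's stance-phase velocity scale),
  a cosine-ramped swing plateau at the swing peak velocity, and a
  terminal-swing hover back at the base level. Left and right are half a
  cycle apart, so a slow foot is always present — the planted-leg return
  that anchors $v_l$.
* **Tibiae** — the kinematic midpoint of torso and foot, the intermediate
  micro-Doppler band of a shank.

Class-conditional defaults (configuration values of this artifact, not
measured effect sizes of any cohort): young walk at $1.3 \pm 0.10$ m/s with
swing peaks $1.7 \pm 0.10$ m/s, cycles of $1.05 \pm 0.05$ s, stance duty
0.40 and stance velocity scale 0.10 m/s; elderly at $1.0 \pm 0.15$ m/s,
swing peaks $1.4 \pm 0.10$ m/s, cycles $1.15 \pm 0.05$ s, a longer stance
duty 0.44 and a flatter stance velocity scale 0.04 m/s. The pattern — gait
slowing, lower swing-velocity peaks, longer cycles and stance, reduced
stance-phase foot dynamics — is the aging signature reported across the
gait-biomechanics literature; the numbers themselves are plausible
placeholders exposed through `gait_default_config()` and the YAML config
file, and nothing downstream depends on their exact values.

```{r}
cfg <- gait_default_config()
params <- sample_class_params("elderly", rng_seed = 1, config = cfg)
traj <- simulate_walker(params, n_cycles = 5, rng_seed = 2)
signal <- synthesize_baseband(traj, noise_sd = 0.05, rng_seed = 3)
spec <- select_analysis_interval(compute_spectrogram(signal))
env <- extract_envelopes(spec, rho = 0.2)
autoplot(spec)
autoplot(env)
```

### Why the waveforms look the way they do

The simulator's waveform shapes were chosen for their spectral behaviour
under the relative peak threshold, not only their kinematics; several are
deliberate deviations from the "obvious" textbook shapes.

**The mean-envelope bias budget.** The power-weighted mean velocity sits
below the torso speed by

$$ \Delta v_m \approx \frac{\sum_{legs} \eta_i^2\,(S - \bar v_i)}
   {1 + \sum_{legs} \eta_i^2}, $$

because legs average slower than the torso over a cycle (a foot that kept up
with a 1.3 m/s torso would need swing peaks beyond the Nyquist velocity, so
displacement-consistent feet are impossible at this sampling rate). Leg
reflectivities must therefore stay small for $v_m$ to recover the torso
speed to a few percent: with the defaults the bias is 3–4%.

**Foot visibility against the torso.** For $v_u$ and $v_l$ to track the
legs, foot echoes must exceed $0.2$ of the frame's maximum amplitude, which
is set by the torso. A sinusoidal torso oscillation concentrates into a
near-single-bin tone twice per step (a fold caustic of the velocity
turnaround), raising the threshold above any foot weak enough to satisfy the
bias budget; the triangle oscillation's constant slew keeps the torso ridge
smeared across ~10 bins in every window. Likewise, the stance-foot profile
keeps the planted foot a near-tone (slew below ~0.2 m/s²), both dwell edges
sit at a common base level so hand-overs between the two feet look alike,
and a small end wiggle de-correlates the two feet's echoes so they cannot
cancel coherently when both are slow.

**Exact dwell tiling.** The two requirements — feet weak for $v_m$, feet
strong for detection — pinch hardest at frames whose window straddles a
slow-foot hand-over, where each foot contributes only a partial-window
tone. Two structural choices dissolve the pinch. First, the slow spans of
the two feet tile the cycle *exactly* (the swing pulse occupies precisely
half a cycle): overlapping dwells would put two slow feet in the same
window right at the hand-over, doubling the slow-leg deficit of $v_m$ there
and splitting the anchor energy between two mutually coherent tones.
Second, the hand-over instants are phase-locked away from the torso
oscillation's extrema, so the threshold at those frames is set by the
smeared mid-sweep ridge. With both in place, the ordering
$v_l \le v_m \le v_u$ holds to one velocity bin at every frame across
hundreds of simulated walkers at all tested noise levels — a property the
test suite asserts on 50 walkers. Designs with overlapping dwell spans or
sinusoidal torso fluctuation measurably violate it on 0.1–1% of frames.

**Sampling.** Per-participant draws use truncated normal distributions,
symmetric about the class mean (so configured means are preserved) and
capped so that no achievable radial velocity can alias; the swing-peak draw
is floored at the realized torso band so the upper envelope always has a
swing leg to track, which skews swing peaks slightly upward for the fastest
walkers.

### What passing tests do and do not show

The simulator produces the morphology the method consumes — a torso band
with leg flashes, class-dependent envelope structure, realistic sequence
lengths — with exactly known ground truth, which is what the recovery,
ordering and classification tests exercise. It does **not** emulate arm
swing, multi-path or clutter, site-dependent noise spectra, range-dependent
attenuation, body-size differences between cohorts, or within-class gait
pathologies. Classification accuracies on simulated cohorts therefore
validate the pipeline's mechanics (envelope extraction preserves the class
signal; the LSTM can exploit it; the protocol arithmetic is right), and
must not be quoted as expected field performance on real recordings.

## Numerical and procedural choices

* **STFT**: symmetric Hamming coefficients $0.54 - 0.46\cos(2\pi n/(L-1))$,
  unnormalized forward DFT (per-frame Parseval constant $L$), center-aligned
  frames with edge frames dropped, velocity axis spanning
  $(-f_s/2, f_s/2]$ in Doppler with motion toward the radar positive.
* **Hop**: 8 samples (75 frames/s), so two gait cycles give ~150 frames,
  inside the 99–224 range the method was designed around. Configurable.
* **Cycle estimation**: the per-frame total power of a multi-scatterer echo
  is nearly constant (each scatterer contributes its full power to every
  frame regardless of spectral smear), so periodicity is read from the
  lagged correlation of mean-subtracted spectrogram columns. Its first
  significant peak is the *step* period — the left/right-symmetric walker
  makes the step the fundamental — and the gait cycle is two steps. The
  degenerate constant-velocity case has no periodicity and errors, advising
  a manual interval.
* **Peak rule**: a discrete local maximum is a bin strictly greater than
  both neighbours; a plateau counts once at its leftmost bin; array
  endpoints are ineligible. The threshold applies to amplitude $|S_R|$, not
  power. Frames with no significant peak carry the previous frame's
  $v_u/v_l$ forward (gap-free sequences for the classifier); an empty first
  frame is an error.
* **LSTM**: gates in input/forget/output/candidate order, Glorot-uniform
  initialization with the forget bias at $+1$, global gradient-norm clipping
  at 5, Adam ($\beta_1 = 0.9$, $\beta_2 = 0.999$). Full-scale defaults
  follow the method description (400 hidden cells, batch 128, learning rate
  $10^{-4}$ attenuated by 0.9 every 30 epochs); `max_epochs = 150` is this
  package's choice (no stopping rule is prescribed anywhere), long enough
  that the decay schedule executes meaningfully. Zero-padding is per batch
  to the batch maximum without masking; inference is always per-sequence
  and unpadded, so predictions cannot depend on batch grouping. Ties in the
  softmax break toward the first label (young).
* **Desk scale**: simulated experiments in the tests and the reproduction
  script use `lstm_config_test_scale()` — 64 hidden cells, batch 32,
  learning rate $10^{-3}$, 40 epochs, channel standardization on — sized
  for cohorts of ~300 two-cycle sequences. Standardization is part of this
  reduced configuration because the lower envelope lives on a ~0.05 m/s
  scale: a small network given a few hundred Adam updates cannot rescale it
  internally, while the full-scale configuration keeps raw velocities in
  m/s as the method describes. Simulation sizes used by the suite: 50
  walkers for the ordering invariant, 20 for parameter recovery, an 87/213
  cohort with 5 hold-out trials for classification, 40/40 with 10 paired
  trials for the stance-phase contrast.
* **Hold-out protocol**: stratified 7:3 splits by largest-remainder
  allocation (300 recordings split into exactly 210 + 90, with 61/149 young
  per part), one fresh training per trial, per-trial seeds derived from the
  master seed so different conditions see identical splits (paired
  comparisons), confusion matrices row-normalized with rows = predicted
  class. Whether the original protocol stratified its splits or retrained
  per trial is not documented; both choices here are explicit and logged.
* **SVM baseline**: the twelve-parameter feature set (mean, population SD,
  max, min of each envelope) is this package's concretization of a
  "simple parameters" baseline; the historical parameter list is not
  enumerated anywhere, so agreement with it should not be assumed. Features
  are standardized with training-set statistics; cost and gamma come from an
  internal stratified cross-validated grid, logged in the fitted object.

## Known limitations

* The five-scatterer kinematic model is stylized; see the trade-off
  discussion above for the one place it shows (isolated lower-envelope
  excursions at step transitions).
* The mean envelope is intrinsically biased low by leg power (3–4% of the
  torso speed at the shipped reflectivities); treat `mean(v_m)` as a
  slightly conservative torso-speed estimate.
* Training reads the hidden state at the padded batch end (no masking), but
  inference reads the true final frame; this mirrors the described training
  scheme literally, and with the shipped configurations the mismatch has no
  measurable accuracy cost, but `masking = TRUE` is available.
* Simulated class separability is far cleaner than field data; hold-out
  accuracies near 1.0 on default cohorts say nothing about accuracy on real
  radar recordings.
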