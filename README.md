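# gaitdoppler

Radar-based gait analysis for aging research: simulate, process and classify
micro-Doppler recordings of walking people.

Fall risk in older adults correlates with age-related gait changes, and a
continuous-wave micro-Doppler radar can observe gait remotely — no markers,
no cameras, no lighting or clothing constraints. This package implements the
full analysis chain for classifying young versus elderly gait from such
recordings, together with a parametric cohort simulator that provides
ground-truth data where real cohort recordings are unavailable. It is aimed
at researchers prototyping radar gait pipelines and at anyone wanting a
transparent, fully testable reference implementation of the method.

## The method

A 24 GHz radar samples the demodulated echo of a walker at 600 Hz. The
complex baseband signal of N point scatterers is

    s_R(t) = Σ_i  η_i A exp{ -j 4π R_i(t) / λ },

and a scatterer at radial velocity v appears at the Doppler frequency
f_d = 2 v / λ. A short-time Fourier transform (Hamming window of 128
samples) turns the signal into a time-velocity spectrogram |S_R(t, v)|²,
from which three velocity time series are extracted per frame:

* `v_m(t)` — power-weighted mean velocity (first moment over the velocity
  axis): the torso;
* `v_u(t)` — the largest *significant-peak* velocity: the swinging leg;
* `v_l(t)` — the smallest: the planted, stance-phase leg;

where a significant peak is a local amplitude maximum exceeding ρ = 0.2 of
the frame's maximum amplitude. A steady-state two-gait-cycle interval of
these envelopes (sequence length varies with cadence, roughly 100–220
frames) feeds a sequence-to-label LSTM — sequence input → LSTM layer (400
hidden cells at full scale) → fully connected → softmax over
{young, elderly} — trained with Adam (batch 128, initial learning rate 1e-4
attenuated ×0.9 every 30 epochs) and per-batch zero padding. Seven input
conditions (each subset of {v_u, v_m, v_l}) are compared under a repeated
7:3 hold-out protocol, against an RBF-SVM baseline on twelve summary
velocity parameters.

## Worked example

Simulate a small labeled cohort, extract envelope sequences, and run a
paired comparison of two input conditions and the SVM baseline at the
package's documented desk scale:

```r
library(gaitdoppler)

ds   <- make_dataset(n_young = 30, n_elderly = 30, rng_seed = 1)
prep <- prepare_sequences(ds)
range(prep$n_frames)
#> [1] 144 180

cmp <- compare_conditions(prep, conditions = c(2, 3, "svm"),
                          n_trials = 5,
                          config = lstm_config_test_scale(),
                          master_seed = 7)
cmp[, c("condition", "mean_accuracy", "sd_accuracy")]
#> # A tibble: 3 × 3
#>   condition mean_accuracy sd_accuracy
#>   <chr>             <dbl>       <dbl>
#> 1 2                 0.867      0.0497
#> 2 3                 0.989      0.0248
#> 3 svm               1          0
```

Each row is the mean held-out accuracy over 5 stratified 7:3 hold-out
trials; all conditions see identical splits, so the rows are directly
comparable. Condition 2 feeds only the mean envelope `v_m` (the torso:
walking-speed information), condition 3 only the lower envelope `v_l` (the
stance-phase leg) — on this simulated cohort the default class differences
(speed, swing peaks, cycle duration, stance-phase structure) make all three
classifiers strong, with the stance-phase envelope the most informative
LSTM input. `report` (a list column) holds the full per-trial logs and
pooled confusion matrices:

```r
cmp$report[[2]]
#> <gait_eval> condition 3: mean accuracy 0.989 over 5 trial(s) (split 70:30)
#> confusion (% within predicted class; rows = predicted, cols = true):
#>          true
#> predicted young elderly
#>   young    97.8     2.2
#>   elderly   0.0   100.0
```

Single recordings follow the same verbs:

```r
p    <- sample_class_params("elderly", rng_seed = 42)
sig  <- synthesize_baseband(simulate_walker(p, n_cycles = 5, rng_seed = 43),
                            noise_sd = 0.05, rng_seed = 44)
spec <- select_analysis_interval(compute_spectrogram(sig))
env  <- extract_envelopes(spec, rho = 0.2)
autoplot(spec)   # time-velocity power map
autoplot(env)    # the three envelope series
mean(env$v_m)    # ~ the walker's torso speed (a few % low; see vignette)
```

A thin command-line interface (`exec/gaitdoppler`) exposes the same steps as
`simulate | spectrogram | envelopes | train | evaluate` subcommands for
shell pipelines.

## Documentation

The methods vignette (`vignettes/gait-classification-methods.Rmd`) describes
the signal model, the envelope definitions, the simulator's kinematic design
and its spectral rationale, all numerical choices, and known limitations —
including exactly what accuracies on simulated cohorts do and do not say
about real recordings.
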