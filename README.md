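# runpause

Simulation and analysis of live-cell single-molecule imaging of
minus-end-directed motor proteins (dynein) and the endosomal cargo they
move. The package addresses a concrete experimental question: when single
motors bind the microtubule for well under a second at a time, how do those
brief encounters produce reliable long-range cargo transport — and how do
you measure all of that from noisy time-lapse movies?

It is written for quantitative cell biologists doing single-particle
tracking: it provides both a ground-truth-carrying stochastic simulator of
the experiment and the complete analysis chain one would run on real data.

## The model and statistics at its core

* **Motor binding kinetics.** Binding events reside on the microtubule for
  exponential times, `tau ~ Exp(r_off)`; the survival curve
  `S(tau) = exp(-lambda tau)` is fit to `1 - CDF`, and the off-rate is
  `r_off = 1/tau_res` (0.59 s mean residence gives 1.7 s^-1).
* **Track classification.** Tracked particles are stationary, minus- or
  plus-end directed by their net displacement relative to a nucleus
  (minus-end) reference, with a 0.32 um threshold = 80 nm tracking error
  x 4 frames.
* **Run/pause segmentation.** Per-frame axial steps under 20 nm are zero;
  >= 4 consecutive same-direction steps form a run, >= 2 zero steps a
  pause; cargo motion is a semi-Markov alternation of ~0.6 s runs and
  0.4-0.6 s pauses.
* **Fluorophore counting.** Spot intensity histograms are fit by a
  two-Gaussian mixture with shared sigma and constrained means
  (`mu2 ~ 2 mu1` for a GFP dimer), separating one- from two-fluorophore
  molecules.
* **Supporting fits.** MSD (`<x^2> = 4Dt + c`), exponential photobleach
  decay, object-based colocalization with a flipped-channel chance
  control, and Fisher exact 2x2 comparisons by direct hypergeometric
  summation.

## Worked example

Simulate 5,000 microtubule binding events at the measured off-rate, fit
the residence survival curve, and convert to an off-rate; then simulate a
cargo vesicle and segment its trajectory:

```r
library(runpause)

ev  <- sample_binding_events(motor_params(off_rate = 1.7), 5000, seed = 2)
fit <- fit_residence_survival(ev$duration_s, n_bootstrap = 200, seed = 3)
fit
#> Exponential residence fit (survival_lsq, n = 5000)
#>   off-rate lambda = 1.71 /s, mean residence = 0.585 s
#>   mean residence CI: 0.566-0.602 s

cargo <- simulate_cargo_trajectory(dextran_cargo_params(), duration = 100,
                                   frame_interval = 0.1, seed = 7)
seg <- segment_motion(cargo$trajectory, nucleus_ref(0, 0))
segment_velocities(seg)
#>        kind  n mean_velocity_um_s sd_velocity_um_s mean_duration_s
#> 1 run_minus 17           1.254771        0.4867745        1.247059
#> 2  run_plus 27           1.457414        0.5065459        1.070370
```

The survival fit returns the unbinding rate (1.71 /s against a generating
1.7 /s, CI 0.566-0.602 s on the mean residence) and the segment table the
per-kind run velocities, close to the generating 1.2 um/s. Detected run
durations exceed the generating 0.59 s mean because the four-step minimum
censors short runs and sub-frame pauses merge adjacent runs -- estimator
properties discussed in the vignette. An end-to-end driver,
`run_tracking_experiment()`, renders binding events into synthetic HILO
movies, re-detects and links them, classifies the recovered tracks and
refits the off-rate — the full pipeline against known ground truth.

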