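---
title: "Single-molecule motor kinetics and cargo run-pause analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-molecule motor kinetics and cargo run-pause analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(runpause)
```

## The system being modelled

Cytoplasmic dynein is the dominant minus-end-directed microtubule motor.
In living cells single fluorescently tagged dynein molecules bind the
microtubule (MT) from the cytoplasm, reside on it for well under a second,
and unbind again; only a minority of binding events produce a directed run.
Endosomal cargo (dextran- or EGF-loaded vesicles), together with the
dynactin complex and a cargo adaptor, stays tethered near the MT, and a
cargo run starts when a diffusing motor lands next to such a complex and
ends when the motor unbinds. Long-range transport toward the perinuclear
region is the accumulation of many such short runs separated by pauses.

`runpause` implements that picture twice over: as a stochastic generator
(so every analysis can be validated against known ground truth) and as the
analysis chain used on real single-particle data — spot detection and
linking, track classification against a nucleus reference, run/pause
segmentation, kinetic curve fits, object-based colocalization, and
population transport summaries.

## The generative model

### Motor binding events

Binding events are i.i.d.: a residence duration $\tau \sim
\mathrm{Exp}(r_\mathrm{off})$ with $r_\mathrm{off} = 1.7\,\mathrm{s^{-1}}$
(mean residence $0.59\,\mathrm{s}$), and a behavioural class drawn from the
(stationary, minus, plus) mixture $(0.5, 0.3, 0.2)$. Moving events advance
at a speed drawn once per event from a normal truncated at zero
($1.2 \pm 0.7\,\mathrm{\mu m/s}$ minus-ward, $1.1 \pm 0.7$ plus-ward), so
runs appear as straight lines in kymographs. Localization noise
(default $0.08\,\mathrm{\mu m}$ per frame, the tracking error from which
the classification threshold derives) is added independently per frame.

One modelling decision deserves emphasis. The whole-track classifier calls
an event "minus" only when its net displacement exceeds
$0.32\,\mathrm{\mu m}$. A short-lived event moving at a modest speed can
be genuinely minus-directed yet fall below that threshold, so class labels
and classifier output cannot both be exactly recoverable unless moving
events are required to clear the threshold. `simulate_dynein_tracks()`
therefore has an `enforce_class_consistency` flag (default `TRUE`): moving
events redraw duration and speed jointly until the noise-free net
displacement exceeds the threshold. This makes labels exactly recoverable
at zero noise, at a price: conditioning lengthens moving events, so the
pooled residence distribution is no longer $\mathrm{Exp}(1.7)$ (its mean
rises to roughly $0.72\,\mathrm{s}$). Analyses of classification fidelity
should use the default; analyses of residence kinetics should set the flag
to `FALSE`. The package's own validation does exactly that, one run per
question.

### Cargo trajectories

Cargo motion is a semi-Markov alternation pause → run → pause. Pauses are
the waiting times for a motor to arrive; runs terminate when the motor
unbinds, so the default run mean is $1/1.7 \approx 0.59\,\mathrm{s}$,
mirroring the motor off-rate. Pause means are 0.6 s (dextran-like) and
0.4 s (EGF-like); run direction is minus-ward with probability
`minus_bias`. A fraction of vesicles is immobile and, in the
MT-depolymerized control condition, diffuses with
$D = 0.003\,\mathrm{\mu m^2/s}$. Paused mobile vesicles are held static:
in the cells being modelled, vesicles stay within tens of nanometres of
the MT even without a motor tether, and treating tethered pauses as
diffusive at the nocodazole $D$ would add ~0.5 µm/min of spurious folded
net motion to minute-scale summaries.

The measured run/pause statistics do not constrain net transport: a vesicle
alternating 0.6 s runs and 0.6 s pauses at 1.2 µm/s would wander several
µm/min, while measured net speeds are 0.2 (dextran) and 0.5 (EGF) µm/min.
Those two observations are reconciled by the fraction of vesicles that
never run. `calibrate_immobile_fraction()` makes that calibration explicit:
it computes the expected absolute net displacement per minute of a mobile
vesicle by Monte Carlo over run sums and sets the immobile fraction so the
population mean matches the target net speed. Net-speed realism is thus
imposed by calibration, not an emergent prediction, and the package says
so rather than hiding the dial.

### Imaging

Movies emulate 50-fps HILO acquisition: each molecule is an isotropic 2D
Gaussian (sigma 1.3 px) whose amplitude is `photon_scale` per surviving
fluorophore, two fluorophores per dimer (one GFP per heavy chain), each
bleaching in a single step with exponential lifetime at
$0.17\,\mathrm{s^{-1}}$ (time constant 5.9 s). Poisson shot noise acts on
signal plus background and Gaussian read noise is added. Pixel size
(0.16 µm) and PSF sigma are package defaults for a typical 100×/EMCCD
setup, not measured values; the defaults give peak SNR ≈ 14 per
fluorophore, comfortably above the SNR ≥ 10 regime the tracking-fidelity
claims are made for.

## The analysis chain

### Detection and linking

Spots are local maxima of a difference-of-Gaussians response thresholded at
5 robust (MAD) noise units; centroids are intensity-weighted means in a
7×7 window after subtracting an annulus-median background; detections
closer than `2 * max_sigma` merge into the brighter one. Linking is greedy
nearest-neighbour per frame pair, resolved globally by ascending distance,
with links longer than `max_step` per elapsed frame rejected and gaps up to
`max_gap` frames bridged. Spots are canonically ordered before matching,
so linking is deterministic and invariant to input order. The reference
protocol this package emulates tracked manually identified events with an
interactive tool; this
module replaces that with an automatic detector/linker and validates it
only against synthetic ground truth.

Temporal sliding averaging (`sliding_average()`, centred and
boundary-truncated) is available for low-SNR data but is off by default in
`track_movie()`: averaging smears binding and unbinding edges and biases
apparent residences upward.

### Track classification and segmentation

The axial coordinate of a track is its change in distance to the nucleus
reference (minus-ward positive). Classification uses the net start-to-end
axial displacement with strict thresholds at ±0.32 µm (80 nm tracking
error × 4 frames); ties are stationary. Segmentation symbolizes each
between-frame step as zero (|axial step| < 20 nm), minus- or plus-ward;
maximal stretches of ≥ 4 same-direction steps are runs, ≥ 2 zero steps are
pauses, and everything shorter is "undetermined" and excluded from
statistics — neither runs nor pauses are padded with ambiguous steps. The
20 nm test is applied to the axial (nucleus-projected) step because the
run definition is directional; a 2D-magnitude mode is available as
configuration. A run is terminated by any zero or contrary step.

Two measurement properties of these rules are worth knowing. First, with
exponential dwells the ≥ 4-step rule left-censors the run distribution:
detected runs are conditioned on lasting ≥ 4 frames, and by memorylessness
their mean exceeds the generating mean by roughly the 4-frame minimum;
sub-frame pauses are likewise invisible, merging same-direction runs.
These are properties of the estimator, not bugs, and the tests assert them
as directional facts (detected runs only lengthen, counts only shrink).
Second,
when a dwell boundary falls inside a frame interval the boundary step
usually inherits the run's direction, transferring about half a frame from
each flanking pause to the run. Parameter-recovery checks therefore use
fixed dwells on the nominal 0.1 s frame grid of the long-term imaging
(where boundaries align and recovery is exact) with deterministic run
speed, so the only residual error is trace-edge truncation.

### Kinetic fits

* **Residence survival.** The empirical survival curve $S(\tau) = 1 -
  \mathrm{CDF}$ is fit by $e^{-\lambda\tau}$ (least squares), or
  $\lambda = 1/\bar\tau$ by maximum likelihood; both agree for exponential
  data and the package asserts it. Confidence intervals are percentile
  bootstrap (no single interval convention is standard for this fit, so the
  package picks one and names it). The off-rate is $1/\tau_\mathrm{res}$.
* **Intensity mixture.** Spot intensity histograms (Freedman–Diaconis bins)
  are fit by $w\,N(\mu_1,\sigma) + (1-w)\,N(\mu_2,\sigma)$ with a shared
  $\sigma$ and box constraints on the means (defaults 15–30 and 35–50 in
  camera units; the bounds are instrument-specific and rescale with the
  data). A second-component weight below 0.02 flags an effectively
  single-Gaussian sample.
* **MSD.** Ensemble time-averaged 2D MSD, inverse-variance weighted linear
  fit of $\langle x^2 \rangle = 4Dt + c$ over lags up to 25% of the trace
  length; the intercept absorbs localization error as $c \approx
  4\sigma_\mathrm{loc}^2$.
* **Bleach decay.** $A e^{-\lambda_b t}$ on the ensemble mean trace, no
  offset term; a non-decaying mean is flagged with an infinite time
  constant.

When tracking rendered movies, residences are estimated as
$\hat T = (m - \tfrac12)\,\Delta t$ for a track seen in $m \ge 2$ frames,
and the off-rate as $1/(\overline{\hat T} - \Delta t)$ — the memoryless
correction for the 2-frame minimum track length. The residual bias of the
full rendered pipeline is a few percent (bleach censoring plus occasional
collision-induced track splits); at the 300-track scale of the validation
runs the sampling standard error of the off-rate is itself about 6%.

### Object-based colocalization

The reference channel is thresholded (top-5% of intensity, or IsoData on a
256-bin histogram to half-bin convergence), 8-connected components of at
least 4 pixels are counted as $N_\mathrm{ref}$, the other channel is
intensity-masked by the reference mask ("AND"), re-thresholded, and its
surviving components counted as $N_\mathrm{joint}$; the co-occurrence
percentage is $100\,
N_\mathrm{joint}/N_\mathrm{ref}$. Because joint spots are re-thresholded
objects, $N_\mathrm{joint}$ is not formally bounded by $N_\mathrm{ref}$.
The re-threshold of the AND image deserves one caveat: IsoData always
splits a histogram, so applied blindly to the in-mask values it would carve
pure background noise into spurious objects whenever no true joint signal
is present. The joint threshold is therefore floored at the other
channel's own global threshold — a joint spot must be at least as bright
as what counts as signal anywhere in that channel — and for the
top-percent method the channel-wide quantile is used directly, since the
mask is itself a quantile selection. A mask∩mask mode is provided as an
alternative. The chance level is
estimated by mirroring the reference channel left-right
(`flipped_channel_control()`). Per-cell mean ± SD and pooled-count
percentages are both reported, because the two conventions genuinely
differ and published figures do not always say which one they use.

### Transport summaries

Motile fraction (tracks exceeding a net displacement within a window), net
speed (absolute net axial displacement over 60 s, in µm/min), delivery
time (distance/net speed, default 10 µm to a perinuclear lysosome), and a
2×2 Fisher exact test implemented by direct hypergeometric summation
(`ad/bc` odds ratio; the 2×3 Freeman–Halton case delegates to the standard
routine). Population comparisons of the three-class behaviour default to
minus-vs-rest 2×2; the full 2×3 test is available.

## Numerical choices and degenerate inputs

* One top-level seed per simulation; per-unit sub-seeds derive through
  multiplicative (Lehmer-style) mixing so nested splits never collide, and
  every generator is bit-reproducible for a fixed seed.
* Strict inequalities at the classification threshold; exact ties are
  stationary. A constant image under top-percent thresholding keeps every
  pixel (tie rule); IsoData refuses constant images.
* Tracks need ≥ 2 frames for classification and residence, ≥ 3 frames
  (2 steps) for segmentation; shorter inputs are rejected with a reason.
* The truncated-normal speed draw rejects non-positive values; a zero-SD
  speed at a non-positive mean is an error.
* `fit_msd` clips negative slopes to $D = 0$; `fit_bleach_decay` reports an
  infinite time constant rather than a negative rate.

## Validation scales

The packaged validation runs use sizes chosen to make sampling error small
relative to the tolerances being asserted while staying desk-scale: 5,000
events for rate recovery, 800 × 100-frame tracks for diffusion, 5,000
samples for the mixture, 150 spot pairs per overlap level, and 300
rendered binding events (about 50 small movies) for the end-to-end
pipeline. At 300 tracks the off-rate carries ~6% sampling error, so the
10% end-to-end check is expected to fail for roughly one seed in ten —
that residual risk is inherent to the 300-event scale of the original
experiment rather than to the implementation.

## What the synthetic data does and does not show

The generator reproduces the statistical structure the analyses assume:
exponential residences, a three-class velocity mixture, two-fluorophore
intensity structure with single-step bleaching, semi-Markov run–pause
cargo motion, diffraction-limited spots over Poisson noise, and
channel pairs with a controllable co-occurrence fraction. It deliberately
omits MT network geometry, HILO illumination profiles, 3D defocus,
fluorophore blinking, motion blur within an exposure, and any correlation
between a motor's speed and its residence. Passing tests therefore
demonstrate that the analysis chain is correct and unbiased *under the
stated model*, not that the model captures every property of real
microscopy data; on real data the detector/linker parameters and the
intensity-mixture bounds in particular should be expected to need tuning.

## Known limitations

* The linker is greedy nearest-neighbour; it is validated at low density
  (≲ 0.02 spots/µm²) and will swap identities in dense fields.
* Colocalization recovery is validated on well-separated synthetic spots;
  clustered biological structures can merge under 8-connectivity.
* The run/pause rules quantize durations to the frame interval; at 0.1 s
  frames a 0.4 s pause is only four steps, so duration histograms carry
  visible discretization.
* Bleach-censored residences are only negligibly biased when the bleach
  time constant is an order of magnitude above the mean residence, as
  here; slower fluorophores or faster motors would need the censoring
  model, not the plain exponential fit.
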