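---
title: "Reference-free correction of hyperpolarization decay in 2D NMR"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reference-free correction of hyperpolarization decay in 2D NMR}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hyperwdecon)
```

## The problem

Dissolution dynamic nuclear polarization with hyperpolarized water (HyperW)
boosts protein NMR sensitivity by orders of magnitude: the hyperpolarized
solvent transfers polarization to backbone amides through proton exchange,
and a fast 2D experiment (a BEST-HMQC-type sequence) is recorded while the
polarization lasts. The price is paid along the indirect dimension. Every
t1 increment starts from a different reservoir polarization, so the
intrinsic indirect-dimension FID `I(t1)` of every resonance is multiplied
by a single exogenous envelope

    E(t1) = eps * exp(-R * t1),    S(t1) = E(t1) * I(t1)

where `eps` is the enhancement at `t1 = 0` and `R` the effective exogenous
decay rate on the t1 axis (typically around 450 1/s, i.e. 0.45 per ms, for
a 12.8 ms maximum evolution time). Multiplication by an exponential in
time is convolution with a Lorentzian in frequency: every line is broadened
by `R/pi` Hz along the indirect dimension, which at these rates destroys
residue resolution entirely.

Because the envelope is the *same* for all resonances -- the reservoir
decays with one rate, and for intrinsically disordered proteins the
intrinsic relaxation is nearly residue-uniform -- the envelope is a
recognizable common feature of every indirect-dimension trace. This package
estimates `R` directly from the recorded traces with a small neural
network, divides the time-domain data by `exp(-R * t1)` before the indirect
Fourier transform, and quantifies the recovered resolution and sensitivity.
No reference signal is required. The thermal offset of the envelope is
taken as exactly zero (the enhancement dwarfs thermal polarization); an
`offset` field exists in `decay_model()` for the small-enhancement regime.

## Data model

Data are States-hypercomplex: two complex matrices (cosine- and
sine-modulated components), `n_t1_complex x n_t2`. The exogenous decay is
phase-independent and multiplies both components identically. Roles
(`intrinsic`, `hyperpolarized`, `deconvolved`) track provenance, and
`apply_decay()` / `remove_decay()` are exact algebraic inverses on
noiseless data (verified to 1e-10 relative in the tests). `remove_decay()`
deliberately leaves the scalar `eps` in place: a global scale does not
affect line shape and keeping it preserves the sensitivity gain.

Rates are stored in 1/s on the t1 axis throughout; experimental reports
often quote 1/ms (0.45 1/ms = 450 1/s).

## The synthetic-data generator

`synthesize_intrinsic()` builds intrinsic interferograms as sums of damped
complex oscillations with per-resonance offsets, decay rates, amplitudes,
and an amide proton exchange rate `kex`. Two physical rules are modelled:

* **Exchange gating.** Only residues with `kex` above a threshold (default
  2 1/s) receive polarization from the water and contribute signal; the
  filter is a hard step, since no transfer-efficiency curve is modelled.
* **Proton-fraction scaling.** Signal is linear in the exchangeable proton
  fraction of the solvent, so 90% vs 2% protonated water gives exactly a
  45-fold intensity ratio.

Default resonance ranges emulate an IDP in a fast 2D experiment: offsets in
the central 80% of each spectral width (no aliasing by construction),
indirect intrinsic decay in a narrow band of 40-60 1/s (IDP residue
dynamics are nearly uniform -- the same property that justifies a single
exogenous rate), direct-dimension decay 30-60 1/s, amplitudes 0.5-1.5, and
`kex` uniform on 0-20 1/s so typical sets include undetectable residues.
The standard scheme is 64 complex t1 increments at 0.2 ms (t1_max =
12.8 ms), 200 direct points at 0.5 ms, two scans per FID and a 100 ms
recycle delay, giving a wall-clock duration of about 51 s.

`distort()` applies the envelope and adds white complex Gaussian noise of
standard deviation `noise_sigma` times the maximum magnitude of the decayed
data, independently to both components. What the generator does **not**
emulate: scan-to-scan instability, solvent artifacts, baseline and phase
errors, J-couplings, wall-clock reservoir kinetics between scans, and any
soft dependence of transfer efficiency on `kex`. Passing tests therefore
demonstrate correctness of the algorithms under the stated noise model, not
robustness to every artifact of real spectrometer data.

### Per-trace signal-to-noise

A subtlety worth stating explicitly: the direct-dimension Fourier transform
concentrates each resonance into a few columns but spreads time-domain
noise over all of them, multiplying per-trace noise by `sqrt(n_t2)` while
peak columns gain roughly the direct-dimension sharpening factor. A
"time-domain SNR 20" dataset can thus have selected traces at SNR 1-10,
where no estimator can work. `trace_snr()` reports the SNR of the
energy-ranked traces and `noise_sigma_for_trace_snr()` calibrates the
generator so the weakest selected trace reaches a target SNR; the standard
fixtures use a target of 20.

## The training corpus

`build_training_set()` realises labelled examples

    T(t1) = I(t1) * eps_train * exp(-R_train * t1) + noise

with `eps_train`, `R_train` and the relative noise level each drawn
independently and uniformly from configurable ranges; the label is
`R_train`. Defaults: 100,000 examples, rates 50-1000 1/s (bracketing the
typical 450), enhancements 1-700, relative noise 1e-4 to 0.2, noise drawn
per point (per-trace white complex Gaussian; the alternative -- a per-trace
noise level with per-point draws -- is what is implemented, since nothing
constrains the choice further). Intrinsic traces `I(t1)` are
indirect-dimension columns of intrinsic interferograms: either a measured
dataset supplied by the user (the intended use when analysing real data) or,
by default, freshly generated synthetic sets (256 examples drawn per
generated interferogram). Corpus generation is bitwise reproducible from
its seed.

## The rate estimator

Each complex trace is max-magnitude normalized and encoded as concatenated
real and imaginary parts (`featurize()`), making the estimator exactly
scale-invariant and hence independent of `eps`. The regressor is a fully
connected network, hidden layers of 128 and 64 ReLU units and a linear
scalar output, trained with Adam (step 1e-3, batch 256, 60 epochs, 90/10
train/validation split) on mean squared error of the *normalized* label
`R * t1_max`, so a model transfers across dwell settings sharing the trace
length. Training is deterministic given its seed, and serialized models
(`write_estimator()`) reproduce predictions bitwise on reload.

The network is implemented in-package with plain matrix algebra: it is the
scientific core of the method, it is small (about 25k weights), and a
self-contained implementation keeps training, determinism and
serialization under direct control.

Design points that were genuinely open and how they were settled:

* **Input encoding.** Real+imaginary of the normalized complex trace
  preserves the oscillation structure that a magnitude envelope loses;
  magnitude-only and log-magnitude encodings were evaluated and performed
  no better, so the richer encoding was kept.
* **Aggregation.** `estimate_global_rate()` transforms the direct
  dimension, selects the 50 highest-energy columns (the selection rule for
  "50 FIDs" is energy ranking, the natural objective criterion), predicts
  per column, and reports the arithmetic mean, with the median alongside
  as a robustness diagnostic. If fewer usable columns exist, all are used
  and the count is recorded.
* **Irreducible per-trace scatter.** A single trace confounds the
  exogenous rate with its own intrinsic decay and beating pattern, so
  per-trace predictions scatter by roughly 10-20% even without noise.
  Averaging 50 traces brings the aggregated estimate to a few percent;
  this is the reason the method prescribes averaging in the first place.
* **Validation oracle.** `baseline_rate_ls()` fits the least-squares slope
  of `-log(|S|/|I|)` against t1 -- usable only in simulation, where the
  intrinsic trace is known. Points where either magnitude sits near the
  noise floor are excluded (the magnitude of signal-plus-complex-noise
  biases the logarithm there); a floor of ~10x the trace noise makes the
  oracle unbiased at high SNR, where it agrees with the network to within
  a few percent.

Measured on synthetic data at per-trace SNR >= 20 (the acceptance test
recomputes this): median relative error of the aggregated estimate is
below 10% across true rates of 100-800 1/s, and replicate aggregated
estimates on common-rate data disperse by under 5% sd/mean.

## Processing and deconvolution

`process_spectrum()` runs a fixed pipeline: optional division by
`exp(-R t1)`, apodization, zero-filling, complex FT along t2, States
recombination and complex FT along t1, real part. Numerical choices:

* First points of both time dimensions are halved before transforming
  (standard practice; the discrete transform of a half-sided decay then
  approximates the continuous one and the baseline stays flat). With this,
  measured FWHM matches the Lorentzian law `rate/pi` to better than 1% at
  4x zero-fill when the FID has decayed out.
* Default zero-fill is 4x along t1 (stable width measurement) and none
  along t2.
* Default window is none, correct for noiseless simulation. For noisy
  deconvolution the recommended (and test-exercised) settings are
  `window = "cosine2"` with `max_gain` set to about the per-trace SNR:
  division amplifies late-t1 noise by `exp(R t1)` (a factor ~300 at
  R = 450 1/s and t1_max = 12.8 ms), the window tapers that tail, and
  amplifying beyond the trace SNR adds only noise.
* No phase correction by default (simulated data are zero-phase by
  construction); imported data should be phased upstream.
* Division by a real positive envelope cannot shift frequencies; peak
  centres before and after deconvolution agree to a fraction of a bin.

One accounting consequence, verified in the tests: under white time-domain
noise, dividing by the envelope raises frequency-domain noise by the rms
gain `sqrt(mean(exp(2 R t1)))`, which always exceeds the peak-height
restoration factor. The box-noise SNR of a peak is therefore *lower* after
deconvolution, even though resolution -- and with it peak separability and
positional accuracy -- is restored. Reported SNR* values after
deconvolution should be read with that in mind.

## Metrology

`pick_peaks()` finds 8-neighbourhood local maxima above a threshold times a
robust noise estimate (MAD of the whole plane) and above a small fraction
of the global maximum (suppressing truncation ripples in noiseless data),
greedily separated, with parabolic sub-bin centres. `measure_fwhm()`
interpolates half-height crossings linearly -- model-free and stable at 4x
zero-fill, rather than committing to a line-shape fit. `compute_snr()`
divides peak height by the standard deviation of a user-chosen signal-free
box (no universal noise-region convention exists, so the region is
explicit), refusing regions that touch the peak's footprint or have zero
variance. `enhancement_factors()` returns both the plain SNR ratio
(`epsilon_star`) and the sqrt-measurement-time-normalized ratio
(`epsilon = epsilon_star * sqrt(time_c / time_h)`); no receiver-gain or
scan-count normalization is attempted, since those instrument settings are
not modelled. `compare_spectra()` matches peaks greedily by descending
height within a per-axis tolerance and reports per-pair position deltas and
width ratios.

## Problem sizes used in the tests

The suite trains the default network once (100,000 examples, 60 epochs,
about 4 minutes on one CPU) and shares it. Recovery is evaluated on 20
fresh datasets per true rate over 100-800 1/s; width-law checks use a
512-increment acquisition so the intrinsic FID decays out (at 64 increments
the intrinsic line is truncation-dominated and the Lorentzian law cannot be
observed); the end-to-end fixture keeps the experimental 64-increment
scheme and compares deconvolved against reference-processed intrinsic
spectra under identical processing. These sizes were chosen as the smallest
that make the statistical assertions stable.

## Known limitations

* The exogenous envelope is a single exponential; any slow secondary
  component of the reservoir decay is not modelled.
* The estimator is trained per trace-length contract (64 points by
  default); other schemes require retraining (seconds to minutes).
* At per-trace SNR below ~10 the network's predictions shrink toward the
  middle of the training range; the per-trace SNR tools exist to diagnose
  exactly this.
* Vendor-format import is out of scope; data enter either through the
  simulator or through the documented JSON container
  (`write_dataset()` / `read_dataset()`), which stores numbers as
  full-precision text and round-trips bitwise.
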