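# hyperwdecon

Reference-free correction of hyperpolarization-decay line broadening in 2D
NMR interferograms.

## The problem

Hyperpolarized-water (dissolution-DNP) NMR boosts protein signal by orders
of magnitude: polarized solvent protons exchange onto backbone amides
while a fast 2D ¹H–¹⁵N correlation experiment is recorded. But the water
polarization decays during the point-by-point sampling of the indirect
dimension, so the intrinsic indirect-dimension FID *I*(t₁) of every
resonance is multiplied by a common exogenous envelope

> *S*(t₁) = ε · exp(−R₁,eff · t₁) · *I*(t₁)

where ε is the enhancement at t₁ = 0 and R₁,eff the effective exogenous
decay rate (typically ≈ 0.45 ms⁻¹ = 450 s⁻¹ at a 12.8 ms maximum evolution
time). In the spectrum this convolves every line with a Lorentzian of width
R₁,eff/π Hz along the indirect dimension — ≈ 143 Hz of added width, which
abolishes residue resolution.

Because the envelope is the same for every trace (one water reservoir, one
decay rate; intrinsically disordered proteins additionally have nearly
residue-uniform relaxation), it can be identified *from the data alone*.
`hyperwdecon` implements the full workflow for scientists developing or
using such experiments:

1. **simulate** — States-hypercomplex 2D interferograms of IDP-like
   resonance sets: exchange-gated amplitudes (only residues with
   k_ex > 2 s⁻¹ are polarized), linear proton-fraction scaling, the
   exogenous envelope, calibrated complex Gaussian noise;
2. **estimate** — a small feed-forward neural network (128+64 ReLU units),
   trained on 100,000 simulated traces T(t₁) = I(t₁)·ε·exp(−R·t₁)+noise,
   predicts R₁,eff per indirect-dimension trace; the mean over the 50
   highest-energy traces is the global estimate;
3. **deconvolve** — division of the time-domain data by exp(−R₁,eff·t₁)
   before the indirect Fourier transform (with optional gain clamping and
   apodization to control the amplified tail noise);
4. **evaluate** — peak picking, FWHM, SNR, enhancement factors
   ε = ε\*·√(t_conv/t_hyper) and ε\* = SNR_hyper/SNR_conv, and matched
   before/after comparisons.

## Worked example

Broaden and recover a single resonance (intrinsic indirect decay
50 s⁻¹, exogenous rate 450 s⁻¹):

```r
library(hyperwdecon)

scheme    <- acq_scheme(n_t1_complex = 512, dt1 = 2e-4, n_t2 = 200, dt2 = 5e-4)
res       <- data.frame(f1 = 500, f2 = 300, r2_ind = 50, r2_dir = 40,
                        amplitude = 1, kex = 10)
intrinsic <- synthesize_intrinsic(res, scheme)
hyper     <- distort(intrinsic, decay_model(epsilon = 300, rate = 450),
                     noise_sigma = 0, seed = 1)

width1 <- function(ifg, rate = NULL) {
  sp <- process_spectrum(ifg, rate = rate, window = "none", zero_fill = c(4, 1))
  pk <- pick_peaks(sp, min_height_frac = 0.2)
  measure_fwhm(sp, pk[1, ], axis = 1)
}
width1(intrinsic)          # intrinsic width
width1(hyper)              # broadened
width1(hyper, rate = 450)  # deconvolved
```

which prints

```
intrinsic indirect FWHM :  16.0 Hz (Lorentzian law:  15.9)
HyperW-broadened FWHM   : 159.3 Hz (law: 159.2)
deconvolved FWHM        :  16.0 Hz
```

— the exogenous decay added R/π ≈ 143 Hz of width and the division
restored the intrinsic line exactly.

On a realistic 50-resonance dataset the rate is *estimated*, not given.
Train the default network once and apply it (both steps are deterministic
given their seeds):

```r
scheme <- acq_scheme(64, 2e-4, 200, 5e-4)
corpus <- build_training_set(config = training_config(seed = 7), scheme = scheme)
model  <- train_estimator(corpus, seed = 3)           # ~4 min, CPU
fx     <- make_fixture("opn_like", seed = 2)          # 50 resonances, true rate 450
est    <- estimate_global_rate(model, fx$hyperpolarized_ifg, n_traces = 50)
glance(est)
#> # A tibble: 1 × 4
#>   mean_rate    sd median_rate n_traces
#>       <dbl> <dbl>       <dbl>    <int>
#> 1      447.  106.        440.       50
```

The per-trace predictions scatter (each trace confounds the common
envelope with its own beating pattern), which is exactly why the method
averages 50 of them: the aggregated mean lands within a few percent of the
true 450 s⁻¹. Deconvolve and compare against reference processing with:

```r
spec <- process_spectrum(fx$hyperpolarized_ifg, rate = est$mean_rate,
                         window = "cosine2", zero_fill = c(4, 2), max_gain = 20)
autoplot(spec)
```

A command-line surface over the same functions (verbs `simulate`, `train`,
`estimate`, `deconvolve`, `evaluate`, `fixture`; YAML configs; JSON
provenance logs) is installed at
`system.file("cli", "hyperwdecon.R", package = "hyperwdecon")`.

## Package layout

| file | contents |
| --- | --- |
| `R/scheme.R`, `R/interferogram.R`, `R/decay.R` | acquisition schemes, hypercomplex containers, the decay envelope and its apply/remove algebra |
| `R/simulate.R`, `R/training-set.R` | resonance sampling, intrinsic synthesis, distortion, the labelled training corpus |
| `R/mlp.R`, `R/estimate.R` | the neural-network regressor, featurization, global rate estimation, the least-squares oracle |
| `R/spectrum.R` | apodization, zero-filling, hypercomplex Fourier processing |
| `R/peaks.R` | peak picking, FWHM, SNR, enhancement factors, spectrum comparison |
| `R/io.R`, `R/fixtures.R` | JSON dataset/model containers (bitwise round trip), standard scenarios, YAML scenario configs |
| `vignettes/hyperwdecon-methods.Rmd` | the model, its assumptions, parameter choices and limitations |
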