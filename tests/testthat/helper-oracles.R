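# independent oracles and small fixtures shared across test files

# exponential via truncated power series, independent of exp()
exp_series <- function(x, terms = 40L) {
  sum(x^(0:terms) / factorial(0:terms))
}

# textbook DFT by direct summation (no fft), x sampled at dwell dt
naive_dft <- function(x, dt, freqs) {
  t <- (seq_along(x) - 1) * dt
  vapply(freqs, function(f) sum(x * exp(-2i * pi * f * t)), complex(1))
}

one_resonance <- function(f1 = 500, f2 = 300, r2_ind = 50, r2_dir = 40,
                          amplitude = 1, kex = 10) {
  data.frame(f1 = f1, f2 = f2, r2_ind = r2_ind, r2_dir = r2_dir,
             amplitude = amplitude, kex = kex)
}

# the fast hyperpolarized scheme (64 x 0.2 ms) and a long variant whose
# indirect FID decays out fully, for width-law measurements
scheme_fast <- function() acq_scheme(64L, 2e-4, 200L, 5e-4)
scheme_long <- function(n_t2 = 64L) acq_scheme(512L, 2e-4, n_t2, 5e-4)

# scale an interferogram by a constant (tests of linearity)
scale_ifg <- function(ifg, a) {
  ifg$cos <- ifg$cos * a
  ifg$sin <- ifg$sin * a
  ifg
}
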