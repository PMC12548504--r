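test_that("peak picking finds isolated resonances and their heights", {
  sch <- scheme_long(n_t2 = 200L)
  one <- synthesize_intrinsic(one_resonance(), sch)
  sp1 <- process_spectrum(one, window = "cosine2", zero_fill = c(4L, 2L))
  expect_equal(nrow(pick_peaks(sp1)), 1L)
  # two separated resonances are both found with heights in the
  # amplitude ratio
  res <- rbind(one_resonance(f1 = -900, f2 = -300, amplitude = 1),
               one_resonance(f1 = 800, f2 = 350, amplitude = 0.6))
  sp2 <- process_spectrum(synthesize_intrinsic(res, sch),
                          window = "cosine2", zero_fill = c(4L, 2L))
  pk <- pick_peaks(sp2, min_separation = 3L)
  expect_equal(nrow(pk), 2L)
  expect_lt(abs(pk$height[2] / pk$height[1] - 0.6), 0.6 * 0.02)
  # ordering is height-descending
  expect_true(all(diff(pk$height) <= 0))
})

test_that("pure noise yields almost no false positives at 5 sigma", {
  sch <- scheme_fast()
  set.seed(1234)
  n <- 64L * 200L
  mk <- function() matrix(complex(real = rnorm(n), imaginary = rnorm(n)),
                          64L, 200L)
  ifg <- interferogram(mk(), mk(), sch, role = "intrinsic")
  sp <- process_spectrum(ifg, window = "none", zero_fill = c(1L, 1L))
  pk <- pick_peaks(sp, threshold = 5, min_height_frac = 0)
  n_bins <- length(sp$intensity)
  expect_gte(n_bins, 1e4)
  expect_lt(nrow(pk) / n_bins, 1e-4)
})

test_that("FWHM measurement matches the Lorentzian width law", {
  sch <- scheme_long(n_t2 = 64L)
  ifg <- synthesize_intrinsic(one_resonance(r2_ind = 100), sch)
  sp <- process_spectrum(ifg, window = "none", zero_fill = c(8L, 1L))
  pk <- pick_peaks(sp, min_height_frac = 0.2)
  w <- measure_fwhm(sp, pk[1, ], axis = 1L)
  expect_lt(abs(w - 100 / pi) / (100 / pi), 0.03)
  # invariant under intensity rescaling
  sp2 <- sp; sp2$intensity <- sp$intensity * 17
  pk2 <- pick_peaks(sp2, min_height_frac = 0.2)
  expect_equal(measure_fwhm(sp2, pk2[1, ], axis = 1L), w)
  # width after adding an exogenous rate grows by rate/pi
  hyp <- apply_decay(ifg, decay_model(1, 450))
  sph <- process_spectrum(hyp, window = "none", zero_fill = c(8L, 1L))
  pkh <- pick_peaks(sph, min_height_frac = 0.2)
  wh <- measure_fwhm(sph, pkh[1, ], axis = 1L)
  expect_lt(abs((wh - w) - 450 / pi) / (450 / pi), 0.05)
})

test_that("a truncated peak reports a missing half-height crossing", {
  sch <- scheme_fast()
  # resonance near the direct-dimension edge: left crossing off the grid
  ifg <- synthesize_intrinsic(one_resonance(f2 = -999, r2_dir = 5), sch)
  sp <- process_spectrum(ifg, window = "none", zero_fill = c(1L, 1L))
  ij <- which(sp$intensity == max(sp$intensity), arr.ind = TRUE)
  peak <- list(i1 = ij[1], i2 = ij[2])
  expect_error(measure_fwhm(sp, peak, axis = 2L),
               class = "hw_truncation_error")
})

test_that("SNR is height over noise-box standard deviation", {
  sch <- scheme_fast()
  sig <- synthesize_intrinsic(one_resonance(f1 = 500, f2 = 300), sch)
  box <- list(f1 = c(1300, 2400), f2 = c(-900, -300))
  # an exactly signal-free region has zero sd: a degenerate input, and
  # the error says so
  sp0 <- process_spectrum(sig, window = "none", zero_fill = c(1L, 1L))
  pk0 <- pick_peaks(sp0, min_height_frac = 0.2)
  sp0z <- sp0
  sp0z$intensity[sp0$axis1 >= 1300 & sp0$axis1 <= 2400,
                 sp0$axis2 >= -900 & sp0$axis2 <= -300] <- 0
  expect_error(compute_snr(sp0z, pk0[1, ], box), class = "hw_domain_error")
  # overlap with the peak footprint is refused
  set.seed(77)
  n <- 64L * 200L
  noise <- matrix(complex(real = rnorm(n, sd = 0.02),
                          imaginary = rnorm(n, sd = 0.02)), 64L, 200L)
  noisy <- interferogram(sig$cos + noise, sig$sin + noise, sch,
                         role = "intrinsic")
  spn <- process_spectrum(noisy, window = "none", zero_fill = c(1L, 1L))
  pkn <- pick_peaks(spn, min_height_frac = 0.2)
  expect_error(compute_snr(spn, pkn[1, ],
                           list(f1 = c(400, 600), f2 = c(250, 350))),
               class = "hw_domain_error")
  snr1 <- compute_snr(spn, pkn[1, ], box)
  # doubling the signal at fixed noise doubles the SNR
  noisy2 <- interferogram(2 * sig$cos + noise, 2 * sig$sin + noise, sch,
                          role = "intrinsic")
  spn2 <- process_spectrum(noisy2, window = "none", zero_fill = c(1L, 1L))
  pkn2 <- pick_peaks(spn2, min_height_frac = 0.2)
  snr2 <- compute_snr(spn2, pkn2[1, ], box)
  expect_lt(abs(snr2 / snr1 - 2), 0.05)
})

test_that("measured SNR agrees with the white-noise propagation law", {
  # complex white noise of per-part sd s in both components lands in the
  # real spectrum with sd s * sqrt(n1 * n2); calibrate for SNR 20 and check
  sch <- scheme_fast()
  sig <- synthesize_intrinsic(one_resonance(f1 = 500, f2 = 300), sch)
  sp_clean <- process_spectrum(sig, window = "none", zero_fill = c(1L, 1L))
  h <- max(sp_clean$intensity)
  s_abs <- h / (20 * sqrt(64 * 200))
  box <- list(f1 = c(1300, 2400), f2 = c(-900, -300))
  snrs <- vapply(1:20, function(i) {
    set.seed(4000 + i)
    n <- 64L * 200L
    mk <- function() matrix(complex(real = rnorm(n, sd = s_abs),
                                    imaginary = rnorm(n, sd = s_abs)),
                            64L, 200L)
    noisy <- interferogram(sig$cos + mk(), sig$sin + mk(), sch,
                           role = "intrinsic")
    sp <- process_spectrum(noisy, window = "none", zero_fill = c(1L, 1L))
    pk <- pick_peaks(sp, min_height_frac = 0.2)
    compute_snr(sp, pk[1, ], box)
  }, numeric(1))
  expect_lt(abs(mean(snrs) - 20) / 20, 0.15)
})

test_that("enhancement factors combine SNR and sqrt measurement time", {
  e <- enhancement_factors(10, 100, 10, 100)
  expect_equal(e$epsilon, 1)
  expect_equal(e$epsilon_star, 1)
  expect_equal(enhancement_factors(50, 30, 10, 30)$epsilon_star, 5)
  # 80 min conventional vs 50 s hyperpolarized: sqrt(96) time payback
  e2 <- enhancement_factors(50, 50, 10, 4800)
  expect_equal(e2$epsilon / e2$epsilon_star, sqrt(96))
  expect_equal(e2$epsilon, 5 * 9.797959, tolerance = 1e-6)
  expect_error(enhancement_factors(-1, 1, 1, 1), class = "hw_domain_error")
  expect_error(enhancement_factors(1, 0, 1, 1), class = "hw_domain_error")
})

test_that("spectrum comparison matches peaks and reports deltas", {
  sch <- scheme_fast()
  res <- sample_resonances(10, seed = 12, scheme = sch)
  int <- synthesize_intrinsic(res, sch)
  sp <- process_spectrum(int, window = "cosine2", zero_fill = c(4L, 2L))
  self <- compare_spectra(sp, sp, match_tol = c(20, 10),
                          min_height_frac = 0.05, min_separation = 3L)
  expect_gt(nrow(self$pairs), 0)
  expect_equal(self$pairs$d_f1, rep(0, nrow(self$pairs)))
  expect_equal(nrow(self$unmatched_a), 0L)
  # noiseless deconvolution vs reference processing: every peak matches
  # within half a digital-resolution bin
  hyp <- distort(int, decay_model(300, 450), 0, seed = 1)
  dec <- process_spectrum(hyp, rate = 450, window = "cosine2",
                          zero_fill = c(4L, 2L))
  pr <- compare_spectra(dec, sp, match_tol = c(20, 10),
                        min_height_frac = 0.05, min_separation = 3L)
  half_bin <- digital_resolution(sch, c(4L, 2L))[1] / 2
  expect_equal(nrow(pr$unmatched_a), 0L)
  expect_true(all(abs(pr$pairs$d_f1) < half_bin))
  # a spectrum shifted beyond the tolerance matches nothing
  far <- synthesize_intrinsic(one_resonance(f1 = 500), sch)
  near <- synthesize_intrinsic(one_resonance(f1 = 700), sch)
  pn <- compare_spectra(
    process_spectrum(far, window = "cosine2", zero_fill = c(4L, 2L)),
    process_spectrum(near, window = "cosine2", zero_fill = c(4L, 2L)),
    match_tol = c(50, 50))
  expect_equal(nrow(pn$pairs), 0L)
})

test_that("deconvolution SNR accounting follows the analytic gain factors", {
  # division by exp(-R t1) scales frequency-domain noise by the rms of the
  # gain and the peak height by the envelope-sum ratio; both are checked
  sch <- scheme_fast()
  # the resonance sits exactly on a frequency bin of the unpadded grid so
  # peak heights are envelope sums without off-bin attenuation
  sig <- synthesize_intrinsic(one_resonance(f1 = 468.75, f2 = 300,
                                            r2_ind = 50), sch)
  R <- 200
  hyp <- distort(sig, decay_model(1, R), noise_sigma = 0.005, seed = 31)
  raw <- process_spectrum(hyp, window = "none", zero_fill = c(1L, 1L))
  dec <- process_spectrum(hyp, rate = R, window = "none",
                          zero_fill = c(1L, 1L))
  sel1 <- raw$axis1 > 1300 & raw$axis1 < 2400
  sel2 <- raw$axis2 > -900 & raw$axis2 < -300
  noise_gain <- sd(dec$intensity[sel1, sel2]) /
    sd(raw$intensity[sel1, sel2])
  t1 <- (0:63) * 2e-4
  fp <- c(0.5, rep(1, 63))
  expected_noise_gain <- sqrt(mean(exp(2 * R * t1)))
  expected_height_gain <- sum(fp * exp(-50 * t1)) /
    sum(fp * exp(-(50 + R) * t1))
  height_gain <- max(dec$intensity) / max(raw$intensity)
  expect_lt(abs(noise_gain / expected_noise_gain - 1), 0.10)
  expect_lt(abs(height_gain / expected_height_gain - 1), 0.10)
  # consequently SNR* changes by the ratio of the two factors
  expect_lt(abs((height_gain / noise_gain) /
                  (expected_height_gain / expected_noise_gain) - 1), 0.15)
})

test_that("peak lists and pairings round-trip through TSV", {
  sch <- scheme_fast()
  res <- rbind(one_resonance(f1 = -900, f2 = -300),
               one_resonance(f1 = 800, f2 = 350))
  sp <- process_spectrum(synthesize_intrinsic(res, sch),
                         window = "cosine2", zero_fill = c(4L, 2L))
  pk <- pick_peaks(sp, min_separation = 3L)
  path <- tempfile(fileext = ".tsv")
  write_peaks_tsv(pk, path)
  back <- read_peaks_tsv(path)
  expect_equal(back$f1_hz, pk$f1)
  expect_equal(back$fwhm1_hz, pk$fwhm1)
  pr <- compare_spectra(sp, sp, match_tol = c(20, 10), min_separation = 3L)
  path2 <- tempfile(fileext = ".tsv")
  write_pairing_tsv(pr, path2)
  expect_equal(nrow(read_peaks_tsv(path2)), nrow(pr$pairs))
})
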