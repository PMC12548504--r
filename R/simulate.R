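#' Default sampling intervals for synthetic resonances
#'
#' Offsets are confined to the central 80% of each spectral width so no
#' resonance aliases or sits on the spectrum edge. Intrinsic decay ranges
#' reflect an intrinsically disordered protein: residue dynamics are nearly
#' uniform, so the indirect-dimension decay is drawn from a narrow band
#' around 50 1/s. Exchange rates span both sides of the 2 1/s detectability
#' threshold so that typical sets contain undetectable residues too.
#'
#' @param scheme An [acq_scheme()].
#' @return Named list of `c(low, high)` intervals for `f1`, `f2` (Hz),
#'   `r2_ind`, `r2_dir`, `kex` (1/s) and `amplitude`.
#' @export
default_resonance_ranges <- function(scheme) {
  sw1 <- 1 / scheme$dt1
  sw2 <- 1 / scheme$dt2
  list(
    f1 = c(-0.4, 0.4) * sw1,
    f2 = c(-0.4, 0.4) * sw2,
    r2_ind = c(40, 60),
    r2_dir = c(30, 60),
    amplitude = c(0.5, 1.5),
    kex = c(0, 20)
  )
}

#' Draw a random set of resonances
#'
#' Each resonance has indirect/direct offsets (Hz), intrinsic decay rates
#' along both time axes (1/s), an amplitude, and an amide-proton exchange
#' rate `kex` (1/s) that governs whether it picks up polarization from the
#' water reservoir. All fields are drawn independently and uniformly from
#' their intervals; degenerate intervals `c(x, x)` pin a field.
#'
#' @param n Number of resonances.
#' @param ranges Named list of intervals as in [default_resonance_ranges()];
#'   missing entries fall back to the defaults for `scheme`.
#' @param seed Integer seed; identical seeds give identical sets.
#' @param scheme An [acq_scheme()] used for the default offset ranges.
#' @return A tibble with class `hw_resonances`, one row per resonance.
#' @export
sample_resonances <- function(n, ranges = list(), seed = 1L,
                              scheme = NULL) {
  n <- check_count(n, "n")
  defaults <- if (!is.null(scheme)) default_resonance_ranges(scheme) else
    list(f1 = c(-2000, 2000), f2 = c(-800, 800), r2_ind = c(40, 60),
         r2_dir = c(30, 60), amplitude = c(0.5, 1.5), kex = c(0, 20))
  ranges <- modifyList(defaults, ranges)
  for (nm in names(ranges)) {
    r <- ranges[[nm]]
    if (!is.numeric(r) || length(r) != 2L || !all(is.finite(r)) || r[1] > r[2])
      stop_hw("range for '", nm, "' must be c(low, high) with low <= high",
              class = "hw_domain_error")
  }
  draw <- function(r) runif(n, r[1], r[2])
  res <- withr_seed(seed, {
    tibble::tibble(
      f1 = draw(ranges$f1),
      f2 = draw(ranges$f2),
      r2_ind = draw(ranges$r2_ind),
      r2_dir = draw(ranges$r2_dir),
      amplitude = draw(ranges$amplitude),
      kex = draw(ranges$kex)
    )
  })
  class(res) <- c("hw_resonances", class(res))
  res
}

# evaluate expr under a local RNG state seeded with `seed`
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Synthesize an intrinsic hypercomplex interferogram
#'
#' Builds the undistorted (thermal-equilibrium-like) time-domain data as a
#' sum of damped complex oscillations. Only resonances whose amide exchange
#' rate exceeds `kex_threshold` contribute: slowly exchanging residues do
#' not receive polarization from the water reservoir and are invisible in
#' this experiment. Signal amplitude scales linearly with the exchangeable
#' proton fraction of the solvent (`water_fraction`), so, e.g., 90% vs 2%
#' protonated water gives a 45-fold intensity ratio.
#'
#' The cosine component carries `cos(2 pi f1 t1)` modulation and the sine
#' component `sin(2 pi f1 t1)`, both times the complex direct-dimension
#' oscillation `exp(i 2 pi f2 t2)` and the intrinsic decays
#' `exp(-r2_ind t1 - r2_dir t2)`.
#'
#' @param resonances A tibble from [sample_resonances()] (or any data frame
#'   with the same columns).
#' @param scheme An [acq_scheme()].
#' @param water_fraction Exchangeable proton fraction in (0, 1].
#' @param kex_threshold Detectability threshold on `kex` in 1/s; default 2.
#' @return An `intrinsic` [interferogram()]. If no resonance passes the
#'   filter, an all-zero interferogram is returned with a warning.
#' @export
synthesize_intrinsic <- function(resonances, scheme, water_fraction = 1,
                                 kex_threshold = 2) {
  stopifnot(inherits(scheme, "hw_scheme"))
  water_fraction <- check_number(water_fraction, "water_fraction",
                                 lower = 0, upper = 1, allow_zero = FALSE)
  res <- as.data.frame(resonances)
  need <- c("f1", "f2", "r2_ind", "r2_dir", "amplitude", "kex")
  if (!all(need %in% names(res)))
    stop_hw("resonances must have columns ", paste(need, collapse = ", "),
            class = "hw_domain_error")
  nyq1 <- 1 / (2 * scheme$dt1); nyq2 <- 1 / (2 * scheme$dt2)
  if (any(abs(res$f1) >= nyq1) || any(abs(res$f2) >= nyq2))
    stop_hw("resonance offsets exceed the Nyquist frequencies",
            class = "hw_domain_error")
  keep <- res$kex > kex_threshold
  t1 <- t1_grid(scheme); t2 <- t2_grid(scheme)
  cosm <- matrix(0 + 0i, scheme$n_t1_complex, scheme$n_t2)
  sinm <- cosm
  if (!any(keep)) {
    warning("no resonance exceeds kex_threshold = ", kex_threshold,
            "; returning an all-zero interferogram", call. = FALSE)
  } else {
    for (k in which(keep)) {
      a <- res$amplitude[k] * water_fraction
      env1 <- exp(-res$r2_ind[k] * t1)
      dir_osc <- a * exp((2i * pi * res$f2[k] - res$r2_dir[k]) * t2)
      cosm <- cosm + (cos(2 * pi * res$f1[k] * t1) * env1) %o% dir_osc
      sinm <- sinm + (sin(2 * pi * res$f1[k] * t1) * env1) %o% dir_osc
    }
  }
  interferogram(cosm, sinm, scheme, role = "intrinsic",
                meta = list(water_fraction = water_fraction,
                            kex_threshold = kex_threshold,
                            n_active = sum(keep),
                            provenance = sprintf(
                              "synthesize_intrinsic: %d/%d resonances, wf=%g",
                              sum(keep), nrow(res), water_fraction)))
}

#' Distort an intrinsic interferogram into a hyperpolarized one
#'
#' Applies the exogenous decay envelope with [apply_decay()] and then adds
#' independent complex Gaussian noise to both hypercomplex components. The
#' noise standard deviation (per real/imaginary part) is
#' `noise_sigma * max(|decayed data|)`, i.e. `noise_sigma` is relative to
#' the strongest time-domain point, so `1/noise_sigma` is the nominal
#' time-domain SNR of the strongest trace.
#'
#' @param ifg An `intrinsic` [interferogram()].
#' @param model A [decay_model()].
#' @param noise_sigma Relative noise level, >= 0.
#' @param seed Integer seed for the noise stream.
#' @return A `hyperpolarized` interferogram; metadata records model, noise
#'   level and seed.
#' @export
distort <- function(ifg, model, noise_sigma = 0, seed = 1L) {
  noise_sigma <- check_number(noise_sigma, "noise_sigma", lower = 0)
  out <- apply_decay(ifg, model)
  if (noise_sigma > 0) {
    sd_abs <- noise_sigma * ifg_max_mod(out)
    d <- dim(out$cos)
    noise <- withr_seed(seed, {
      n <- prod(d)
      list(
        cos = matrix(complex(real = rnorm(n, sd = sd_abs),
                             imaginary = rnorm(n, sd = sd_abs)), d[1], d[2]),
        sin = matrix(complex(real = rnorm(n, sd = sd_abs),
                             imaginary = rnorm(n, sd = sd_abs)), d[1], d[2])
      )
    })
    out$cos <- out$cos + noise$cos
    out$sin <- out$sin + noise$sin
  }
  out$meta$noise_sigma <- noise_sigma
  out$meta$seed <- seed
  log_provenance(out, sprintf("distort: noise_sigma=%g seed=%s", noise_sigma,
                              format(seed)))
}

#' Per-trace signal-to-noise calibration
#'
#' The direct-dimension Fourier transform concentrates a resonance's signal
#' into a few columns while spreading white time-domain noise over all of
#' them (amplifying the per-trace noise by `sqrt(n_t2)`), so the
#' signal-to-noise ratio of the extracted indirect-dimension traces differs
#' substantially from the nominal time-domain level set in [distort()].
#' `trace_snr()` reports the per-trace SNR (maximum clean trace magnitude
#' over the per-part noise standard deviation after recombination) that a
#' given relative noise level would produce for the `n_traces`
#' highest-energy columns; `noise_sigma_for_trace_snr()` inverts this,
#' returning the `noise_sigma` at which the weakest selected trace reaches
#' `target_snr`.
#'
#' @param ifg An `intrinsic` [interferogram()].
#' @param model The [decay_model()] that will be applied.
#' @param noise_sigma Relative time-domain noise level (see [distort()]).
#' @param n_traces Number of energy-ranked columns considered.
#' @return `trace_snr()`: numeric vector of per-trace SNRs (energy-ranked);
#'   `noise_sigma_for_trace_snr()`: a single `noise_sigma` value.
#' @export
trace_snr <- function(ifg, model, noise_sigma, n_traces = 50L) {
  stopifnot(inherits(ifg, "hw_interferogram"))
  clean <- apply_decay(ifg, model)
  tr <- indirect_traces(clean)
  ord <- order(tr$energy, decreasing = TRUE)
  ord <- ord[seq_len(min(n_traces, sum(tr$energy > 0)))]
  col_max <- apply(Mod(tr$traces[, ord, drop = FALSE]), 2L, max)
  sigma_trace <- noise_sigma * ifg_max_mod(clean) * sqrt(ifg$scheme$n_t2)
  col_max / sigma_trace
}

#' @rdname trace_snr
#' @param target_snr Desired SNR of the weakest selected trace.
#' @export
noise_sigma_for_trace_snr <- function(ifg, model, target_snr = 20,
                                      n_traces = 50L) {
  target_snr <- check_number(target_snr, "target_snr", lower = 0,
                             allow_zero = FALSE)
  snr_at_unit <- trace_snr(ifg, model, noise_sigma = 1,
                           n_traces = n_traces)
  min(snr_at_unit) / target_snr
}
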