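#' Standard synthetic scenarios
#'
#' Deterministic fixture datasets used by the examples and the test suite.
#' All scenarios use the acquisition settings of a fast hyperpolarized
#' BEST-HMQC-style experiment: 64 complex t1 increments at dt1 = 0.2 ms
#' (t1_max = 12.8 ms), a 100 ms direct acquisition window, 2 scans per FID
#' and a 100 ms recycle delay. Ground truth (decay model, noise level,
#' seed) is stored in the dataset metadata.
#'
#' * `"opn_like"` -- a 50-resonance intrinsically disordered protein in a
#'   2% protonated buffer (uniform intrinsic indirect decay of 50 1/s, as
#'   appropriate for an IDP), enhancement 300, exogenous rate 450 1/s; the
#'   noise level is calibrated with [noise_sigma_for_trace_snr()] so the
#'   weakest of the 50 strongest indirect-dimension traces has SNR 20.
#' * `"r5_like"` -- a 19-residue peptide, same conditions.
#' * `"single_peak"` -- two resonances of which exactly one exchanges fast
#'   enough to be detected; noiseless, unit enhancement.
#'
#' @param name Scenario id.
#' @param seed Integer seed.
#' @param dir Directory for the container files; default `tempdir()`.
#' @return Invisibly, a list with `intrinsic` and `hyperpolarized` file
#'   paths, the in-memory objects, and `truth` (decay model, noise_sigma,
#'   scheme, resonances).
#' @export
make_fixture <- function(name, seed = 1L, dir = tempdir()) {
  scenarios <- c("opn_like", "r5_like", "single_peak")
  if (!is.character(name) || length(name) != 1L || !(name %in% scenarios))
    stop_hw("unknown scenario '", paste(name, collapse = ","),
            "'; available: ", paste(scenarios, collapse = ", "),
            class = "hw_domain_error")
  scheme <- acq_scheme(64L, 2e-4, 200L, 5e-4, scans_per_fid = 2L,
                       recycle_delay = 0.1, acq_window = 0.1)
  cfg <- switch(name,
    opn_like = list(n = 50L, ranges = list(r2_ind = c(50, 50)), wf = 0.02,
                    model = decay_model(epsilon = 300, rate = 450),
                    trace_snr = 20),
    r5_like = list(n = 19L, ranges = list(r2_ind = c(50, 50)), wf = 0.02,
                   model = decay_model(epsilon = 300, rate = 450),
                   trace_snr = 20),
    single_peak = list(n = 2L,
                       ranges = list(f1 = c(500, 500), f2 = c(300, 300),
                                     r2_ind = c(50, 50), r2_dir = c(40, 40),
                                     amplitude = c(1, 1), kex = c(1, 10)),
                       wf = 1,
                       model = decay_model(epsilon = 1, rate = 450),
                       noise_sigma = 0)
  )
  res <- sample_resonances(cfg$n, ranges = cfg$ranges,
                           seed = derive_seed(seed, 11), scheme = scheme)
  if (name == "single_peak") {
    # pin one resonance below and one above the exchange threshold
    res$kex <- c(1, 10)
    res$f1 <- c(-700, 500)
  }
  intrinsic <- synthesize_intrinsic(res, scheme, water_fraction = cfg$wf)
  noise_sigma <- if (is.null(cfg$trace_snr)) cfg$noise_sigma else
    noise_sigma_for_trace_snr(intrinsic, cfg$model,
                              target_snr = cfg$trace_snr, n_traces = 50L)
  hyper <- distort(intrinsic, cfg$model, noise_sigma = noise_sigma,
                   seed = derive_seed(seed, 12))
  hyper$meta$scenario <- name
  intrinsic$meta$scenario <- name
  p_int <- file.path(dir, sprintf("%s_seed%d_intrinsic.json", name, seed))
  p_hyp <- file.path(dir, sprintf("%s_seed%d_hyperpolarized.json", name, seed))
  write_dataset(p_int, intrinsic)
  write_dataset(p_hyp, hyper)
  invisible(list(
    intrinsic = p_int, hyperpolarized = p_hyp,
    intrinsic_ifg = intrinsic, hyperpolarized_ifg = hyper,
    truth = list(model = cfg$model, noise_sigma = noise_sigma,
                 scheme = scheme, resonances = res, water_fraction = cfg$wf)
  ))
}

#' Read a simulation scenario configuration file
#'
#' YAML key-value schema:
#' ```
#' scheme:   {n_t1_complex, dt1, n_t2, dt2, scans_per_fid, recycle_delay,
#'            acq_window}
#' resonances: {n_resonances, seed, ranges: {f1: [lo, hi], f2: [...], r2_ind: [...],
#'              r2_dir: [...], amplitude: [...], kex: [...]}}
#' water_fraction: 0.02
#' kex_threshold: 2
#' decay:    {epsilon, rate, offset}
#' noise_sigma: 0.05
#' seed: 1
#' ```
#' Missing blocks fall back to the `"opn_like"` defaults.
#'
#' @param path YAML file.
#' @return A named list ready for [run_scenario()].
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path))
    stop_hw("no such config file: ", path, class = "hw_format_error")
  cfg <- yaml::read_yaml(path)
  defaults <- list(
    scheme = list(n_t1_complex = 64L, dt1 = 2e-4, n_t2 = 200L, dt2 = 5e-4,
                  scans_per_fid = 2L, recycle_delay = 0.1, acq_window = 0.1),
    resonances = list(n_resonances = 50L, seed = 1L, ranges = list()),
    water_fraction = 0.02,
    kex_threshold = 2,
    decay = list(epsilon = 300, rate = 450, offset = 0),
    noise_sigma = 0.05,
    seed = 1L
  )
  modifyList(defaults, cfg %||% list())
}

#' Run a simulation scenario
#'
#' @param cfg A list from [read_scenario_config()] (or built directly).
#' @return List with `intrinsic` and `hyperpolarized` interferograms.
#' @export
run_scenario <- function(cfg) {
  s <- cfg$scheme
  scheme <- acq_scheme(s$n_t1_complex, s$dt1, s$n_t2, s$dt2,
                       s$scans_per_fid, s$recycle_delay, s$acq_window)
  ranges <- lapply(cfg$resonances$ranges, unlist)
  res <- sample_resonances(cfg$resonances$n_resonances, ranges = ranges,
                           seed = cfg$resonances$seed, scheme = scheme)
  intrinsic <- synthesize_intrinsic(res, scheme,
                                    water_fraction = cfg$water_fraction,
                                    kex_threshold = cfg$kex_threshold)
  model <- decay_model(cfg$decay$epsilon, cfg$decay$rate,
                       cfg$decay$offset %||% 0)
  hyper <- distort(intrinsic, model, noise_sigma = cfg$noise_sigma,
                   seed = cfg$seed)
  list(intrinsic = intrinsic, hyperpolarized = hyper)
}
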