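#' Configuration for the training corpus of the rate estimator
#'
#' The corpus pairs intrinsic indirect-dimension traces `I(t1)` with a
#' synthetic exogenous envelope: each example is
#' `T(t1) = I(t1) * eps * exp(-R * t1) + noise`, labelled with the drawn
#' rate `R`. Enhancements, rates and noise levels are each drawn uniformly
#' and independently from their intervals. Defaults bracket the regimes seen
#' in hyperpolarized-water protein work: rates 50--1000 1/s around the
#' typical ~450 1/s, enhancements 1--700, relative noise up to 0.2.
#'
#' @param n_examples Number of labelled traces; default 100000.
#' @param rate_range `c(low, high)` training rates in 1/s.
#' @param eps_range `c(low, high)` training enhancements.
#' @param noise_sigma_range `c(low, high)` noise level relative to each
#'   clean trace's maximum magnitude.
#' @param seed Integer seed; the whole corpus is reproducible from it.
#' @return An object of class `hw_training_config`.
#' @export
training_config <- function(n_examples = 100000L,
                            rate_range = c(50, 1000),
                            eps_range = c(1, 700),
                            noise_sigma_range = c(1e-4, 0.2),
                            seed = 1L) {
  chk_range <- function(r, name, lower = 0) {
    if (!is.numeric(r) || length(r) != 2L || !all(is.finite(r)) ||
        r[1] > r[2] || r[1] < lower)
      stop_hw(name, " must be an ordered interval with low >= ", lower,
              class = "hw_domain_error")
    as.numeric(r)
  }
  structure(list(
    n_examples = check_count(n_examples, "n_examples"),
    rate_range = chk_range(rate_range, "rate_range"),
    eps_range = chk_range(eps_range, "eps_range"),
    noise_sigma_range = chk_range(noise_sigma_range, "noise_sigma_range"),
    seed = check_count(seed, "seed", lower = 0L)
  ), class = "hw_training_config")
}

#' Default synthetic source of intrinsic indirect-dimension traces
#'
#' Returns a generator closure that, for each integer it is called with,
#' synthesizes a fresh intrinsic interferogram from a newly drawn resonance
#' set. Used by [build_training_set()] when no measured interferogram is
#' supplied.
#'
#' @param scheme An [acq_scheme()].
#' @param n_resonances Resonances per generated set; default 50.
#' @param ranges Resonance sampling intervals, see [sample_resonances()].
#' @return A function `f(seed)` returning an intrinsic [interferogram()].
#' @export
intrinsic_generator <- function(scheme, n_resonances = 50L, ranges = list()) {
  force(scheme); force(n_resonances); force(ranges)
  function(seed) {
    res <- sample_resonances(n_resonances, ranges = ranges, seed = seed,
                             scheme = scheme)
    synthesize_intrinsic(res, scheme)
  }
}

#' Build the labelled training corpus for the rate estimator
#'
#' Draws intrinsic traces (indirect-dimension columns after the direct
#' Fourier transform, see [indirect_traces()]) from the supplied source,
#' multiplies each by an exogenous envelope with a freshly drawn rate and
#' enhancement, adds complex Gaussian noise, and labels the example with the
#' drawn rate. Generation is bitwise reproducible from `config$seed`.
#'
#' @param intrinsic_source Either an intrinsic [interferogram()] (measured
#'   or synthetic) whose usable columns are resampled, or a generator
#'   function as returned by [intrinsic_generator()].
#' @param config A [training_config()].
#' @param scheme Required when `intrinsic_source` is a generator function or
#'   `NULL`; ignored otherwise. With `intrinsic_source = NULL`, the default
#'   [intrinsic_generator()] for `scheme` is used.
#' @param traces_per_block For generator sources, how many examples to draw
#'   from each freshly synthesized interferogram before generating the next.
#' @return An object of class `hw_training_set`: complex trace matrix
#'   (`n_t1_complex` x `n_examples`), numeric `labels` in 1/s, the t1 grid,
#'   and provenance.
#' @export
build_training_set <- function(intrinsic_source = NULL, config = training_config(),
                               scheme = NULL, traces_per_block = 256L) {
  stopifnot(inherits(config, "hw_training_config"))
  n <- config$n_examples
  if (is.null(intrinsic_source)) {
    if (is.null(scheme))
      stop_hw("scheme is required when intrinsic_source is NULL",
              class = "hw_domain_error")
    intrinsic_source <- intrinsic_generator(scheme)
  }

  usable_cols <- function(ifg) {
    tr <- indirect_traces(ifg)
    keep <- tr$energy > 1e-6 * max(tr$energy)
    if (max(tr$energy) == 0 || !any(keep)) return(NULL)
    tr$traces[, keep, drop = FALSE]
  }

  withr_seed(config$seed, {
    if (inherits(intrinsic_source, "hw_interferogram")) {
      pool <- usable_cols(intrinsic_source)
      if (is.null(pool))
        stop_hw("intrinsic source yields only all-zero traces",
                class = "hw_domain_error")
      n_t1 <- nrow(pool)
      dt1 <- intrinsic_source$scheme$dt1
      traces <- pool[, sample.int(ncol(pool), n, replace = TRUE),
                     drop = FALSE]
    } else if (is.function(intrinsic_source)) {
      blocks <- ceiling(n / traces_per_block)
      out <- vector("list", blocks)
      first <- NULL
      for (b in seq_len(blocks)) {
        ifg <- intrinsic_source(derive_seed(config$seed, b))
        if (is.null(first)) first <- ifg
        pool <- usable_cols(ifg)
        if (is.null(pool))
          stop_hw("intrinsic source yields only all-zero traces",
                  class = "hw_domain_error")
        take <- min(traces_per_block, n - (b - 1L) * traces_per_block)
        out[[b]] <- pool[, sample.int(ncol(pool), take, replace = TRUE),
                         drop = FALSE]
      }
      traces <- do.call(cbind, out)
      n_t1 <- nrow(traces)
      dt1 <- first$scheme$dt1
    } else {
      stop_hw("intrinsic_source must be an interferogram or a function",
              class = "hw_domain_error")
    }

    t1 <- (seq_len(n_t1) - 1L) * dt1
    labels <- runif(n, config$rate_range[1], config$rate_range[2])
    eps <- runif(n, config$eps_range[1], config$eps_range[2])
    sig <- runif(n, config$noise_sigma_range[1], config$noise_sigma_range[2])

    # clean = I(t1) * eps * exp(-R t1), column-wise
    env <- exp(-outer(t1, labels))
    clean <- traces * env * rep(eps, each = n_t1)
    maxmod <- apply(Mod(clean), 2L, max)
    if (any(maxmod == 0))
      stop_hw("intrinsic source yields only all-zero traces",
              class = "hw_domain_error")
    sd_abs <- rep(sig * maxmod, each = n_t1)
    noise <- complex(real = rnorm(n_t1 * n) * sd_abs,
                     imaginary = rnorm(n_t1 * n) * sd_abs)
    examples <- clean + matrix(noise, n_t1, n)

    structure(list(
      traces = examples, labels = labels, t1 = t1, dt1 = dt1,
      n_t1 = n_t1, t1_max = n_t1 * dt1, config = config,
      provenance = sprintf("build_training_set: n=%d seed=%d generator=%s",
                           n, config$seed,
                           as.character(packageVersion("hyperwdecon")))
    ), class = "hw_training_set")
  })
}

#' @export
print.hw_training_set <- function(x, ...) {
  cat(sprintf("<hw_training_set> %d examples of %d complex points\n",
              length(x$labels), x$n_t1))
  cat(sprintf("  labels in [%.3g, %.3g] 1/s; t1_max = %g s\n",
              min(x$labels), max(x$labels), x$t1_max))
  invisible(x)
}
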