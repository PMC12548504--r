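#' Extract complex indirect-dimension traces from an interferogram
#'
#' Applies the direct-dimension Fourier transform to both hypercomplex
#' components and recombines them States-style: the complex t1 trace at each
#' direct-dimension frequency is `Re(FT_t2(cos)) + i Re(FT_t2(sin))`. For a
#' zero-phase resonance this is a one-sided damped complex exponential in
#' t1 -- the "FID along t1" that the rate estimator consumes.
#'
#' @param ifg An [interferogram()].
#' @return A list with `traces` (complex matrix, `n_t1_complex` rows, one
#'   column per direct-dimension frequency), `axis2` (frequency axis in Hz)
#'   and `energy` (per-column summed squared magnitude).
#' @export
indirect_traces <- function(ifg) {
  stopifnot(inherits(ifg, "hw_interferogram"))
  sh <- fftshift_idx(ifg$scheme$n_t2)
  ft2 <- function(m) t(stats::mvfft(t(m)))[, sh, drop = FALSE]
  fc <- ft2(ifg$cos)
  fs <- ft2(ifg$sin)
  traces <- matrix(complex(real = Re(fc), imaginary = Re(fs)),
                   nrow = nrow(fc))
  list(traces = traces,
       axis2 = freq_axis(ifg$scheme$n_t2, ifg$scheme$dt2),
       energy = colSums(Mod(traces)^2))
}
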