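#' Acquisition scheme of a 2D hypercomplex experiment
#'
#' Timing and counting parameters of a States-type 2D experiment: the number
#' of complex indirect-dimension increments and their dwell time, the direct
#' dimension grid, scans per FID and the inter-scan recycle delay.
#'
#' @param n_t1_complex Number of complex indirect (t1) increments.
#' @param dt1 Indirect dwell time in seconds (indirect spectral width is
#'   `1/dt1` Hz).
#' @param n_t2 Number of direct-dimension points.
#' @param dt2 Direct dwell time in seconds.
#' @param scans_per_fid Scans averaged per FID (NS).
#' @param recycle_delay Inter-scan recycle delay in seconds.
#' @param acq_window Direct acquisition time per scan in seconds.
#'
#' @return An object of class `hw_scheme`.
#' @examples
#' sch <- acq_scheme(64, 2e-4, 200, 5e-4)
#' t1_max(sch)                 # 12.8 ms
#' acquisition_duration(sch)   # ~51 s at 2 scans
#' @export
acq_scheme <- function(n_t1_complex, dt1, n_t2, dt2,
                       scans_per_fid = 2L, recycle_delay = 0.1,
                       acq_window = 0.1) {
  out <- list(
    n_t1_complex = check_count(n_t1_complex, "n_t1_complex"),
    dt1 = check_number(dt1, "dt1", lower = 0, allow_zero = FALSE),
    n_t2 = check_count(n_t2, "n_t2"),
    dt2 = check_number(dt2, "dt2", lower = 0, allow_zero = FALSE),
    scans_per_fid = check_count(scans_per_fid, "scans_per_fid"),
    recycle_delay = check_number(recycle_delay, "recycle_delay",
                                 lower = 0, allow_zero = FALSE),
    acq_window = check_number(acq_window, "acq_window",
                              lower = 0, allow_zero = FALSE)
  )
  structure(out, class = "hw_scheme")
}

#' @rdname acq_scheme
#' @param scheme An `hw_scheme`.
#' @export
t1_max <- function(scheme) {
  stopifnot(inherits(scheme, "hw_scheme"))
  scheme$n_t1_complex * scheme$dt1
}

# t1/t2 sampling grids start at zero, the NMR convention for FIDs
t1_grid <- function(scheme) (seq_len(scheme$n_t1_complex) - 1L) * scheme$dt1
t2_grid <- function(scheme) (seq_len(scheme$n_t2) - 1L) * scheme$dt2

#' Wall-clock duration of a hypercomplex 2D acquisition
#'
#' Each complex increment is recorded twice (cosine- and sine-modulated
#' component), each component averaged over `scans_per_fid` scans, and each
#' scan costs the recycle delay plus the direct acquisition window.
#'
#' @param scheme An [acq_scheme()].
#' @return Total acquisition time in seconds.
#' @examples
#' acquisition_duration(acq_scheme(64, 2e-4, 200, 5e-4, scans_per_fid = 2))
#' @export
acquisition_duration <- function(scheme) {
  stopifnot(inherits(scheme, "hw_scheme"))
  scheme$n_t1_complex * 2 * scheme$scans_per_fid *
    (scheme$recycle_delay + scheme$acq_window)
}

#' @export
print.hw_scheme <- function(x, ...) {
  cat(sprintf(
    "<hw_scheme> %d complex t1 increments x %d t2 points\n", x$n_t1_complex,
    x$n_t2))
  cat(sprintf("  dt1 = %g s (SW1 %g Hz), dt2 = %g s (SW2 %g Hz)\n",
              x$dt1, 1 / x$dt1, x$dt2, 1 / x$dt2))
  cat(sprintf("  NS = %d, recycle %g s, acq window %g s -> %.1f s total\n",
              x$scans_per_fid, x$recycle_delay, x$acq_window,
              acquisition_duration(x)))
  invisible(x)
}
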