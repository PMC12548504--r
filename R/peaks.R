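#' Pick peaks in a 2D spectrum
#'
#' Finds local maxima (over the 8-neighbourhood) whose height exceeds
#' `threshold` times a robust noise estimate (the median absolute deviation
#' of all intensities) and, to suppress truncation ripples in noiseless
#' simulations, also `min_height_frac` of the global maximum. Maxima are
#' accepted greedily in height-descending order with `(f1, f2)` lexicographic
#' tie-break; any candidate within `min_separation` bins (Chebyshev
#' distance) of an accepted peak is suppressed. Centres are refined to
#' sub-bin precision by parabolic interpolation along each axis.
#'
#' @param spec An [process_spectrum()] result.
#' @param threshold Multiple of the noise standard deviation; default 5.
#' @param min_separation Minimum separation between peaks in bins; default 2.
#' @param min_height_frac Relative height floor; default 0.01.
#' @param measure_widths If `TRUE` (default), fill `fwhm1`/`fwhm2` via
#'   [measure_fwhm()] (NA where a half-height crossing is missing).
#' @return A tibble of class `hw_peaks` with columns `f1`, `f2` (Hz),
#'   `height`, `fwhm1`, `fwhm2` (Hz), `i1`, `i2` (bin indices), ordered by
#'   descending height. The noise estimate is attached as attribute
#'   `noise_sd`. An empty tibble is a valid result.
#' @export
pick_peaks <- function(spec, threshold = 5, min_separation = 2L,
                       min_height_frac = 0.01, measure_widths = TRUE) {
  stopifnot(inherits(spec, "hw_spectrum2d"))
  threshold <- check_number(threshold, "threshold", lower = 0,
                            allow_zero = FALSE)
  min_separation <- check_count(min_separation, "min_separation", lower = 0L)
  z <- spec$intensity
  if (!all(is.finite(z)))
    stop_hw("spectrum contains non-finite intensities",
            class = "hw_domain_error")
  noise_sd <- stats::mad(z)
  floor_abs <- max(threshold * noise_sd, min_height_frac * max(z))

  n1 <- nrow(z); n2 <- ncol(z)
  cand <- which(z > floor_abs, arr.ind = TRUE)
  is_max <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    i <- cand[k, 1L]; j <- cand[k, 2L]
    nb <- z[max(1L, i - 1L):min(n1, i + 1L),
            max(1L, j - 1L):min(n2, j + 1L)]
    is_max[k] <- z[i, j] == max(nb) && sum(nb == z[i, j]) == 1L
  }
  cand <- cand[is_max, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty_peaks(noise_sd))

  h <- z[cand]
  ord <- order(-h, spec$axis1[cand[, 1L]], spec$axis2[cand[, 2L]])
  cand <- cand[ord, , drop = FALSE]
  h <- h[ord]
  taken <- matrix(NA_integer_, 0L, 2L)
  keep <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (nrow(taken) == 0L ||
        all(pmax(abs(taken[, 1L] - cand[k, 1L]),
                 abs(taken[, 2L] - cand[k, 2L])) > min_separation)) {
      keep[k] <- TRUE
      taken <- rbind(taken, cand[k, , drop = FALSE])
    }
  }
  cand <- cand[keep, , drop = FALSE]
  h <- h[keep]

  d1 <- spec$axis1[2L] - spec$axis1[1L]
  d2 <- spec$axis2[2L] - spec$axis2[1L]
  refine <- function(i, j) {
    s1 <- if (i > 1L && i < n1)
      parabolic_offset(z[i - 1L, j], z[i, j], z[i + 1L, j]) else 0
    s2 <- if (j > 1L && j < n2)
      parabolic_offset(z[i, j - 1L], z[i, j], z[i, j + 1L]) else 0
    hh <- z[i, j]
    if (i > 1L && i < n1)
      hh <- max(hh, parabolic_height(z[i - 1L, j], z[i, j], z[i + 1L, j]))
    c(spec$axis1[i] + s1 * d1, spec$axis2[j] + s2 * d2, hh)
  }
  ref <- t(vapply(seq_len(nrow(cand)),
                  function(k) refine(cand[k, 1L], cand[k, 2L]),
                  numeric(3L)))

  peaks <- tibble::tibble(
    f1 = ref[, 1L], f2 = ref[, 2L], height = ref[, 3L],
    fwhm1 = NA_real_, fwhm2 = NA_real_,
    i1 = as.integer(cand[, 1L]), i2 = as.integer(cand[, 2L])
  )
  if (measure_widths && nrow(peaks) > 0L) {
    peaks$fwhm1 <- vapply(seq_len(nrow(peaks)), function(k)
      tryCatch(measure_fwhm(spec, peaks[k, ], axis = 1L),
               error = function(e) NA_real_), numeric(1L))
    peaks$fwhm2 <- vapply(seq_len(nrow(peaks)), function(k)
      tryCatch(measure_fwhm(spec, peaks[k, ], axis = 2L),
               error = function(e) NA_real_), numeric(1L))
  }
  attr(peaks, "noise_sd") <- noise_sd
  class(peaks) <- c("hw_peaks", class(peaks))
  peaks
}

empty_peaks <- function(noise_sd) {
  peaks <- tibble::tibble(f1 = numeric(), f2 = numeric(),
                          height = numeric(), fwhm1 = numeric(),
                          fwhm2 = numeric(), i1 = integer(), i2 = integer())
  attr(peaks, "noise_sd") <- noise_sd
  class(peaks) <- c("hw_peaks", class(peaks))
  peaks
}

parabolic_offset <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (den == 0) 0 else 0.5 * (ym - yp) / den
}

parabolic_height <- function(ym, y0, yp) {
  den <- ym - 2 * y0 + yp
  if (den == 0) y0 else y0 - (ym - yp)^2 / (8 * den)
}

#' Full width at half maximum of a peak along one axis
#'
#' Takes the 1D slice through the peak's bin along the chosen axis, refines
#' the apex height by parabolic interpolation, and locates the half-height
#' crossings on both sides by linear interpolation. Model-free and stable at
#' 4x zero-fill; no line-shape fit is involved.
#'
#' @param spec An [process_spectrum()] result.
#' @param peak One row of a [pick_peaks()] tibble (or a list with `i1`,
#'   `i2`).
#' @param axis 1 (indirect) or 2 (direct).
#' @return Width in Hz.
#' @export
measure_fwhm <- function(spec, peak, axis = 1L) {
  stopifnot(inherits(spec, "hw_spectrum2d"), axis %in% c(1L, 2L))
  i1 <- as.integer(peak$i1); i2 <- as.integer(peak$i2)
  z <- spec$intensity
  if (i1 < 1L || i1 > nrow(z) || i2 < 1L || i2 > ncol(z))
    stop_hw("peak indices outside the spectrum", class = "hw_domain_error")
  if (axis == 1L) {
    y <- z[, i2]; ax <- spec$axis1; i0 <- i1
  } else {
    y <- z[i1, ]; ax <- spec$axis2; i0 <- i2
  }
  n <- length(y)
  # allow the apex bin to sit one bin off the stored index
  win <- max(1L, i0 - 2L):min(n, i0 + 2L)
  i0 <- win[which.max(y[win])]
  apex <- if (i0 > 1L && i0 < n)
    parabolic_height(y[i0 - 1L], y[i0], y[i0 + 1L]) else y[i0]
  half <- apex / 2

  cross <- function(idx_seq) {
    prev <- i0
    for (i in idx_seq) {
      if (y[i] <= half) {
        frac <- (y[prev] - half) / (y[prev] - y[i])
        return(ax[prev] + frac * (ax[i] - ax[prev]))
      }
      prev <- i
    }
    stop_hw("half-height crossing not found (truncated peak)",
            class = "hw_truncation_error")
  }
  if (i0 == 1L || i0 == n)
    stop_hw("half-height crossing not found (truncated peak)",
            class = "hw_truncation_error")
  abs(cross(seq.int(i0 + 1L, n)) - cross(seq.int(i0 - 1L, 1L)))
}

#' Signal-to-noise ratio of a peak
#'
#' Peak height divided by the standard deviation of the intensities inside a
#' user-specified signal-free box. The caller must choose a region free of
#' signals; as a guard, the box is checked against the footprint
#' (centre +/- FWHM per axis, or +/- 2 bins where no width is available) of
#' the supplied peak.
#'
#' @param spec An [process_spectrum()] result.
#' @param peak One row of a [pick_peaks()] tibble.
#' @param noise_region List with `f1 = c(lo, hi)` and `f2 = c(lo, hi)` in Hz.
#' @return Dimensionless SNR.
#' @export
compute_snr <- function(spec, peak, noise_region) {
  stopifnot(inherits(spec, "hw_spectrum2d"))
  if (!is.list(noise_region) || !all(c("f1", "f2") %in% names(noise_region)))
    stop_hw("noise_region must be list(f1 = c(lo, hi), f2 = c(lo, hi))",
            class = "hw_domain_error")
  r1 <- sort(noise_region$f1); r2 <- sort(noise_region$f2)
  d1 <- spec$axis1[2L] - spec$axis1[1L]
  d2 <- spec$axis2[2L] - spec$axis2[1L]
  w1 <- if (is.finite(peak$fwhm1 %||% NA) && !is.na(peak$fwhm1))
    peak$fwhm1 else 2 * d1
  w2 <- if (is.finite(peak$fwhm2 %||% NA) && !is.na(peak$fwhm2))
    peak$fwhm2 else 2 * d2
  if (peak$f1 + w1 > r1[1] && peak$f1 - w1 < r1[2] &&
      peak$f2 + w2 > r2[1] && peak$f2 - w2 < r2[2])
    stop_hw("noise region overlaps the peak footprint",
            class = "hw_domain_error")
  sel1 <- spec$axis1 >= r1[1] & spec$axis1 <= r1[2]
  sel2 <- spec$axis2 >= r2[1] & spec$axis2 <= r2[2]
  if (sum(sel1) * sum(sel2) < 2L)
    stop_hw("noise region contains fewer than 2 bins",
            class = "hw_domain_error")
  s <- stats::sd(spec$intensity[sel1, sel2])
  if (s == 0)
    stop_hw("noise region has zero standard deviation (noiseless spectrum)",
            class = "hw_domain_error")
  peak$height / s
}

#' Enhancement factors from SNR and measurement-time pairs
#'
#' `epsilon_star` is the plain SNR ratio between the hyperpolarized and the
#' conventional spectrum; `epsilon` additionally normalizes for measurement
#' time, which SNR repays as its square root:
#' `epsilon = epsilon_star * sqrt(time_c / time_h)`.
#'
#' @param snr_h,time_h SNR and measurement time (s) of the hyperpolarized
#'   spectrum.
#' @param snr_c,time_c SNR and measurement time (s) of the conventional
#'   spectrum.
#' @return Named list with `epsilon` and `epsilon_star`.
#' @examples
#' enhancement_factors(snr_h = 50, time_h = 50, snr_c = 10, time_c = 4800)
#' @export
enhancement_factors <- function(snr_h, time_h, snr_c, time_c) {
  for (nm in c("snr_h", "time_h", "snr_c", "time_c")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop_hw(nm, " must be a single positive number",
              class = "hw_domain_error")
  }
  eps_star <- snr_h / snr_c
  list(epsilon = eps_star * sqrt(time_c / time_h), epsilon_star = eps_star)
}

#' Match peaks between two spectra
#'
#' Picks peaks in both spectra and matches them greedily: peaks of `a` are
#' visited in height-descending order and each takes the nearest unmatched
#' peak of `b` within `match_tol` Hz per axis. Unmatched peaks on both sides
#' are reported.
#'
#' @param a,b [process_spectrum()] results with overlapping axis ranges.
#' @param match_tol Tolerance in Hz; length 1 (both axes) or 2 `c(f1, f2)`.
#' @param ... Passed to [pick_peaks()].
#' @return An object of class `hw_pairing`: `pairs` (tibble with positions,
#'   per-axis deltas `d_f1`/`d_f2`, heights and width ratios
#'   `fwhm1_ratio`/`fwhm2_ratio` = b/a), `unmatched_a`, `unmatched_b`.
#' @export
compare_spectra <- function(a, b, match_tol, ...) {
  stopifnot(inherits(a, "hw_spectrum2d"), inherits(b, "hw_spectrum2d"))
  if (max(a$axis1) < min(b$axis1) || max(b$axis1) < min(a$axis1) ||
      max(a$axis2) < min(b$axis2) || max(b$axis2) < min(a$axis2))
    stop_hw("spectra have disjoint axis ranges", class = "hw_domain_error")
  if (length(match_tol) == 1L) match_tol <- rep(match_tol, 2L)
  pa <- pick_peaks(a, ...)
  pb <- pick_peaks(b, ...)
  used_b <- logical(nrow(pb))
  rows <- list()
  for (k in seq_len(nrow(pa))) {
    d1 <- pb$f1 - pa$f1[k]
    d2 <- pb$f2 - pa$f2[k]
    ok <- !used_b & abs(d1) <= match_tol[1] & abs(d2) <= match_tol[2]
    if (!any(ok)) next
    j <- which(ok)[which.min((d1[ok] / match_tol[1])^2 +
                               (d2[ok] / match_tol[2])^2)]
    used_b[j] <- TRUE
    rows[[length(rows) + 1L]] <- tibble::tibble(
      f1_a = pa$f1[k], f2_a = pa$f2[k], f1_b = pb$f1[j], f2_b = pb$f2[j],
      d_f1 = d1[j], d_f2 = d2[j],
      height_a = pa$height[k], height_b = pb$height[j],
      fwhm1_ratio = pb$fwhm1[j] / pa$fwhm1[k],
      fwhm2_ratio = pb$fwhm2[j] / pa$fwhm2[k],
      idx_a = k, idx_b = j
    )
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else tibble::tibble(
    f1_a = numeric(), f2_a = numeric(), f1_b = numeric(), f2_b = numeric(),
    d_f1 = numeric(), d_f2 = numeric(), height_a = numeric(),
    height_b = numeric(), fwhm1_ratio = numeric(), fwhm2_ratio = numeric(),
    idx_a = integer(), idx_b = integer())
  structure(list(
    pairs = pairs,
    unmatched_a = pa[setdiff(seq_len(nrow(pa)), pairs$idx_a), , drop = FALSE],
    unmatched_b = pb[!used_b, , drop = FALSE],
    match_tol = match_tol
  ), class = "hw_pairing")
}

#' @export
print.hw_pairing <- function(x, ...) {
  cat(sprintf("<hw_pairing> %d matched, %d unmatched in a, %d in b\n",
              nrow(x$pairs), nrow(x$unmatched_a), nrow(x$unmatched_b)))
  if (nrow(x$pairs) > 0L)
    cat(sprintf("  |d_f1| max %.3g Hz, |d_f2| max %.3g Hz\n",
                max(abs(x$pairs$d_f1)), max(abs(x$pairs$d_f2))))
  invisible(x)
}

#' Write / read peak lists and pairing tables as TSV
#'
#' Tab-separated files with a header row. Peak lists carry
#' `f1_hz f2_hz height fwhm1_hz fwhm2_hz snr`; pairing tables carry the
#' columns of `pairs` from [compare_spectra()].
#'
#' @param peaks An `hw_peaks` tibble (an `snr` column is written as NA if
#'   absent).
#' @param path Output file.
#' @return `path`, invisibly (writers); a tibble (reader).
#' @export
write_peaks_tsv <- function(peaks, path) {
  df <- data.frame(
    f1_hz = peaks$f1, f2_hz = peaks$f2, height = peaks$height,
    fwhm1_hz = peaks$fwhm1, fwhm2_hz = peaks$fwhm2,
    snr = if ("snr" %in% names(peaks)) peaks$snr else NA_real_
  )
  write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks_tsv
#' @param pairing An `hw_pairing` from [compare_spectra()].
#' @export
write_pairing_tsv <- function(pairing, path) {
  write.table(as.data.frame(pairing$pairs), path, sep = "\t",
              row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peaks_tsv
#' @export
read_peaks_tsv <- function(path) {
  tibble::as_tibble(read.table(path, header = TRUE, sep = "\t"))
}
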