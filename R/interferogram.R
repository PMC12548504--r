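#' Hypercomplex 2D interferogram
#'
#' A States-type 2D time-domain dataset: two complex matrices holding the
#' cosine- and sine-modulated components, each `n_t1_complex x n_t2`, plus
#' the acquisition scheme, a role tag, and free-form metadata.
#'
#' Roles track provenance through the pipeline: `intrinsic` data are
#' undistorted (thermal-equilibrium-like), `hyperpolarized` data carry the
#' exogenous decay envelope (and possibly noise), `deconvolved` data have had
#' the envelope divided out, and `training` marks corpora material. Role
#' transitions are enforced by [apply_decay()] (intrinsic to hyperpolarized)
#' and [remove_decay()] (hyperpolarized to deconvolved).
#'
#' @param cos_comp,sin_comp Complex matrices, `n_t1_complex x n_t2`; rows are
#'   indirect-time increments, columns direct-dimension samples.
#' @param scheme An [acq_scheme()].
#' @param role One of `"intrinsic"`, `"hyperpolarized"`, `"training"`,
#'   `"deconvolved"`.
#' @param meta Named list; recognised entries include `water_fraction`
#'   (0--1), `seed`, `decay_model` (ground truth for synthetic data) and
#'   `provenance` (character log).
#'
#' @return An object of class `hw_interferogram`.
#' @export
interferogram <- function(cos_comp, sin_comp, scheme,
                          role = c("intrinsic", "hyperpolarized",
                                   "training", "deconvolved"),
                          meta = list()) {
  role <- match.arg(role)
  stopifnot(inherits(scheme, "hw_scheme"))
  cos_comp <- as_complex_matrix(cos_comp, "cos_comp")
  sin_comp <- as_complex_matrix(sin_comp, "sin_comp")
  dims <- c(scheme$n_t1_complex, scheme$n_t2)
  if (!identical(dim(cos_comp), dims) || !identical(dim(sin_comp), dims))
    stop_hw("component dimensions do not match the acquisition scheme (",
            dims[1], " x ", dims[2], ")", class = "hw_shape_error")
  if (!all(is.finite(Re(cos_comp)), is.finite(Im(cos_comp)),
           is.finite(Re(sin_comp)), is.finite(Im(sin_comp))))
    stop_hw("interferogram contains non-finite values",
            class = "hw_domain_error")
  structure(
    list(cos = cos_comp, sin = sin_comp, scheme = scheme, role = role,
         meta = meta),
    class = "hw_interferogram"
  )
}

as_complex_matrix <- function(x, name) {
  if (!is.matrix(x))
    stop_hw(name, " must be a matrix", class = "hw_shape_error")
  if (!is.complex(x)) storage.mode(x) <- "complex"
  x
}

#' @export
print.hw_interferogram <- function(x, ...) {
  cat(sprintf("<hw_interferogram> role '%s', %d x %d hypercomplex\n",
              x$role, nrow(x$cos), ncol(x$cos)))
  if (!is.null(x$meta$water_fraction))
    cat(sprintf("  water_fraction = %g\n", x$meta$water_fraction))
  if (!is.null(x$meta$decay_model))
    cat(sprintf("  ground-truth decay: eps = %g, rate = %g 1/s\n",
                x$meta$decay_model$epsilon, x$meta$decay_model$rate))
  cat(sprintf("  max |signal| = %.4g\n", ifg_max_mod(x)))
  invisible(x)
}

ifg_max_mod <- function(ifg) max(Mod(ifg$cos), Mod(ifg$sin))

# append a line to the provenance log carried in meta
log_provenance <- function(ifg, line) {
  ifg$meta$provenance <- c(ifg$meta$provenance, line)
  ifg
}
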