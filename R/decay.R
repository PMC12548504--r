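#' Exogenous decay envelope of a hyperpolarized 2D experiment
#'
#' The envelope `E(t1) = epsilon * exp(-rate * t1) + offset` that the
#' decaying water hyperpolarization imprints on every indirect-dimension
#' trace. `epsilon` is the (dimensionless) signal enhancement at `t1 = 0`
#' and `rate` the effective exogenous decay rate on the t1 axis, in 1/s.
#' Experimental reports often quote the rate in 1/ms; multiply by 1000 when
#' passing such values here (0.45 1/ms = 450 1/s). The offset defaults to
#' exactly 0: at large enhancements the residual thermal polarization is
#' negligible; a nonzero offset is retained as a field for the
#' small-enhancement regime.
#'
#' @param epsilon Enhancement at `t1 = 0`; must be positive.
#' @param rate Exogenous decay rate in 1/s on the t1 axis; non-negative.
#' @param offset Dimensionless baseline; non-negative, default 0.
#' @return An object of class `hw_decay_model`.
#' @examples
#' m <- decay_model(epsilon = 300, rate = 450)
#' evaluate_decay(m, c(0, 1e-3, 5e-3))
#' @export
decay_model <- function(epsilon = 1, rate = 0, offset = 0) {
  structure(
    list(
      epsilon = check_number(epsilon, "epsilon", lower = 0, allow_zero = FALSE),
      rate = check_number(rate, "rate", lower = 0),
      offset = check_number(offset, "offset", lower = 0)
    ),
    class = "hw_decay_model"
  )
}

#' @export
print.hw_decay_model <- function(x, ...) {
  cat(sprintf("<hw_decay_model> E(t1) = %g * exp(-%g * t1) + %g\n",
              x$epsilon, x$rate, x$offset))
  invisible(x)
}

#' Evaluate the exogenous decay envelope on a time grid
#'
#' @param model An [decay_model()].
#' @param times Non-negative times in seconds.
#' @return `epsilon * exp(-rate * times) + offset`, strictly positive and
#'   non-increasing in `times`.
#' @export
evaluate_decay <- function(model, times) {
  stopifnot(inherits(model, "hw_decay_model"))
  if (!is.numeric(times) || !all(is.finite(times)))
    stop_hw("times must be finite numbers", class = "hw_domain_error")
  if (any(times < 0))
    stop_hw("negative times are outside the decay-model domain",
            class = "hw_domain_error")
  model$epsilon * exp(-model$rate * times) + model$offset
}

#' Imprint the exogenous decay on an intrinsic interferogram
#'
#' Multiplies every row (fixed t1 increment) of both hypercomplex components
#' by the envelope value at that increment's t1. Polarization loss is
#' phase-independent, so the cosine- and sine-modulated components are scaled
#' identically. The input role must be `intrinsic`; the output role is
#' `hyperpolarized` and the model is recorded in the metadata as ground
#' truth.
#'
#' @param ifg An `intrinsic` [interferogram()].
#' @param model A [decay_model()].
#' @return A `hyperpolarized` interferogram.
#' @seealso [remove_decay()] for the inverse, [distort()] to also add noise.
#' @export
apply_decay <- function(ifg, model) {
  stopifnot(inherits(ifg, "hw_interferogram"))
  if (ifg$role != "intrinsic")
    stop_hw("apply_decay expects an 'intrinsic' interferogram, got '",
            ifg$role, "'", class = "hw_role_error")
  env <- evaluate_decay(model, t1_grid(ifg$scheme))
  out <- ifg
  out$cos <- ifg$cos * env
  out$sin <- ifg$sin * env
  out$role <- "hyperpolarized"
  out$meta$decay_model <- model
  log_provenance(out, sprintf(
    "apply_decay: epsilon=%g rate=%g offset=%g", model$epsilon, model$rate,
    model$offset))
}

#' Divide out the exogenous decay from a hyperpolarized interferogram
#'
#' Each row is divided by `exp(-rate * t1)`; the enhancement `epsilon` is a
#' global scalar that does not affect line shape and is deliberately NOT
#' divided out, so the recovered data keep the sensitivity gain. With
#' `max_gain` set, the division factor `exp(+rate * t1)` is clamped at that
#' value, limiting how much late-t1 noise is amplified.
#'
#' @param ifg A `hyperpolarized` [interferogram()].
#' @param rate Decay rate to remove, in 1/s; non-negative.
#' @param max_gain Optional cap (> 1) on the division factor.
#' @return A `deconvolved` interferogram; provenance records rate and clamp.
#' @export
remove_decay <- function(ifg, rate, max_gain = NULL) {
  stopifnot(inherits(ifg, "hw_interferogram"))
  if (ifg$role != "hyperpolarized")
    stop_hw("remove_decay expects a 'hyperpolarized' interferogram, got '",
            ifg$role, "'", class = "hw_role_error")
  rate <- check_number(rate, "rate", lower = 0)
  gain <- exp(rate * t1_grid(ifg$scheme))
  if (!is.null(max_gain)) {
    max_gain <- check_number(max_gain, "max_gain", lower = 1)
    gain <- pmin(gain, max_gain)
  }
  if (!all(is.finite(gain)))
    stop_hw("division factor overflows; set max_gain",
            class = "hw_domain_error")
  out <- ifg
  out$cos <- ifg$cos * gain
  out$sin <- ifg$sin * gain
  if (!all(is.finite(Re(out$cos)), is.finite(Re(out$sin))))
    stop_hw("non-finite result in remove_decay", class = "hw_domain_error")
  out$role <- "deconvolved"
  out$meta$removed_rate <- rate
  out$meta$max_gain <- max_gain
  log_provenance(out, sprintf("remove_decay: rate=%g max_gain=%s", rate,
                              if (is.null(max_gain)) "none" else max_gain))
}
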