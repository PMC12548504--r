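#' Featurize a complex indirect-dimension trace
#'
#' Normalizes the trace by its maximum magnitude and concatenates the real
#' and imaginary parts into a fixed-length real vector. The encoding is
#' scale-invariant (`featurize(c * trace)` equals `featurize(trace)` for any
#' `c > 0`), which makes the downstream rate estimator independent of the
#' enhancement; the discarded scale is stored alongside the features.
#'
#' @param trace Complex (or real) vector, the t1-domain trace.
#' @param n_expected Optional expected trace length; mismatch is an error.
#' @return An object of class `hw_features`: `values` (length
#'   `2 * length(trace)`) and `scale` (the removed maximum magnitude).
#' @export
featurize <- function(trace, n_expected = NULL) {
  if (!(is.complex(trace) || is.numeric(trace)) || length(trace) == 0L)
    stop_hw("trace must be a non-empty numeric or complex vector",
            class = "hw_domain_error")
  trace <- as.complex(trace)
  if (!all(is.finite(Re(trace)) & is.finite(Im(trace))))
    stop_hw("trace contains non-finite values", class = "hw_domain_error")
  if (!is.null(n_expected) && length(trace) != n_expected)
    stop_hw("trace length ", length(trace), " != expected ", n_expected,
            class = "hw_shape_error")
  m <- max(Mod(trace))
  if (m == 0)
    stop_hw("all-zero trace cannot be featurized", class = "hw_domain_error")
  x <- trace / m
  structure(list(values = c(Re(x), Im(x)), scale = m),
            class = "hw_features")
}

# feature matrix (rows = examples) from a complex trace matrix (columns =
# examples); vectorized version of featurize()
feature_matrix <- function(traces) {
  m <- apply(Mod(traces), 2L, max)
  if (any(m == 0))
    stop_hw("all-zero trace cannot be featurized", class = "hw_domain_error")
  x <- traces / rep(m, each = nrow(traces))
  cbind(t(Re(x)), t(Im(x)))
}

#' Train the neural-network rate estimator
#'
#' Fits a small fully connected network (ReLU hidden layers, linear scalar
#' output) that regresses the exogenous decay rate from a featurized t1
#' trace. The training target is the dimensionless normalized rate
#' `R * t1_max`, so a trained model transfers across dwell-time settings
#' that share the trace length. Loss is mean squared error on the
#' normalized label; optimisation is Adam on shuffled mini-batches with a
#' held-out validation split. Training is deterministic given `seed`.
#'
#' @param ts An [build_training_set()] corpus.
#' @param hidden Hidden layer sizes; default `c(128, 64)`.
#' @param epochs Training epochs.
#' @param batch_size Mini-batch size.
#' @param learn_rate Adam step size.
#' @param val_fraction Held-out fraction in (0, 1).
#' @param seed Integer seed controlling initialisation, the split and the
#'   batch order.
#' @return An object of class `hw_estimator` with the weights, the
#'   input-length contract, the normalization spec and a training record
#'   (seed, epochs, final train/validation loss, validation MAE in 1/s,
#'   corpus provenance).
#' @export
train_estimator <- function(ts, hidden = c(128L, 64L), epochs = 60L,
                            batch_size = 256L, learn_rate = 1e-3,
                            val_fraction = 0.1, seed = 1L) {
  stopifnot(inherits(ts, "hw_training_set"))
  val_fraction <- check_number(val_fraction, "val_fraction", lower = 0,
                               upper = 1)
  if (val_fraction <= 0 || val_fraction >= 1)
    stop_hw("val_fraction must be in (0, 1)", class = "hw_domain_error")
  X <- feature_matrix(ts$traces)
  y <- ts$labels * ts$t1_max
  n <- nrow(X)

  withr_seed(seed, {
    n_val <- max(1L, floor(val_fraction * n))
    val_idx <- sample.int(n, n_val)
    tr_idx <- setdiff(seq_len(n), val_idx)
    net <- mlp_init(c(ncol(X), hidden, 1L), seed = derive_seed(seed, 1))
    fit <- mlp_train(net, X[tr_idx, , drop = FALSE], y[tr_idx],
                     epochs = epochs, batch_size = batch_size,
                     learn_rate = learn_rate,
                     X_val = X[val_idx, , drop = FALSE], y_val = y[val_idx])
    val_pred <- mlp_forward(fit$net, X[val_idx, , drop = FALSE])
    structure(list(
      net = fit$net,
      hidden = as.integer(hidden),
      activation = "relu",
      n_t1 = ts$n_t1,
      input_length = 2L * ts$n_t1,
      t1_max = ts$t1_max,
      normalization = "max-magnitude; features = c(Re, Im) of trace/max|trace|",
      label_scale = "rate * t1_max (dimensionless)",
      training = list(
        seed = seed, epochs = epochs, batch_size = batch_size,
        learn_rate = learn_rate, n_examples = n, n_val = n_val,
        train_loss = fit$train_loss, val_loss = fit$val_loss,
        val_mae_rate = mean(abs(val_pred - y[val_idx])) / ts$t1_max,
        corpus = ts$provenance,
        loss_history = fit$history
      )
    ), class = "hw_estimator")
  })
}

#' @export
print.hw_estimator <- function(x, ...) {
  cat(sprintf("<hw_estimator> %d -> %s -> 1 (%s)\n", x$input_length,
              paste(x$hidden, collapse = " -> "), x$activation))
  cat(sprintf("  trained on %d examples, val MSE %.4g, val MAE %.3g 1/s\n",
              x$training$n_examples, x$training$val_loss,
              x$training$val_mae_rate))
  invisible(x)
}

#' Predict the exogenous decay rate of one trace
#'
#' @param model An [train_estimator()] model.
#' @param trace Complex t1 trace of the model's expected length.
#' @return Non-negative rate in 1/s. A negative network output is clipped
#'   to 0 with a message.
#' @export
predict_rate <- function(model, trace) {
  stopifnot(inherits(model, "hw_estimator"))
  fv <- featurize(trace, n_expected = model$n_t1)
  y <- mlp_forward(model$net, matrix(fv$values, nrow = 1L))
  r <- y / model$t1_max
  if (r < 0) {
    message("negative rate prediction (", format(r), " 1/s) clipped to 0")
    r <- 0
  }
  r
}

#' Estimate the global exogenous decay rate of a 2D dataset
#'
#' The direct dimension is Fourier transformed first; the exogenous decay is
#' then a common feature of every indirect-dimension trace, so the
#' `n_traces` columns with the highest signal energy are selected, the rate
#' is predicted for each, and the arithmetic mean is reported as the global
#' estimate (the median is carried alongside as a robustness diagnostic).
#' If fewer usable columns exist, all of them are used and the count is
#' recorded.
#'
#' @param model An [train_estimator()] model.
#' @param ifg A `hyperpolarized` (or any non-zero) [interferogram()].
#' @param n_traces Number of energy-ranked columns to use; default 50.
#' @param selection Column selection rule; only `"energy"` is implemented.
#' @return An object of class `hw_rate_estimate` with `per_trace_rates`,
#'   `mean_rate`, `sd`, `median_rate` and `n_traces`.
#' @export
estimate_global_rate <- function(model, ifg, n_traces = 50L,
                                 selection = c("energy")) {
  stopifnot(inherits(model, "hw_estimator"),
            inherits(ifg, "hw_interferogram"))
  selection <- match.arg(selection)
  n_traces <- check_count(n_traces, "n_traces")
  tr <- indirect_traces(ifg)
  if (max(tr$energy) == 0)
    stop_hw("all-zero interferogram: no trace to estimate from",
            class = "hw_domain_error")
  if (nrow(tr$traces) != model$n_t1)
    stop_hw("trace length ", nrow(tr$traces), " != model contract ",
            model$n_t1, class = "hw_shape_error")
  usable <- which(tr$energy > 1e-9 * max(tr$energy))
  take <- usable[order(tr$energy[usable], decreasing = TRUE)]
  take <- take[seq_len(min(n_traces, length(take)))]
  X <- feature_matrix(tr$traces[, take, drop = FALSE])
  rates <- pmax(mlp_forward(model$net, X) / model$t1_max, 0)
  rate_estimate(rates)
}

#' Per-trace rate predictions and their aggregate
#'
#' @param per_trace_rates Non-negative rates in 1/s.
#' @return An object of class `hw_rate_estimate`.
#' @export
rate_estimate <- function(per_trace_rates) {
  if (!is.numeric(per_trace_rates) || length(per_trace_rates) == 0L ||
      !all(is.finite(per_trace_rates)) || any(per_trace_rates < 0))
    stop_hw("per_trace_rates must be finite non-negative numbers",
            class = "hw_domain_error")
  structure(list(
    per_trace_rates = as.numeric(per_trace_rates),
    mean_rate = mean(per_trace_rates),
    sd = if (length(per_trace_rates) > 1L) sd(per_trace_rates) else 0,
    median_rate = median(per_trace_rates),
    n_traces = length(per_trace_rates)
  ), class = "hw_rate_estimate")
}

#' @export
print.hw_rate_estimate <- function(x, ...) {
  cat(sprintf(
    "<hw_rate_estimate> mean %.4g 1/s (sd %.3g, median %.4g) over %d traces\n",
    x$mean_rate, x$sd, x$median_rate, x$n_traces))
  invisible(x)
}

#' Least-squares rate baseline from a paired intrinsic trace
#'
#' Validation oracle usable only when the intrinsic trace is known (i.e. in
#' simulation): the exogenous rate is the least-squares slope of
#' `-log(|s| / |i|)` against t1. Points where either magnitude falls below
#' `noise_floor` are excluded -- the floor is applied to both traces because
#' the log of a noise-dominated tail of `|s|` would otherwise bias the
#' slope.
#'
#' @param s_trace Complex hyperpolarized trace.
#' @param i_trace Complex intrinsic trace, same length.
#' @param t1 Time grid in seconds, same length.
#' @param noise_floor Magnitude threshold; default 0 (use all non-zero
#'   points).
#' @return Rate in 1/s.
#' @export
baseline_rate_ls <- function(s_trace, i_trace, t1, noise_floor = 0) {
  if (length(s_trace) != length(i_trace) || length(s_trace) != length(t1))
    stop_hw("s_trace, i_trace and t1 must have equal lengths",
            class = "hw_shape_error")
  ms <- Mod(as.complex(s_trace))
  mi <- Mod(as.complex(i_trace))
  keep <- mi > noise_floor & ms > noise_floor & mi > 0 & ms > 0
  if (sum(keep) < 3L)
    stop_hw("fewer than 3 usable points above the noise floor",
            class = "hw_domain_error")
  y <- -log(ms[keep] / mi[keep])
  unname(coef(lm(y ~ t1[keep]))[2L])
}

#' @method tidy hw_rate_estimate
#' @export
tidy.hw_rate_estimate <- function(x, ...) {
  tibble::tibble(trace = seq_len(x$n_traces), rate = x$per_trace_rates)
}

#' @method glance hw_rate_estimate
#' @export
glance.hw_rate_estimate <- function(x, ...) {
  tibble::tibble(mean_rate = x$mean_rate, sd = x$sd,
                 median_rate = x$median_rate, n_traces = x$n_traces)
}

#' @method tidy hw_estimator
#' @export
tidy.hw_estimator <- function(x, ...) {
  sizes <- c(x$input_length, x$hidden, 1L)
  tibble::tibble(
    layer = seq_len(length(sizes) - 1L),
    from = sizes[-length(sizes)],
    to = sizes[-1L],
    n_weights = sizes[-length(sizes)] * sizes[-1L] + sizes[-1L]
  )
}

#' @method glance hw_estimator
#' @export
glance.hw_estimator <- function(x, ...) {
  tibble::tibble(
    n_examples = x$training$n_examples,
    epochs = x$training$epochs,
    train_loss = x$training$train_loss,
    val_loss = x$training$val_loss,
    val_mae_rate = x$training$val_mae_rate,
    seed = x$training$seed
  )
}
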