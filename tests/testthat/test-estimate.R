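test_that("featurization is scale-invariant and invertible", {
  set.seed(6)
  trace <- complex(real = rnorm(64), imaginary = rnorm(64))
  f1 <- featurize(trace)
  f2 <- featurize(7.3 * trace)
  expect_equal(f1$values, f2$values, tolerance = 1e-12)
  expect_equal(f2$scale, 7.3 * f1$scale, tolerance = 1e-12)
  # unit-magnitude constant trace maps to ones and zeros
  fc <- featurize(rep(1 + 0i, 16))
  expect_equal(fc$values, c(rep(1, 16), rep(0, 16)))
  # magnitude reconstructed from features times the stored scale is exact
  n <- length(trace)
  rebuilt <- Mod(complex(real = f1$values[1:n],
                         imaginary = f1$values[n + 1:n])) * f1$scale
  expect_equal(rebuilt, Mod(trace))
  expect_error(featurize(rep(0 + 0i, 8)), class = "hw_domain_error")
  expect_error(featurize(trace, n_expected = 32), class = "hw_shape_error")
})

test_that("training is deterministic and learns a constant-rate corpus", {
  sch <- scheme_fast()
  src <- synthesize_intrinsic(sample_resonances(20, seed = 8, scheme = sch),
                              sch)
  cfg <- training_config(n_examples = 3000L, rate_range = c(300, 300),
                         noise_sigma_range = c(0, 0), seed = 5)
  ts <- build_training_set(src, config = cfg)
  m1 <- train_estimator(ts, epochs = 15L, seed = 2)
  m2 <- train_estimator(ts, epochs = 15L, seed = 2)
  expect_identical(m1$net$W, m2$net$W)
  expect_identical(m1$net$b, m2$net$b)
  # held-out predictions recover the single training rate
  tr <- indirect_traces(src)
  keep <- order(tr$energy, decreasing = TRUE)[1:20]
  preds <- vapply(keep, function(k)
    predict_rate(m1, tr$traces[, k] * exp(-300 * ts$t1)), numeric(1))
  expect_lt(abs(mean(preds) - 300) / 300, 0.05)
})

test_that("the trained model beats the trivial mean predictor", {
  mod <- get_test_model()
  expect_true(is.finite(mod$training$val_loss))
  # MAE of the mean predictor for uniform labels is range/4
  label_sd <- (1000 - 50) / sqrt(12)
  expect_lt(mod$training$val_mae_rate, label_sd)
})

test_that("rate prediction is invariant to input rescaling", {
  mod <- get_test_model()
  set.seed(9)
  sch <- scheme_fast()
  src <- synthesize_intrinsic(sample_resonances(10, seed = 3, scheme = sch),
                              sch)
  tr <- indirect_traces(src)
  k <- which.max(tr$energy)
  trace <- tr$traces[, k] * exp(-450 * (0:63) * 2e-4)
  expect_equal(predict_rate(mod, trace), predict_rate(mod, 128 * trace),
               tolerance = 1e-9)
  expect_error(predict_rate(mod, trace[1:10]), class = "hw_shape_error")
})

test_that("the global estimate recovers a known rate and reports edges", {
  mod <- get_test_model()
  sch <- scheme_fast()
  res <- sample_resonances(50, seed = 77,
                           ranges = list(r2_ind = c(50, 50)), scheme = sch)
  int <- synthesize_intrinsic(res, sch, water_fraction = 0.02)
  dm <- decay_model(300, 450)
  ns <- noise_sigma_for_trace_snr(int, dm, 20, 50)
  hyp <- distort(int, dm, noise_sigma = ns, seed = 78)
  est <- estimate_global_rate(mod, hyp, n_traces = 50)
  expect_s3_class(est, "hw_rate_estimate")
  expect_equal(est$n_traces, 50L)
  expect_lt(abs(est$mean_rate - 450) / 450, 0.10)
  expect_equal(est$mean_rate, mean(est$per_trace_rates))
  # enhancement invariance of the whole pipeline: epsilon x100 changes nothing
  est2 <- estimate_global_rate(mod, scale_ifg(hyp, 100), n_traces = 50)
  expect_equal(est$per_trace_rates, est2$per_trace_rates, tolerance = 1e-9)
  # fewer usable columns than requested: all are used and the count recorded
  sch_small <- acq_scheme(64L, 2e-4, 30L, 5e-4)
  int_s <- synthesize_intrinsic(one_resonance(), sch_small)
  hyp_s <- distort(int_s, dm, 0, seed = 1)
  est_s <- estimate_global_rate(mod, hyp_s, n_traces = 50)
  expect_equal(est_s$n_traces, 30L)
  # all-zero data are rejected
  zero <- suppressWarnings(synthesize_intrinsic(one_resonance(kex = 1), sch))
  zh <- apply_decay(zero, dm)
  expect_error(estimate_global_rate(mod, zh), class = "hw_domain_error")
})

test_that("averaging many traces is more stable than single traces", {
  mod <- get_test_model()
  sch <- scheme_fast()
  means <- numeric(8); singles <- numeric(0)
  for (i in 1:8) {
    res <- sample_resonances(50, seed = 600 + i, scheme = sch)
    int <- synthesize_intrinsic(res, sch, water_fraction = 0.02)
    dm <- decay_model(300, 450)
    ns <- noise_sigma_for_trace_snr(int, dm, 20, 50)
    hyp <- distort(int, dm, noise_sigma = ns, seed = 700 + i)
    est <- estimate_global_rate(mod, hyp, 50)
    means[i] <- est$mean_rate
    singles <- c(singles, est$per_trace_rates)
  }
  expect_lt(sd(means), sd(singles))
})

test_that("estimation error grows with the noise level on average", {
  mod <- get_test_model()
  sch <- scheme_fast()
  # probed far from the middle of the training range, where heavy noise
  # visibly shrinks predictions toward the prior
  R <- 800
  err_at <- function(mult) {
    mean(vapply(1:20, function(i) {
      res <- sample_resonances(30, seed = 300 + i, scheme = sch)
      int <- synthesize_intrinsic(res, sch, water_fraction = 0.02)
      dm <- decay_model(300, R)
      ns <- mult * noise_sigma_for_trace_snr(int, dm, 20, 50)
      hyp <- distort(int, dm, noise_sigma = ns, seed = 400 + i)
      abs(estimate_global_rate(mod, hyp, 50)$mean_rate - R) / R
    }, numeric(1)))
  }
  e_low <- err_at(0.2)   # per-trace SNR ~ 100
  e_high <- err_at(5)    # per-trace SNR ~ 4
  expect_lte(e_low, e_high)
})

test_that("least-squares baseline recovers rates from paired traces", {
  t1 <- (0:63) * 2e-4
  i_tr <- exp((2i * pi * 320 - 55) * t1)
  s_tr <- i_tr * exp(-450 * t1)
  expect_equal(baseline_rate_ls(s_tr, i_tr, t1), 450, tolerance = 1e-8)
  expect_equal(baseline_rate_ls(i_tr, i_tr, t1), 0, tolerance = 1e-10)
  expect_error(baseline_rate_ls(s_tr, i_tr, t1, noise_floor = 10),
               class = "hw_domain_error")
  expect_error(baseline_rate_ls(s_tr[1:10], i_tr, t1),
               class = "hw_shape_error")
})

test_that("tidy and glance expose the fit as tibbles", {
  est <- rate_estimate(c(440, 450, 460))
  td <- tidy(est)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3L)
  gl <- glance(est)
  expect_equal(gl$mean_rate, 450)
  expect_equal(gl$n_traces, 3L)
  mod <- get_test_model()
  expect_equal(nrow(tidy(mod)), 3L)
  expect_true(is.finite(glance(mod)$val_loss))
})
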