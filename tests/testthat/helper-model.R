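# The default rate estimator, shared by every test file that needs a
# trained network: the default 100,000-example corpus at the package's
# default ranges, the default architecture and the default training run.
# Trained lazily once per test run (~4 min) and cached.
.hw_test_cache <- new.env(parent = emptyenv())

get_test_model <- function() {
  if (is.null(.hw_test_cache$model)) {
    sch <- acq_scheme(64L, 2e-4, 200L, 5e-4)
    ts <- build_training_set(config = training_config(seed = 7L),
                             scheme = sch)
    .hw_test_cache$model <- train_estimator(ts, seed = 3L)
  }
  .hw_test_cache$model
}
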