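# The synthetic recovery fixture: one moderately sized training run shared
# by the acceptance checks that need a trained model. Cached so the cost is
# paid once per test session.

.recovery_cache <- new.env(parent = emptyenv())

recovery_fixture <- function() {
  if (!is.null(.recovery_cache$fit)) return(as.list(.recovery_cache))
  sampler <- phantom_sampler(height = 64, width = 64)
  train <- generate_dataset(60, sampler, style_internal(), seed = 101)
  val <- generate_dataset(8, sampler, style_internal(), seed = 102)
  test_a <- generate_dataset(15, sampler, style_internal(), seed = 103)
  test_b <- generate_dataset(15, sampler, style_external(), seed = 104)
  net <- build_network(network_config(width_scale = 0.25, input_size = 64,
                                      seed = 11))
  fit <- fit_network(net, train, val,
                     train_config(batch_size = 4, max_epochs = 20,
                                  input_size = 64, seed = 12))
  .recovery_cache$fit <- fit
  .recovery_cache$test_a <- test_a
  .recovery_cache$test_b <- test_b
  as.list(.recovery_cache)
}
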