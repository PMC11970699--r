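# The 200-replicate recovery experiment at study-like truth is used by
# several distributional checks; compute it once per test run.
.recovery_cache <- new.env(parent = emptyenv())

recovery_200 <- function() {
  if (is.null(.recovery_cache$exp)) {
    .recovery_cache$exp <- recovery_experiment(simulation_spec(), 200)
  }
  .recovery_cache$exp
}
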