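# One full default-condition pipeline run shared by the acceptance tests;
# built lazily so the cheap unit files never pay for it.
.acc_cache <- new.env(parent = emptyenv())

acc_screen_run <- function() {
  if (is.null(.acc_cache$run))
    .acc_cache$run <- run_host_screen(spec = simulation_spec(), seed = 1)
  .acc_cache$run
}
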