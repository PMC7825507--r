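# Shared fixtures. Coarse settings keep unit-level simulations fast;
# experiments that reproduce the reference depth results use the
# default full-resolution settings instead.
coarse_settings <- function(...) {
  sim_settings(n = 150, dr = 0.05, max_sim_time = 2e6, ...)
}

glucose_fixture <- function() builtin_solutes()[1, ]

# The glucose calibration is used by several acceptance-level tests;
# run it once per test session and cache.
calibrated_glucose <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- calibrate_glucose()
    cache
  }
})
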