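# Shared fixtures. Synthesis of sharp-transition profiles at 256 Hz warns
# when fast expiratory flow under-resolves phase 2; that is expected for
# these study conditions, so the helper silences it.

quiet_synth <- function(...) suppressWarnings(synthesize_recording(...))

# a standard healthy-rat recording for tests that just need "a breath"
std_recording <- function(mode = "PPV", sensor = ideal_sensor(),
                          n_breaths = 4, seed = 1,
                          params = expirogram_params(), ...) {
  quiet_synth(params, flow_pattern(mode), sensor, n_breaths = n_breaths,
              seed = seed, ...)
}

# directly constructed capnogram from an analytic profile on a fine grid
profile_capnogram <- function(params, n = 600L) {
  pr <- make_expirogram_profile(params)
  v <- seq(0, params$vt, length.out = n)
  structure(list(v = v, pco2 = pr(v), vt = params$vt,
                 breath_id = NA_integer_),
            class = "vol_capnogram")
}
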