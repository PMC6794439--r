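# Long simulations reused across test files, computed lazily once per run.
.trace_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .trace_cache))
    assign(key, force(expr), envir = .trace_cache)
  get(key, envir = .trace_cache)
}

# 500 s clamp trace at a fixed IP3 level, base parameters, 10 ms sampling
clamp_trace <- function(level, T = 500, dt_out = 0.01,
                        ap = astro_params()) {
  cached(sprintf("clamp_%g_%g_%g_%g_%g", level, T, dt_out, ap$r_L, ap$k_ER),
         simulate_reference(protocol_clamp(level, T), neuron_params(), ap,
                            dt_out = dt_out))
}

# full preset bundles (reference + digital + report), 1 ms grid
preset_bundle <- function(preset) {
  cached(paste0("bundle_", preset),
         suppressWarnings(run_experiment(preset)))
}
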