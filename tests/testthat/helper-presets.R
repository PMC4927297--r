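# cached noise-free pipelines shared across test files (simulation is
# deterministic at noise_sd = 0, so caching cannot couple tests)
.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) assign(key, force(expr), .fixture_cache)
  .fixture_cache[[key]]
}

noisefree_pipeline <- function(preset, ...) {
  cached(paste0(preset, paste(c(...), collapse = "_")), {
    scn <- scenario_preset(preset, noise_sd = 0, ...)
    cm <- simulate_capacitance(scn)
    rep_ <- simulate_reporter(scn, cm)
    list(scn = scn, cm = cm, cmn = normalize_cm(cm), rep = rep_,
         q = normalize_invert(rep_$fluor))
  })
}

# closed-form normalised recovery for the rat constants, written out
# independently of the package internals
rat_recovery_closed_form <- function(t) {
  0.12 + 0.88 * (0.37 * exp(-t / 5.2) + 0.63 * exp(-t / 66.5))
}
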