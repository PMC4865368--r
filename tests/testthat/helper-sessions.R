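# Shared fixtures: sessions are generated once per test run and cached.

.session_cache <- new.env(parent = emptyenv())

cached_session <- function(key, cfg) {
  if (is.null(.session_cache[[key]])) {
    .session_cache[[key]] <- generate_session(cfg)
  }
  .session_cache[[key]]
}

cached_detection <- function(key, cfg) {
  dkey <- paste0(key, "_detect")
  if (is.null(.session_cache[[dkey]])) {
    gs <- cached_session(key, cfg)
    .session_cache[[dkey]] <- detect_saccades(gs$session)
  }
  .session_cache[[dkey]]
}

# a small mixed session used by several files
small_cfg <- function(...) {
  args <- modifyList(list(n_pps_neurons = 3, n_lps_neurons = 3,
                          n_null_neurons = 1, n_trials_per_direction = 20,
                          rng_seed = 101),
                     list(...))
  do.call(generator_config, args)
}

# data-driven preferred directions for a generated session
neuron_directions <- function(gs, trials_df) {
  ids <- gs$ground_truth$neurons$neuron_id
  data.frame(
    neuron_id = ids,
    preferred_direction = vapply(ids, function(nid) {
      preferred_direction(gs$session, nid, trials_df)
    }, character(1)),
    kind = gs$ground_truth$neurons$kind,
    stringsAsFactors = FALSE)
}

# build a hand-made saccade object for filter tests
make_saccade <- function(duration = 40, amplitude = 9.5, latency = 200,
                         end_x = 10, end_y = 0, peak_velocity = 400) {
  structure(list(onset = 1800, offset = 1800 + duration, duration = duration,
                 amplitude = amplitude, peak_velocity = peak_velocity,
                 latency = latency, end_x = end_x, end_y = end_y),
            class = "saccade")
}
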