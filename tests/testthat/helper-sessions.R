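# Shared fixtures. Sessions are generated once per test run and cached;
# everything is seeded so the suite is deterministic.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small direction-coding session: 24 tuned neurons, 5 trials per cell,
# low frame rate to keep arrays small
small_direction_session <- function() cached("dir_session", function() {
  simulate_session(
    session_config(het_range = 90, trials_per_direction = 5, n_dots = 50,
                   frame_rate = 5, pre_window = 1),
    population_model(24, coding_mode = "sharpened_mean"),
    calcium_params(noise_sd = 0.03, drift_amplitude = 0.02),
    psych_params(sigma = 5, lapse = 0),   # near-perfect behavior
    seed = 101)
})

# category-coding session of matching size
small_category_session <- function() cached("cat_session", function() {
  simulate_session(
    session_config(het_range = 90, trials_per_direction = 5, n_dots = 50,
                   frame_rate = 5, pre_window = 1),
    population_model(24, coding_mode = "category"),
    calcium_params(noise_sd = 0.03, drift_amplitude = 0.02),
    psych_params(sigma = 5, lapse = 0),
    seed = 102)
})

# untuned-noise session for null calibration
small_untuned_session <- function() cached("untuned_session", function() {
  simulate_session(
    session_config(het_range = 90, trials_per_direction = 5, n_dots = 50,
                   frame_rate = 5, pre_window = 1),
    population_model(24, coding_mode = "untuned"),
    calcium_params(noise_sd = 0.05, drift_amplitude = 0.02),
    psych_params(sigma = 30, lapse = 0.1),
    seed = 103)
})

# hand-built trace matrix: neurons respond with a fixed value per
# (neuron, direction) during the stimulus window, zero (or baseline) before.
# response_fn(pref, direction) -> stimulus dF/F.
manual_session_traces <- function(trials, prefs, response_fn, frame_rate = 5,
                                  pre_window = 1, stim_duration = 4,
                                  baseline = 0) {
  frames_per_trial <- round((pre_window + stim_duration) * frame_rate)
  n_frames <- nrow(trials) * frames_per_trial
  traces <- matrix(baseline, length(prefs), n_frames)
  n_stim <- round(stim_duration * frame_rate)
  for (i in seq_len(nrow(trials))) {
    on <- trials$onset_frame[i]
    for (n in seq_along(prefs)) {
      traces[n, on:(on + n_stim - 1)] <-
        response_fn(prefs[n], trials$mean_direction[i])
    }
  }
  attr(traces, "frame_rate") <- frame_rate
  traces
}

# schedule with onset frames matching manual_session_traces
manual_trials <- function(trials_per_direction = 2, het_range = 90,
                          frame_rate = 5, pre_window = 1,
                          stim_duration = 4) {
  cfg <- session_config(het_range = het_range,
                        trials_per_direction = trials_per_direction,
                        frame_rate = frame_rate, pre_window = pre_window,
                        stim_duration = stim_duration)
  design_session(cfg)
}
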