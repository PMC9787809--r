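# Small configurations used throughout the suite. Short trials and few
# subjects keep the unit tests fast; full-size studies are reserved for
# the recovery checks.

tiny_config <- function(...) {
  defaults <- list(n_subjects = 2, trials_per_cell = 1, trial_duration = 5,
                   image_types = "fractal", seed = 101)
  args <- modifyList(defaults, list(...))
  do.call(gaze_config, args)
}

# A single low-noise trial with exactly the given saccades injected.
injected_trial <- function(onsets, amplitudes, directions, seed = 1,
                           noise = 0.02, duration = 15) {
  cfg <- gaze_config(n_subjects = 1, position_noise_sd = noise,
                     trial_duration = duration, seed = seed)
  generate_trial(1, 1,
                 condition = list(head_tilt = 0, image_tilt = 0,
                                  image_type = "fractal"),
                 config = cfg, head_tilt_measured = 0,
                 events = data.frame(onset = onsets, amplitude = amplitudes,
                                     direction = directions))
}

# Smallest angular difference in degrees.
ang_diff <- function(a, b) {
  d <- (a - b) %% 360
  pmin(d, 360 - d)
}
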