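test_that("config validation rejects malformed parameter sets", {
  expect_error(gaze_config(bias_weights = c(0.5, 0.6)), "sum to 1")
  expect_error(gaze_config(bias_weights = c(1.5, -0.5)), "nonnegative")
  expect_error(gaze_config(concentration = -1), "concentration")
  expect_error(gaze_config(sample_rate = 0), "sample_rate")
  expect_error(gaze_config(trial_duration = -1), "trial_duration")
  expect_error(gaze_config(anchor = "gravity"))
  expect_error(gaze_config(ocr_saturation = 0), "ocr_saturation")
})

test_that("config survives a JSON and YAML round trip and rejects unknown fields", {
  cfg <- tiny_config(anchor = "world", ocr_gain = 0.2)
  for (ext in c("json", "yaml")) {
    p <- file.path(tempdir(), paste0("cfg.", ext))
    write_gaze_config(cfg, p)
    back <- read_gaze_config(p)
    expect_equal(unclass(back), unclass(cfg), tolerance = 1e-6)
  }
  p <- file.path(tempdir(), "bad.json")
  jsonlite::write_json(list(n_subjects = 2, frobnicate = 1), p, auto_unbox = TRUE)
  expect_error(read_gaze_config(p), "frobnicate")
})

test_that("counter-roll model is odd, saturating, and opposite to head tilt", {
  cfg <- gaze_config(ocr_gain = 0.1, ocr_saturation = 10)
  expect_equal(ocr_model(0, cfg), 0)
  expect_equal(ocr_model(30, cfg), -3)
  expect_equal(ocr_model(-30, cfg), 3)
  cfg2 <- gaze_config(ocr_gain = 1.0, ocr_saturation = 8)
  expect_equal(ocr_model(30, cfg2), -8)
  expect_true(abs(ocr_model(30, cfg2)) >= 8 && abs(ocr_model(30, cfg2)) <= 10)
  tilts <- seq(-90, 90, by = 7.5)
  expect_equal(ocr_model(tilts, cfg), -ocr_model(-tilts, cfg))
  expect_true(all(abs(ocr_model(tilts, cfg)) <= cfg$ocr_saturation))
  expect_error(ocr_model(NaN, cfg), "finite")
})

test_that("degenerate concentration pins directions to the anchored axes", {
  cfg <- gaze_config(concentration = 1e6, bias_weights = c(1, 0),
                     anchor = "head")
  set.seed(4)
  a <- sample_directions(4, cfg, head_tilt = 30)
  expect_true(all(ang_diff(a, 0) < 0.5 | ang_diff(a, 180) < 0.5))

  cfg_w <- gaze_config(concentration = 1e6, bias_weights = c(1, 0),
                       anchor = "world")
  a0 <- sample_directions(4, cfg_w, head_tilt = 0)
  expect_true(all(ang_diff(a0, 0) < 0.5 | ang_diff(a0, 180) < 0.5))
  # tilted head: world-anchored bias appears at +tilt in head coordinates
  a30 <- sample_directions(4, cfg_w, head_tilt = 30)
  expect_true(all(ang_diff(a30, 30) < 0.5 | ang_diff(a30, 210) < 0.5))
  # retina anchor sits at minus the counter-roll
  cfg_r <- gaze_config(concentration = 1e6, bias_weights = c(1, 0),
                       anchor = "retina", ocr_gain = 0.1, ocr_saturation = 10)
  ar <- sample_directions(4, cfg_r, head_tilt = 30)
  expect_true(all(ang_diff(ar, 3) < 0.5 | ang_diff(ar, 183) < 0.5))
  expect_error(sample_directions(2, cfg, head_tilt = NA), "finite")
})

test_that("mixture weights are recovered from large direction samples", {
  # at kappa = 4 each lobe leaks mass across the +-45 degree sector border;
  # the empirical sector mass must match the analytic mixture integral
  p_in <- integrate(function(t) exp(4 * cos(t)) / (2 * pi * besselI(4, 0)),
                    -pi / 4, pi / 4)$value
  cfg <- gaze_config(bias_weights = c(0.7, 0.3), concentration = 4,
                     anchor = "head")
  set.seed(9)
  a <- sample_directions(4e4, cfg, 0)
  horiz <- mean(ang_diff(a, 0) <= 45 | ang_diff(a, 180) <= 45)
  expect_lt(abs(horiz - (0.7 * p_in + 0.3 * (1 - p_in))), 0.02)
  # with tight lobes the sector mass is the horizontal weight itself
  cfg_hi <- gaze_config(bias_weights = c(0.7, 0.3), concentration = 50,
                        anchor = "head")
  a_hi <- sample_directions(1e4, cfg_hi, 0)
  horiz_hi <- mean(ang_diff(a_hi, 0) <= 45 | ang_diff(a_hi, 180) <= 45)
  expect_lt(abs(horiz_hi - 0.7), 0.02)
})

test_that("trials have the configured sample count and honour saccade_rate = 0", {
  cfg <- gaze_config(n_subjects = 1, trial_duration = 15, sample_rate = 120)
  tr <- generate_trial(1, 1, list(head_tilt = 0, image_tilt = 0,
                                  image_type = "fractal"), cfg)
  expect_equal(nrow(tr), 1800)
  expect_equal(tr$t_s[2] - tr$t_s[1], 1 / 120)

  cfg0 <- gaze_config(n_subjects = 1, saccade_rate = 0, trial_duration = 5)
  tr0 <- generate_trial(1, 1, list(head_tilt = 0, image_tilt = 0,
                                   image_type = "fractal"), cfg0)
  expect_equal(nrow(attr(tr0, "events")), 0)
  expect_equal(nrow(detect_saccades(tr0)), 0)
  expect_error(generate_trial(1, 1, list(head_tilt = 45, image_tilt = 0,
                                         image_type = "fractal"), cfg),
               "head_tilt")
  expect_error(generate_trial(1, 1, list(head_tilt = 0, image_tilt = 0,
                                         image_type = "portrait"), cfg),
               "image_type")
})

test_that("injected events are honoured exactly", {
  tr <- injected_trial(onsets = c(1, 3, 5), amplitudes = c(5, 3, 7),
                       directions = c(0, 90, 225))
  ev <- attr(tr, "events")
  expect_equal(nrow(ev), 3)
  expect_equal(ev$direction, c(0, 90, 225))
  expect_error(injected_trial(onsets = c(1, 1.001), amplitudes = c(5, 5),
                              directions = c(0, 0)), "overlap")
})

test_that("the study covers the factorial design with deterministic output", {
  cfg <- gaze_config(n_subjects = 2, trials_per_cell = 1, trial_duration = 2,
                     seed = 5)
  st1 <- generate_study(cfg)
  st2 <- generate_study(cfg)
  expect_identical(st1, st2)

  first <- st1[!duplicated(paste(st1$subject, st1$trial)), ]
  counts <- table(first$subject, first$head_tilt_nominal_deg,
                  first$image_tilt_deg, first$image_type)
  expect_true(all(counts == 1))
  # 3 head tilts x (2 types x 3 image tilts x 1 rep) = 18 trials per subject
  expect_equal(nrow(first), 2 * 18)

  # serialization determinism
  p1 <- tempfile(fileext = ".csv"); p2 <- tempfile(fileext = ".csv")
  write_gaze_csv(st1, p1); write_gaze_csv(st2, p2)
  expect_identical(readLines(p1), readLines(p2))

  single <- generate_study(gaze_config(n_subjects = 1, head_tilts = 0,
                                       image_tilts = 0, image_types = "scene",
                                       trials_per_cell = 1, trial_duration = 2))
  expect_equal(length(unique(single$trial)), 1)
})

test_that("a study emulating the full session has 180 trials per subject", {
  cfg <- gaze_config(n_subjects = 1, trial_duration = 0.1, sample_rate = 120)
  st <- generate_study(cfg)
  expect_equal(length(unique(st$trial)), 180)
  # 60 trials per head-tilt block
  first <- st[!duplicated(st$trial), ]
  expect_true(all(table(first$head_tilt_nominal_deg) == 60))
})

test_that("torsion channel is present for the configured fraction of subjects", {
  cfg <- gaze_config(n_subjects = 4, trials_per_cell = 1, trial_duration = 1,
                     image_types = "fractal", torsion_fraction = 11 / 14)
  st <- generate_study(cfg)
  has_torsion <- tapply(is.finite(st$torsion_deg), st$subject, any)
  expect_equal(sum(has_torsion), 3)  # round(4 * 11/14)
})
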