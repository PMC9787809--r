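#' Configuration for the synthetic gaze simulator
#'
#' Builds and validates the parameter set for the synthetic free-viewing
#' study. The defaults emulate the head-tilt design the package targets:
#' 14 subjects, head tilt blocks at -30/0/30 degrees, 60 trials per block
#' (30 fractals + 30 natural scenes spread over image tilts -30/0/30),
#' 15 s trials sampled at 120 Hz, a four-lobe cardinal direction bias
#' dominated by the horizontal axis, and ocular counter-roll (OCR) that
#' is opposite in sign to head tilt and saturates at 8-10 degrees.
#'
#' @param n_subjects number of simulated subjects.
#' @param head_tilts nominal head tilt blocks, degrees
#'   (positive = rightward/clockwise roll).
#' @param image_tilts image tilts relative to the head, degrees.
#' @param image_types image categories; `"fractal"` images carry no upright
#'   cue, `"scene"` images are treated as having one for condition
#'   bookkeeping (the simulator itself is content-free).
#' @param trials_per_cell trials per image type x image tilt cell within a
#'   head-tilt block. The default (10) gives 60 trials per block and 180
#'   per subject.
#' @param trial_duration seconds of free viewing per trial.
#' @param sample_rate eye-tracker sampling rate, Hz.
#' @param bias_weights length-2 nonnegative weights `(horizontal, vertical)`
#'   of the cardinal-axis mixture; must sum to 1.
#' @param concentration von Mises concentration kappa of each lobe.
#' @param anchor reference frame the direction bias is fixed to: `"head"`
#'   (rotates fully with the head), `"world"` (stays gravity-aligned), or
#'   `"retina"` (follows the eye, i.e. head plus counter-roll).
#' @param ocr_gain unitless slope of counter-roll magnitude versus head
#'   tilt. Default 0.0857 produces ~2.6 degrees of OCR at a measured 30
#'   degree tilt, matching typical human partial compensation.
#' @param ocr_saturation maximum counter-roll magnitude, degrees.
#' @param saccade_rate mean saccade rate, events/s.
#' @param amplitude_scale mean of the (exponential, small-amplitude-biased)
#'   saccade amplitude distribution, degrees.
#' @param position_noise_sd additive Gaussian position noise, degrees.
#' @param torsion_noise_sd additive Gaussian torsion noise, degrees.
#' @param torsion_fraction fraction of subjects with a usable torsion
#'   channel (default 11/14); the remaining subjects get `NA` torsion.
#' @param head_tilt_jitter_sd between-block sd of measured around expected
#'   head tilt, degrees.
#' @param seed integer master seed; all per-subject/per-trial streams are
#'   split deterministically from it.
#' @return an object of class `gaze_config` (a validated list).
#' @seealso [generate_study()], [generate_trial()], [sample_directions()]
#' @examples
#' cfg <- gaze_config(n_subjects = 2, trials_per_cell = 1, trial_duration = 2)
#' study <- generate_study(cfg)
#' head(study)
#' @export
gaze_config <- function(n_subjects = 14,
                        head_tilts = c(-30, 0, 30),
                        image_tilts = c(-30, 0, 30),
                        image_types = c("fractal", "scene"),
                        trials_per_cell = 10,
                        trial_duration = 15,
                        sample_rate = 120,
                        bias_weights = c(horizontal = 0.7, vertical = 0.3),
                        concentration = 4,
                        anchor = c("retina", "head", "world"),
                        ocr_gain = 0.0857,
                        ocr_saturation = 9,
                        saccade_rate = 3,
                        amplitude_scale = 4,
                        position_noise_sd = 0.1,
                        torsion_noise_sd = 0.5,
                        torsion_fraction = 11 / 14,
                        head_tilt_jitter_sd = 2.5,
                        seed = 1L) {
  anchor <- match.arg(anchor)
  cfg <- list(
    n_subjects = as.integer(n_subjects), head_tilts = as.numeric(head_tilts),
    image_tilts = as.numeric(image_tilts), image_types = as.character(image_types),
    trials_per_cell = as.integer(trials_per_cell),
    trial_duration = as.numeric(trial_duration), sample_rate = as.numeric(sample_rate),
    bias_weights = as.numeric(bias_weights), concentration = as.numeric(concentration),
    anchor = anchor, ocr_gain = as.numeric(ocr_gain),
    ocr_saturation = as.numeric(ocr_saturation),
    saccade_rate = as.numeric(saccade_rate), amplitude_scale = as.numeric(amplitude_scale),
    position_noise_sd = as.numeric(position_noise_sd),
    torsion_noise_sd = as.numeric(torsion_noise_sd),
    torsion_fraction = as.numeric(torsion_fraction),
    head_tilt_jitter_sd = as.numeric(head_tilt_jitter_sd),
    seed = as.integer(seed))
  class(cfg) <- "gaze_config"
  validate_gaze_config(cfg)
}

validate_gaze_config <- function(cfg) {
  stopifnot(inherits(cfg, "gaze_config"))
  if (cfg$n_subjects < 1) stop("n_subjects must be >= 1")
  if (length(cfg$bias_weights) != 2 || any(cfg$bias_weights < 0))
    stop("bias_weights must be two nonnegative numbers")
  if (abs(sum(cfg$bias_weights) - 1) > 1e-8)
    stop("bias_weights must sum to 1")
  if (cfg$concentration < 0) stop("concentration must be >= 0")
  if (cfg$sample_rate <= 0) stop("sample_rate must be > 0")
  if (cfg$trial_duration <= 0) stop("trial_duration must be > 0")
  if (cfg$ocr_gain < 0) stop("ocr_gain must be >= 0")
  if (cfg$ocr_saturation <= 0) stop("ocr_saturation must be > 0")
  if (cfg$saccade_rate < 0) stop("saccade_rate must be >= 0")
  if (cfg$torsion_fraction < 0 || cfg$torsion_fraction > 1)
    stop("torsion_fraction must be in [0, 1]")
  if (any(!is.finite(cfg$head_tilts))) stop("head_tilts must be finite")
  cfg
}

#' Read or write a simulator configuration as JSON or YAML
#'
#' The on-disk schema is the flat field list of [gaze_config()]; unknown
#' fields are rejected so typos fail loudly.
#'
#' @param path file path; format chosen by extension (`.json`, `.yaml`/`.yml`).
#' @param cfg a `gaze_config` object (for writing).
#' @return `read_gaze_config()` returns a validated `gaze_config`;
#'   `write_gaze_config()` returns `path` invisibly.
#' @export
read_gaze_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  known <- names(formals(gaze_config))
  extra <- setdiff(names(raw), known)
  if (length(extra) > 0)
    stop("unknown config fields: ", paste(extra, collapse = ", "))
  do.call(gaze_config, raw)
}

#' @rdname read_gaze_config
#' @export
write_gaze_config <- function(cfg, path) {
  cfg <- validate_gaze_config(cfg)
  x <- unclass(cfg)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(x, path)
  } else {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Static ocular counter-roll model
#'
#' Torsion induced by a static head roll: opposite in sign to the tilt,
#' growing linearly with `ocr_gain` and saturating at `ocr_saturation`
#' degrees, consistent with the 8-10 degree asymptote of human OCR.
#' An odd function of head tilt.
#'
#' @param head_tilt head roll, degrees (positive = clockwise/right).
#' @param config a [gaze_config()] supplying `ocr_gain` and `ocr_saturation`.
#' @return torsion in degrees (positive = clockwise eye rotation from the
#'   subject's viewpoint); vectorised over `head_tilt`.
#' @examples
#' cfg <- gaze_config(ocr_gain = 0.1, ocr_saturation = 10)
#' ocr_model(30, cfg)   # -3
#' ocr_model(-30, cfg)  # 3
#' @export
ocr_model <- function(head_tilt, config) {
  config <- validate_gaze_config(config)
  if (any(!is.finite(head_tilt))) stop("head_tilt must be finite")
  -sign(head_tilt) * pmin(config$ocr_gain * abs(head_tilt), config$ocr_saturation)
}

# Rotation, in head/display coordinates (CCW-positive), of the cardinal
# bias axes for a given anchor and actual head tilt. A world-anchored bias
# appears rotated by +tilt in head coordinates (the world horizon rotates
# counterclockwise relative to a clockwise-tilted head); a retina-anchored
# bias sits at minus the counter-roll.
anchor_rotation <- function(anchor, head_tilt, config) {
  switch(anchor,
    head = 0 * head_tilt,
    world = head_tilt,
    retina = -ocr_model(head_tilt, config),
    stop("unknown anchor: ", anchor))
}

#' Sample saccade directions from the anchored cardinal-bias mixture
#'
#' Draws directions from a four-lobe von Mises mixture with lobes at
#' 0/180 degrees (horizontal, weight `bias_weights[1]`) and 90/270 degrees
#' (vertical, weight `bias_weights[2]`), rotated according to the
#' configured anchor: no rotation for a head-anchored bias, `+head_tilt`
#' for a world-anchored bias, and minus the [ocr_model()] counter-roll for
#' a retina-anchored bias. Returned angles are in head/display coordinates.
#'
#' @param n number of directions (>= 1).
#' @param config a [gaze_config()].
#' @param head_tilt actual head tilt of the condition, degrees.
#' @return numeric vector of angles in `[0, 360)`.
#' @export
sample_directions <- function(n, config, head_tilt = 0) {
  config <- validate_gaze_config(config)
  stopifnot(n >= 1)
  if (!is.finite(head_tilt)) stop("head_tilt must be finite")
  w <- config$bias_weights
  if (sum(w) <= 0) stop("empty mixture")
  rho <- anchor_rotation(config$anchor, head_tilt, config)
  means <- c(0, 180, 90, 270) + rho
  probs <- c(w[1] / 2, w[1] / 2, w[2] / 2, w[2] / 2)
  lobe <- sample.int(4, n, replace = TRUE, prob = probs)
  th <- rvonmises(n, 0, config$concentration) * 180 / pi
  (th + means[lobe]) %% 360
}

# Expected measured head tilt for a nominal block tilt. The canonical
# +-30/0 blocks map to the measured group means of the emulated study
# (27.14 / 0.19 / -26.68); other nominals are attenuated by 0.9, the
# typical shortfall of constrained head roll.
measured_tilt_mean <- function(nominal) {
  out <- 0.9 * nominal
  out[nominal == 30] <- 27.14
  out[nominal == 0] <- 0.19
  out[nominal == -30] <- -26.68
  out
}

# Raised-cosine saccade kinematics. Peak velocity follows the main-sequence
# law V = 500 * (1 - exp(-A / 5)) deg/s; duration is fixed by requiring the
# raised-cosine profile to integrate to the amplitude: D = 2 A / V.
saccade_peak_velocity <- function(amplitude) 500 * (1 - exp(-amplitude / 5))
saccade_duration <- function(amplitude) 2 * amplitude / saccade_peak_velocity(amplitude)

# Normalised raised-cosine position profile on u in [0, 1]:
# integral of (1 - cos(2 pi u)) / 2.
saccade_profile <- function(u) u - sin(2 * pi * u) / (2 * pi)

#' Generate one synthetic free-viewing trial
#'
#' Builds a gaze trace as alternating fixations (gamma-distributed
#' durations, shape 4, mean `1/saccade_rate`) and saccades whose directions
#' come from [sample_directions()], amplitudes from an exponential with
#' mean `amplitude_scale`, and whose velocity profiles are raised cosines
#' obeying the main-sequence law `V = 500 (1 - exp(-A/5))` deg/s. Position
#' noise is additive Gaussian; the torsion channel is the [ocr_model()]
#' value for the measured tilt plus noise (or `NA` when the subject has no
#' torsion signal).
#'
#' @param subject_id,trial_id integer identifiers.
#' @param condition list with elements `head_tilt`, `image_tilt`,
#'   `image_type` drawn from the configured sets.
#' @param config a [gaze_config()].
#' @param head_tilt_measured actual head tilt, degrees; defaults to the
#'   subject/block draw implied by the master seed.
#' @param torsion_available logical; defaults to the subject's deterministic
#'   torsion assignment (the first `round(torsion_fraction * n_subjects)`
#'   subjects have torsion).
#' @param events optional data frame of exact saccades to inject instead of
#'   a random event train: columns `onset` (s), `amplitude` (deg) and
#'   `direction` (deg); events must fit inside the trial and not overlap.
#'   Used for controlled detector validation.
#' @return a data frame in the gaze-sample dialect (`subject`, `trial`,
#'   `t_s`, `x_deg`, `y_deg`, `torsion_deg`, `head_tilt_nominal_deg`,
#'   `head_tilt_measured_deg`, `image_tilt_deg`, `image_type`), with the
#'   injected saccade events attached as `attr(, "events")` for
#'   ground-truth checks.
#' @export
generate_trial <- function(subject_id, trial_id, condition, config,
                           head_tilt_measured = NULL, torsion_available = NULL,
                           events = NULL) {
  config <- validate_gaze_config(config)
  if (!condition$head_tilt %in% config$head_tilts)
    stop("head_tilt not in configured set: ", condition$head_tilt)
  if (!condition$image_tilt %in% config$image_tilts)
    stop("image_tilt not in configured set: ", condition$image_tilt)
  if (!condition$image_type %in% config$image_types)
    stop("image_type not in configured set: ", condition$image_type)
  n <- round(config$trial_duration * config$sample_rate)
  if (n < 10) stop("trial_duration * sample_rate must give >= 10 samples")

  if (is.null(head_tilt_measured)) {
    head_tilt_measured <- with_seed(
      split_seed(config$seed, "tilt", subject_id, condition$head_tilt),
      measured_tilt_mean(condition$head_tilt) + rnorm(1, 0, config$head_tilt_jitter_sd))
  }
  if (is.null(torsion_available)) {
    torsion_available <- subject_id <= round(config$torsion_fraction * config$n_subjects)
  }

  with_seed(split_seed(config$seed, "trial", subject_id, trial_id), {
    t_s <- (seq_len(n) - 1) / config$sample_rate
    dur <- config$trial_duration

    # event train: fixation, saccade, fixation, ... truncated at trial end
    if (!is.null(events)) {
      stopifnot(all(c("onset", "amplitude", "direction") %in% names(events)))
      events <- events[order(events$onset), , drop = FALSE]
      events$duration <- saccade_duration(events$amplitude)
      if (nrow(events) > 0) {
        if (events$onset[1] < 0 ||
            any(events$onset + events$duration > dur))
          stop("injected events must lie inside the trial")
        if (nrow(events) > 1 &&
            any(events$onset[-1] < (events$onset + events$duration)[-nrow(events)]))
          stop("injected events must not overlap")
      }
      events <- events[, c("onset", "amplitude", "duration", "direction")]
    } else if (config$saccade_rate > 0) {
      n_ev <- ceiling(dur * config$saccade_rate * 2 + 10)
      fix_d <- rgamma(n_ev, shape = 4, scale = (1 / config$saccade_rate) / 4)
      amp <- rexp(n_ev, rate = 1 / config$amplitude_scale)
      amp <- pmax(amp, 0.25)          # floor: no degenerate zero-length saccades
      sac_d <- saccade_duration(amp)
      onset <- cumsum(fix_d + c(0, sac_d[-n_ev]))
      keep <- (onset + sac_d) < dur - 0.05
      events <- data.frame(onset = onset[keep], amplitude = amp[keep],
                           duration = sac_d[keep])
    } else {
      events <- data.frame(onset = numeric(0), amplitude = numeric(0),
                           duration = numeric(0))
    }
    k <- nrow(events)
    if (k > 0) {
      if (is.null(events$direction))
        events$direction <- sample_directions(k, config, head_tilt_measured)
      events$dx <- events$amplitude * cos(events$direction * pi / 180)
      events$dy <- events$amplitude * sin(events$direction * pi / 180)
    } else {
      events$direction <- events$dx <- events$dy <- numeric(0)
    }

    # position: step function of completed saccades + within-flight profile
    x <- y <- numeric(n)
    if (k > 0) {
      ends <- events$onset + events$duration
      idx <- findInterval(t_s, ends)        # completed saccades per sample
      cx <- c(0, cumsum(events$dx))
      cy <- c(0, cumsum(events$dy))
      x <- cx[idx + 1]
      y <- cy[idx + 1]
      for (i in seq_len(k)) {
        infl <- which(t_s >= events$onset[i] & t_s < ends[i])
        if (length(infl) > 0) {
          u <- (t_s[infl] - events$onset[i]) / events$duration[i]
          s <- saccade_profile(u)
          x[infl] <- cx[i] + events$dx[i] * s
          y[infl] <- cy[i] + events$dy[i] * s
        }
      }
    }
    x <- x + rnorm(n, 0, config$position_noise_sd)
    y <- y + rnorm(n, 0, config$position_noise_sd)

    torsion <- if (isTRUE(torsion_available)) {
      ocr_model(head_tilt_measured, config) + rnorm(n, 0, config$torsion_noise_sd)
    } else {
      rep(NA_real_, n)
    }

    out <- data.frame(
      subject = as.integer(subject_id), trial = as.integer(trial_id),
      t_s = t_s, x_deg = x, y_deg = y, torsion_deg = torsion,
      head_tilt_nominal_deg = condition$head_tilt,
      head_tilt_measured_deg = head_tilt_measured,
      image_tilt_deg = condition$image_tilt,
      image_type = condition$image_type,
      stringsAsFactors = FALSE)
    attr(out, "events") <- events
    out
  })
}

#' Generate a full synthetic study
#'
#' Populates the complete factorial design: for each subject and each
#' head-tilt block, `trials_per_cell` trials of every image type x image
#' tilt cell, in a deterministic order. Measured head tilt is drawn once
#' per subject x block. Identical `config` (including `seed`) gives
#' bit-identical output.
#'
#' @param config a [gaze_config()].
#' @param keep_events if `TRUE`, attach the injected ground-truth saccade
#'   events of every trial as `attr(, "events")`.
#' @return a data frame of gaze samples in the gaze CSV dialect (see
#'   [generate_trial()]), all trials concatenated.
#' @export
generate_study <- function(config, keep_events = FALSE) {
  config <- validate_gaze_config(config)
  cells <- expand.grid(image_type = config$image_types,
                       image_tilt = config$image_tilts,
                       stringsAsFactors = FALSE)
  trials <- vector("list", 0)
  ev_all <- vector("list", 0)
  for (s in seq_len(config$n_subjects)) {
    trial_id <- 0L
    for (ht in config$head_tilts) {
      tilt_meas <- with_seed(
        split_seed(config$seed, "tilt", s, ht),
        measured_tilt_mean(ht) + rnorm(1, 0, config$head_tilt_jitter_sd))
      for (ci in seq_len(nrow(cells))) {
        for (r in seq_len(config$trials_per_cell)) {
          trial_id <- trial_id + 1L
          tr <- generate_trial(
            s, trial_id,
            condition = list(head_tilt = ht, image_tilt = cells$image_tilt[ci],
                             image_type = cells$image_type[ci]),
            config = config, head_tilt_measured = tilt_meas)
          if (keep_events) {
            ev <- attr(tr, "events")
            if (nrow(ev) > 0) {
              ev$subject <- s
              ev$trial <- trial_id
              ev_all[[length(ev_all) + 1L]] <- ev
            }
          }
          attr(tr, "events") <- NULL
          trials[[length(trials) + 1L]] <- tr
        }
      }
    }
  }
  # column-wise concatenation (fast, avoids repeated data.frame rbind)
  nm <- names(trials[[1]])
  out <- as.data.frame(
    lapply(setNames(nm, nm), function(cn) unlist(lapply(trials, `[[`, cn), use.names = FALSE)),
    stringsAsFactors = FALSE)
  if (keep_events) {
    attr(out, "events") <- if (length(ev_all) > 0) do.call(rbind, ev_all) else NULL
  }
  out
}
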