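#' Saccade detection parameters
#'
#' Parameters of the velocity-threshold detector. The threshold for each
#' velocity component is `lambda_sd` times the robust (median-based)
#' standard deviation of that component, computed per trial, and a sample
#' is supra-threshold when the elliptic criterion
#' `(vx/eta_x)^2 + (vy/eta_y)^2 > 1` holds.
#'
#' @param lambda_sd multiplier of the robust standard deviation (default 8).
#' @param min_duration_ms minimum event duration in ms (default 25 ms,
#'   i.e. 3 samples at 120 Hz).
#' @param merge_interval_ms events separated by less than this are merged
#'   into one (default 25 ms).
#' @return an object of class `detection_params`.
#' @export
detection_params <- function(lambda_sd = 8, min_duration_ms = 25,
                             merge_interval_ms = 25) {
  stopifnot(lambda_sd > 0, min_duration_ms > 0, merge_interval_ms >= 0)
  structure(list(lambda_sd = lambda_sd, min_duration_ms = min_duration_ms,
                 merge_interval_ms = merge_interval_ms),
            class = "detection_params")
}

#' Instantaneous velocity by differential smoothing filter
#'
#' Five-point differentiating kernel
#' `v_n = (x_(n+2) + x_(n+1) - x_(n-1) - x_(n-2)) / (6 dt)`,
#' exact for polynomials of degree <= 2. The first and last two samples
#' have no defined velocity and are returned as `NA` (and excluded from
#' all downstream statistics).
#'
#' @param x numeric position series, degrees.
#' @param dt sampling interval, seconds.
#' @return velocity series in deg/s, same length as `x`.
#' @export
compute_velocity <- function(x, dt) {
  n <- length(x)
  if (n < 5) stop("position series must have >= 5 samples")
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  v <- rep(NA_real_, n)
  i <- 3:(n - 2)
  v[i] <- (x[i + 2] + x[i + 1] - x[i - 1] - x[i - 2]) / (6 * dt)
  v
}

#' Robust standard deviation
#'
#' Median-based spread estimator
#' `sigma = sqrt(median(v^2) - median(v)^2)`, insensitive to a minority of
#' outliers; used to set velocity thresholds.
#'
#' @param v numeric vector; `NA`s are dropped.
#' @return nonnegative scalar.
#' @export
robust_std <- function(v) {
  v <- v[is.finite(v)]
  if (length(v) == 0) stop("robust_std: no finite samples")
  sqrt(max(median(v^2) - median(v)^2, 0))
}

#' Four-quadrant saccade direction
#'
#' Direction of a displacement vector, counterclockwise-positive from
#' rightward horizontal with y upward, in `[0, 360)`.
#'
#' @param dx,dy displacement components, degrees.
#' @return angle in degrees; vectorised.
#' @examples
#' saccade_direction(1, 0)    # 0
#' saccade_direction(0, 1)    # 90
#' saccade_direction(-1, -1)  # 225
#' @export
saccade_direction <- function(dx, dy) {
  if (any(dx == 0 & dy == 0)) stop("zero displacement has no direction")
  (atan2(dy, dx) * 180 / pi) %% 360
}

#' Detect saccades in one gaze trial
#'
#' Velocity-threshold detection: component velocities from
#' [compute_velocity()], per-trial thresholds `eta = lambda_sd *`
#' [robust_std()] per component, supra-threshold samples from the elliptic
#' criterion, runs shorter than `min_duration_ms` discarded, runs closer
#' than `merge_interval_ms` merged. Event amplitude and direction are
#' taken from the total displacement between onset and offset samples.
#'
#' @param trial data frame with columns `t_s`, `x_deg`, `y_deg`
#'   (one trial's samples, timestamps strictly increasing).
#' @param params a [detection_params()].
#' @return data frame with one row per saccade: `onset_t`, `offset_t`,
#'   `duration_ms`, `amplitude_deg`, `peak_vel_dps`, `direction_deg`,
#'   sorted by onset. Zero rows when nothing crosses threshold.
#' @export
detect_saccades <- function(trial, params = detection_params()) {
  need <- c("t_s", "x_deg", "y_deg")
  miss <- setdiff(need, names(trial))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  t_s <- trial$t_s
  if (any(diff(t_s) <= 0)) stop("timestamps must be strictly increasing")
  n <- length(t_s)
  empty <- data.frame(onset_t = numeric(0), offset_t = numeric(0),
                      duration_ms = numeric(0), amplitude_deg = numeric(0),
                      peak_vel_dps = numeric(0), direction_deg = numeric(0))
  if (n < 5) return(empty)
  dt <- median(diff(t_s))
  vx <- compute_velocity(trial$x_deg, dt)
  vy <- compute_velocity(trial$y_deg, dt)
  # floor guards the noise-free degenerate case (exactly constant position)
  ex <- params$lambda_sd * max(robust_std(vx), 1e-12)
  ey <- params$lambda_sd * max(robust_std(vy), 1e-12)
  crit <- (vx / ex)^2 + (vy / ey)^2 > 1
  crit[is.na(crit)] <- FALSE
  if (!any(crit)) return(empty)

  r <- rle(crit)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  on <- starts[r$values]
  off <- ends[r$values]

  # merge runs separated by fewer than merge_interval samples
  gap_smp <- round(params$merge_interval_ms / 1000 / dt)
  if (length(on) > 1 && gap_smp > 0) {
    keep_on <- on[1]
    merged_on <- integer(0); merged_off <- integer(0)
    cur_on <- on[1]; cur_off <- off[1]
    for (i in seq_along(on)[-1]) {
      if (on[i] - cur_off - 1L < gap_smp) {
        cur_off <- off[i]
      } else {
        merged_on <- c(merged_on, cur_on); merged_off <- c(merged_off, cur_off)
        cur_on <- on[i]; cur_off <- off[i]
      }
    }
    merged_on <- c(merged_on, cur_on); merged_off <- c(merged_off, cur_off)
    on <- merged_on; off <- merged_off
  }

  min_smp <- max(1L, round(params$min_duration_ms / 1000 / dt))
  keep <- (off - on + 1L) >= min_smp
  on <- on[keep]; off <- off[keep]
  if (length(on) == 0) return(empty)

  spd <- sqrt(vx^2 + vy^2)
  dx <- trial$x_deg[off] - trial$x_deg[on]
  dy <- trial$y_deg[off] - trial$y_deg[on]
  amp <- sqrt(dx^2 + dy^2)
  dir <- ifelse(amp > 0, (atan2(dy, dx) * 180 / pi) %% 360, NA_real_)
  data.frame(
    onset_t = t_s[on], offset_t = t_s[off],
    duration_ms = (t_s[off] - t_s[on]) * 1000,
    amplitude_deg = amp,
    peak_vel_dps = vapply(seq_along(on),
                          function(i) max(spd[on[i]:off[i]], na.rm = TRUE), 0),
    direction_deg = dir)
}

#' Detect saccades across a whole gaze table
#'
#' Runs [detect_saccades()] on every subject x trial group of a
#' gaze-sample table and carries the condition columns onto the events.
#'
#' @param gaze data frame in the gaze CSV dialect (see [generate_trial()]).
#' @param params a [detection_params()].
#' @return a saccade table: one row per event with `subject`, `trial`, the
#'   event columns of [detect_saccades()], and the trial's condition
#'   columns.
#' @export
detect_study <- function(gaze, params = detection_params()) {
  need <- c("subject", "trial", "t_s", "x_deg", "y_deg")
  miss <- setdiff(need, names(gaze))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  cond_cols <- intersect(
    c("head_tilt_nominal_deg", "head_tilt_measured_deg", "image_tilt_deg",
      "image_type"), names(gaze))
  key <- paste(gaze$subject, gaze$trial, sep = "\r")
  idx <- split(seq_len(nrow(gaze)), key)
  out <- vector("list", length(idx))
  for (i in seq_along(idx)) {
    rows <- idx[[i]]
    tr <- gaze[rows, , drop = FALSE]
    ev <- detect_saccades(tr, params)
    if (nrow(ev) == 0) { out[[i]] <- NULL; next }
    meta <- tr[1, c("subject", "trial", cond_cols), drop = FALSE]
    out[[i]] <- cbind(meta[rep(1, nrow(ev)), , drop = FALSE], ev,
                      row.names = NULL)
  }
  out <- out[!vapply(out, is.null, TRUE)]
  if (length(out) == 0) {
    ev <- detect_saccades(gaze[seq_len(min(5, nrow(gaze))), , drop = FALSE], params)
    return(cbind(gaze[0, c("subject", "trial", cond_cols), drop = FALSE], ev[0, ]))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$subject, res$trial, res$onset_t), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Main-sequence diagnostic
#'
#' Amplitude versus peak velocity of detected saccades, with the Spearman
#' rank correlation as a sanity check that events obey the stereotyped
#' main sequence (larger saccades are faster).
#'
#' @param saccades a saccade table with `amplitude_deg`, `peak_vel_dps`
#'   (>= 3 rows).
#' @return list with `table` (amplitude, peak velocity pairs) and `rho`
#'   (Spearman correlation; `NA` when degenerate, e.g. all amplitudes
#'   identical).
#' @export
main_sequence <- function(saccades) {
  if (nrow(saccades) < 3) stop("need >= 3 saccades for a main sequence")
  a <- saccades$amplitude_deg
  v <- saccades$peak_vel_dps
  rho <- if (sd(a) == 0 || sd(v) == 0) NA_real_ else
    cor(a, v, method = "spearman")
  list(table = data.frame(amplitude_deg = a, peak_vel_dps = v), rho = rho)
}
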