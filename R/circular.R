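#' Circular KDE parameters
#'
#' Grid and kernel of the circular kernel density estimate: a wrapped
#' Gaussian of standard deviation `kernel_width` radians evaluated on a
#' regular grid from 0 to 360 degrees (exclusive) in steps of `grid_step`.
#'
#' @param kernel_width kernel standard deviation in radians (default 0.1,
#'   about 5.73 degrees).
#' @param grid_step grid resolution in degrees (default 0.1); must divide
#'   360 exactly.
#' @return an object of class `kde_params`.
#' @export
kde_params <- function(kernel_width = 0.1, grid_step = 0.1) {
  stopifnot(kernel_width > 0, grid_step > 0)
  m <- 360 / grid_step
  if (abs(m - round(m)) > 1e-9) stop("grid_step must divide 360 exactly")
  structure(list(kernel_width = kernel_width, grid_step = grid_step,
                 n_grid = as.integer(round(m))),
            class = "kde_params")
}

kde_grid <- function(params) (seq_len(params$n_grid) - 1) * params$grid_step

# Wrapped Gaussian kernel evaluated at every grid offset, per-degree units.
wrapped_kernel <- function(params) {
  g <- kde_grid(params)
  sigma <- params$kernel_width * 180 / pi
  k <- numeric(params$n_grid)
  for (w in -2:2) k <- k + dnorm(g + 360 * w, 0, sigma)
  k
}

# Linear binning of angles (degrees) onto the circular grid; returns counts
# (total mass = length(angles)). Grid-aligned angles land in a single bin,
# so grid-multiple shifts of the data shift the binned mass exactly.
bin_angles <- function(angles, params) {
  m <- params$n_grid
  p <- (angles %% 360) / params$grid_step
  i0 <- floor(p)
  w1 <- p - i0
  counts <- numeric(m)
  lo <- (as.integer(i0) %% m) + 1L
  hi <- (as.integer(i0 + 1) %% m) + 1L
  add <- function(idx, w) {
    tab <- rowsum(w, idx)
    counts[as.integer(rownames(tab))] <<- counts[as.integer(rownames(tab))] + tab[, 1]
  }
  add(lo, 1 - w1)
  if (any(w1 > 0)) add(hi[w1 > 0], w1[w1 > 0])
  counts
}

#' Circular kernel density estimate of saccade directions
#'
#' Smooths a set of angles with a wrapped Gaussian kernel on the regular
#' circular grid defined by `params`, returning a density normalised so
#' that `sum(density) * grid_step == 1`. The default engine bins the
#' angles linearly onto the grid and convolves with the kernel by FFT;
#' `method = "direct"` evaluates the wrapped kernel at every grid point
#' exactly (slower; used as an independent cross-check).
#'
#' @param angles numeric vector of directions in degrees (any real values;
#'   reduced modulo 360).
#' @param params a [kde_params()].
#' @param method `"fft"` (binned convolution) or `"direct"` (exact).
#' @return an object of class `direction_distribution`: list with `grid`
#'   (degrees), `density` (per-degree values), `n`, and `params`.
#' @export
circular_kde <- function(angles, params = kde_params(),
                         method = c("fft", "direct")) {
  method <- match.arg(method)
  if (length(angles) == 0) stop("no angles supplied")
  if (any(!is.finite(angles))) stop("angles must be finite")
  m <- params$n_grid
  if (method == "fft") {
    counts <- bin_angles(angles, params)
    kern <- wrapped_kernel(params)
    dens <- Re(fft(fft(counts) * fft(kern), inverse = TRUE)) / m
    dens <- pmax(dens, 0)
  } else {
    g <- kde_grid(params)
    sigma <- params$kernel_width * 180 / pi
    a <- angles %% 360
    dens <- numeric(m)
    chunk <- 512L
    for (s in seq(1L, length(a), by = chunk)) {
      aa <- a[s:min(s + chunk - 1L, length(a))]
      d <- outer(g, aa, `-`)
      d <- ((d + 180) %% 360) - 180
      dens <- dens + rowSums(dnorm(d, 0, sigma) + dnorm(d + 360, 0, sigma) +
                               dnorm(d - 360, 0, sigma))
    }
  }
  dens <- dens / (sum(dens) * params$grid_step)
  structure(list(grid = kde_grid(params), density = dens,
                 n = length(angles), params = params),
            class = "direction_distribution")
}

#' @export
print.direction_distribution <- function(x, ...) {
  cat("Circular direction distribution\n")
  cat(sprintf("  n = %d angles, grid step %.3g deg, kernel sd %.3g rad\n",
              x$n, x$params$grid_step, x$params$kernel_width))
  mode_i <- which.max(x$density)
  cat(sprintf("  mode at %.1f deg (density %.4g per deg)\n",
              x$grid[mode_i], x$density[mode_i]))
  invisible(x)
}

#' Rotate a direction distribution by a grid-multiple angle
#'
#' Returns the distribution rotated clockwise by `delta` degrees (a peak
#' at angle a moves to a - delta). `delta` must be a multiple of the grid
#' step, so the rotation is an exact circular shift.
#'
#' @param dist a `direction_distribution`.
#' @param delta clockwise rotation in degrees.
#' @return a rotated `direction_distribution`.
#' @export
rotate_distribution <- function(dist, delta) {
  step <- dist$params$grid_step
  k <- delta / step
  if (abs(k - round(k)) > 1e-9) stop("delta must be a multiple of the grid step")
  m <- dist$params$n_grid
  k <- round(k) %% m
  idx <- ((seq_len(m) - 1 + k) %% m) + 1
  out <- dist
  out$density <- dist$density[idx]
  out
}

# Correlation between dist_test and dist_ref shifted by each candidate lag.
# Positive lag = test rotated clockwise relative to ref.
xcorr_values <- function(ref, test, lags_k, m, method, stat) {
  if (method == "fft") {
    s_all <- Re(fft(Conj(fft(test)) * fft(ref), inverse = TRUE)) / m
    s <- s_all[(lags_k %% m) + 1]
    if (stat == "dot") return(s)
    mt <- mean(test); mr <- mean(ref)
    return((s - m * mt * mr) / ((m - 1) * sd(test) * sd(ref)))
  }
  if (method == "concat") {
    ref3 <- rep(ref, 3)
    shifted <- function(k) ref3[(m + 1 + k):(2 * m + k)]
  } else {
    shifted <- function(k) ref[(((seq_len(m) - 1 + k) %% m)) + 1]
  }
  vapply(lags_k, function(k) {
    r <- shifted(k)
    if (stat == "dot") sum(test * r) else cor(test, r)
  }, 0)
}

# Deterministic peak pick: max correlation; among (numerical) ties the
# smallest |lag| wins, and +lag beats -lag at equal magnitude.
pick_peak <- function(vals, lags_deg) {
  mx <- max(vals)
  tol <- 1e-12 * max(1, abs(mx))
  cand <- which(vals >= mx - tol)
  cand <- cand[order(abs(lags_deg[cand]), -lags_deg[cand])]
  cand[1]
}

#' Angular displacement between two direction distributions
#'
#' Finds the lag, within `[-max_lag, +max_lag]` degrees, that maximises
#' the correlation between `dist_test` and a circularly shifted
#' `dist_ref`. The window guards against the spurious peaks the 90/180
#' degree symmetry of cardinal-bias distributions would otherwise produce.
#' A positive displacement means `dist_test` is rotated clockwise relative
#' to `dist_ref`.
#'
#' Three interchangeable engines are provided: `"concat"` literally
#' repeats the reference density three times and slides a window over the
#' concatenation; `"shift"` indexes circular shifts directly; `"fft"`
#' computes all circular cross-correlation sums at once by the convolution
#' theorem. All three agree lag-for-lag to machine precision.
#'
#' @param dist_ref,dist_test `direction_distribution`s on the same grid.
#' @param max_lag half-width of the lag search window, degrees (default 45).
#' @param method `"concat"`, `"shift"`, or `"fft"`.
#' @param stat correlation statistic per lag: `"pearson"` (default) or
#'   `"dot"` (raw inner product of the densities).
#' @return an object of class `displacement`: list with `delta` (degrees,
#'   clockwise-positive), `peak_correlation`, `ci_low`/`ci_high` (`NA`
#'   until bootstrapped), `n_boot`, `max_lag`, `stat`.
#' @seealso [bootstrap_displacement()]
#' @export
circular_xcorr_displacement <- function(dist_ref, dist_test, max_lag = 45,
                                        method = c("concat", "shift", "fft"),
                                        stat = c("pearson", "dot")) {
  method <- match.arg(method)
  stat <- match.arg(stat)
  step <- dist_ref$params$grid_step
  if (!isTRUE(all.equal(dist_ref$grid, dist_test$grid)))
    stop("distributions are not on the same grid")
  m <- dist_ref$params$n_grid
  K <- round(max_lag / step)
  lags_k <- -K:K
  lags_deg <- lags_k * step
  vals <- xcorr_values(dist_ref$density, dist_test$density, lags_k, m,
                       method, stat)
  i <- pick_peak(vals, lags_deg)
  structure(list(delta = lags_deg[i], peak_correlation = vals[i],
                 ci_low = NA_real_, ci_high = NA_real_, n_boot = 0L,
                 max_lag = max_lag, stat = stat, method = method),
            class = "displacement")
}

#' @export
print.displacement <- function(x, ...) {
  cat(sprintf("Direction distribution displacement: %.2f deg (peak %s %.4f)\n",
              x$delta, x$stat, x$peak_correlation))
  if (x$n_boot > 0)
    cat(sprintf("  bootstrap 95%% CI [%.2f, %.2f], %d replicates\n",
                x$ci_low, x$ci_high, x$n_boot))
  invisible(x)
}

#' Bootstrap confidence interval for the displacement
#'
#' Resamples each angle set with replacement, recomputes the KDE pair and
#' the displacement for every replicate, and returns the percentile
#' 2.5/97.5 bounds around the full-sample estimate. Deterministic under
#' `seed`. Replicates use the FFT cross-correlation engine.
#'
#' @param angles_ref,angles_test direction samples (degrees) for the
#'   reference and test conditions.
#' @param kde a [kde_params()].
#' @param n_boot number of bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling stream.
#' @param max_lag,stat as in [circular_xcorr_displacement()].
#' @return a `displacement` object with `ci_low`, `ci_high`, `n_boot` set.
#' @export
bootstrap_displacement <- function(angles_ref, angles_test,
                                   kde = kde_params(), n_boot = 1000,
                                   seed = 1, max_lag = 45,
                                   stat = c("pearson", "dot")) {
  stat <- match.arg(stat)
  if (length(angles_ref) == 0 || length(angles_test) == 0)
    stop("empty angle sample")
  stopifnot(n_boot >= 1)
  d_ref <- circular_kde(angles_ref, kde)
  d_test <- circular_kde(angles_test, kde)
  est <- circular_xcorr_displacement(d_ref, d_test, max_lag = max_lag,
                                     method = "fft", stat = stat)
  m <- kde$n_grid
  K <- round(max_lag / kde$grid_step)
  lags_k <- -K:K
  lags_deg <- lags_k * kde$grid_step
  kern_f <- fft(wrapped_kernel(kde))
  one_kde <- function(a) {
    dens <- Re(fft(fft(bin_angles(a, kde)) * kern_f, inverse = TRUE)) / m
    dens <- pmax(dens, 0)
    dens / (sum(dens) * kde$grid_step)
  }
  reps <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      ar <- angles_ref[sample.int(length(angles_ref), replace = TRUE)]
      at <- angles_test[sample.int(length(angles_test), replace = TRUE)]
      vals <- xcorr_values(one_kde(ar), one_kde(at), lags_k, m, "fft", stat)
      lags_deg[pick_peak(vals, lags_deg)]
    }, 0)
  })
  ci <- unname(quantile(reps, c(0.025, 0.975)))
  out <- est
  # percentile bounds; widened (rarely) to bracket the point estimate
  out$ci_low <- min(ci[1], est$delta)
  out$ci_high <- max(ci[2], est$delta)
  out$n_boot <- as.integer(n_boot)
  out$replicates <- reps
  out
}

#' Head/world coordinate transforms for saccade directions
#'
#' With directions counterclockwise-positive and head tilt positive for
#' clockwise (rightward) head roll, a direction measured in head/display
#' coordinates corresponds to `angle - head_tilt` in world (gravity)
#' coordinates; `world_to_head()` inverts the transform exactly.
#'
#' @param angle direction in degrees.
#' @param head_tilt measured head tilt in degrees.
#' @return angle in `[0, 360)`; vectorised.
#' @examples
#' head_to_world(0, 30)                 # 330
#' world_to_head(head_to_world(77, 12), 12)  # 77
#' @export
head_to_world <- function(angle, head_tilt) {
  if (any(!is.finite(angle)) || any(!is.finite(head_tilt)))
    stop("inputs must be finite")
  (angle - head_tilt) %% 360
}

#' @rdname head_to_world
#' @export
world_to_head <- function(angle, head_tilt) {
  if (any(!is.finite(angle)) || any(!is.finite(head_tilt)))
    stop("inputs must be finite")
  (angle + head_tilt) %% 360
}
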