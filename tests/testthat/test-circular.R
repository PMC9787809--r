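test_that("kde parameters are validated", {
  expect_error(kde_params(kernel_width = 0), "kernel_width")
  expect_error(kde_params(grid_step = 0.07), "divide 360")
  expect_equal(kde_params(grid_step = 0.5)$n_grid, 720L)
})

test_that("circular KDE is normalised and uniform for uniform input", {
  kp <- kde_params()
  g <- (0:3599) * 0.1
  d <- circular_kde(g, kp)
  expect_lt(max(abs(d$density - 1 / 360)), 1e-6)
  set.seed(2)
  for (a in list(runif(7, 0, 360), c(0.05), rnorm(500, 90, 40) %% 360)) {
    dd <- circular_kde(a, kp)
    expect_lt(abs(sum(dd$density) * kp$grid_step - 1), 1e-9)
    expect_true(all(dd$density >= 0))
  }
  expect_error(circular_kde(numeric(0)), "no angles")
  expect_error(circular_kde(c(10, NA)), "finite")
})

test_that("KDE respects kernel symmetry and modular arithmetic", {
  kp <- kde_params()
  d <- circular_kde(0, kp)
  at <- function(dd, ang) dd$density[round(ang / kp$grid_step) + 1]
  expect_equal(at(d, 10), at(d, 350), tolerance = 1e-12)
  expect_equal(which.max(d$density), 1)

  d4 <- circular_kde(c(0, 90, 180, 270), kp)
  expect_equal(at(d4, 0), at(d4, 90), tolerance = 1e-12)
  expect_equal(at(d4, 45), at(d4, 135), tolerance = 1e-12)

  set.seed(3)
  a <- runif(50, 0, 360)
  expect_equal(circular_kde(a, kp)$density,
               circular_kde(a + 720, kp)$density, tolerance = 1e-12)
})

test_that("KDE is shift-equivariant", {
  kp <- kde_params()
  set.seed(5)
  a <- c(rnorm(300, 0, 20), rnorm(200, 90, 25)) %% 360
  base <- circular_kde(a, kp)
  # exact for grid-multiple shifts: rotating data counterclockwise by c
  # moves density counterclockwise, i.e. equals clockwise rotation by -c
  shifted <- circular_kde(a + 30, kp)
  expect_equal(shifted$density, rotate_distribution(base, -30)$density,
               tolerance = 1e-12)
  # general shifts agree within linear-binning tolerance
  shifted2 <- circular_kde(a + 30.04, kp)
  ref <- circular_kde(a + 30, kp)
  expect_lt(max(abs(shifted2$density - rotate_distribution(base, -30)$density)),
            2e-4)
})

test_that("binned-FFT and direct KDE evaluation agree", {
  kp <- kde_params()
  set.seed(11)
  a <- c(rnorm(150, 10, 15), rnorm(100, 200, 30)) %% 360
  expect_lt(max(abs(circular_kde(a, kp, "fft")$density -
                    circular_kde(a, kp, "direct")$density)), 1e-5)
})

test_that("displacement is zero for identical distributions and exact for shifts", {
  kp <- kde_params()
  set.seed(6)
  d <- circular_kde(c(rnorm(800, 0, 25), rnorm(300, 90, 25)) %% 360, kp)
  expect_equal(circular_xcorr_displacement(d, d)$delta, 0)
  for (rot in c(20, -13.5, 44.9)) {
    r <- circular_xcorr_displacement(d, rotate_distribution(d, rot))
    expect_equal(r$delta, rot)
  }
})

test_that("the +-45 degree window resolves 90-degree-symmetric aliases", {
  kp <- kde_params()
  dsym <- circular_kde(c(0, 90, 180, 270), kp)  # exactly 90-deg symmetric
  r <- circular_xcorr_displacement(dsym, rotate_distribution(dsym, 50))
  expect_equal(r$delta, -40)
})

test_that("all three cross-correlation engines agree lag-for-lag", {
  kp <- kde_params(grid_step = 0.5)  # coarser grid keeps the loop engines fast
  set.seed(8)
  for (i in 1:5) {
    n1 <- sample(50:400, 1); n2 <- sample(50:400, 1)
    d1 <- circular_kde(runif(n1, 0, 360), kp)
    d2 <- circular_kde((rnorm(n2, 45, 30)) %% 360, kp)
    m <- kp$n_grid
    lags <- -90:90
    for (stat in c("pearson", "dot")) {
      v_concat <- gazeframe:::xcorr_values(d1$density, d2$density, lags, m,
                                           "concat", stat)
      v_shift <- gazeframe:::xcorr_values(d1$density, d2$density, lags, m,
                                          "shift", stat)
      v_fft <- gazeframe:::xcorr_values(d1$density, d2$density, lags, m,
                                        "fft", stat)
      expect_equal(v_concat, v_shift, tolerance = 1e-12)
      expect_equal(v_fft, v_shift, tolerance = 1e-9)
    }
  }
})

test_that("pearson and dot statistics agree on the argmax for rotated pairs", {
  kp <- kde_params()
  set.seed(13)
  d <- circular_kde(c(rnorm(600, 0, 20), rnorm(250, 90, 20)) %% 360, kp)
  dr <- rotate_distribution(d, 17)
  expect_equal(circular_xcorr_displacement(d, dr, stat = "pearson")$delta,
               circular_xcorr_displacement(d, dr, stat = "dot")$delta)
})

test_that("swapping reference and test negates the displacement", {
  kp <- kde_params()
  set.seed(14)
  a1 <- c(rnorm(500, 5, 22), rnorm(200, 95, 22)) %% 360
  a2 <- (a1 - 12) %% 360
  d1 <- circular_kde(a1, kp); d2 <- circular_kde(a2, kp)
  f <- circular_xcorr_displacement(d1, d2)
  b <- circular_xcorr_displacement(d2, d1)
  expect_equal(f$delta, -b$delta, tolerance = kp$grid_step + 1e-9)
  expect_error(circular_xcorr_displacement(d1, circular_kde(a1, kde_params(grid_step = 0.5))),
               "grid")
})

test_that("bootstrap CIs are deterministic, tight for identical samples", {
  set.seed(21)
  cfg <- gaze_config(anchor = "head", concentration = 4)
  a <- sample_directions(5000, cfg, 0)
  b1 <- bootstrap_displacement(a, a, n_boot = 150, seed = 9)
  b2 <- bootstrap_displacement(a, a, n_boot = 150, seed = 9)
  expect_identical(b1$ci_low, b2$ci_low)
  expect_identical(b1$ci_high, b2$ci_high)
  expect_lte(b1$ci_low, 0)
  expect_gte(b1$ci_high, 0)
  # estimator sd at n = 5000 is bounded below by ~1.3 degrees (information
  # bound for this mixture), so the 95% interval is a few degrees wide
  expect_lt(b1$ci_high - b1$ci_low, 7)
  expect_true(b1$ci_low <= b1$delta && b1$delta <= b1$ci_high)
  expect_error(bootstrap_displacement(numeric(0), a), "empty")
})

test_that("head/world transforms follow the stated convention and invert", {
  expect_equal(head_to_world(0, 30), 330)
  expect_equal(head_to_world(90, 0), 90)
  expect_equal(world_to_head(330, 30), 0)
  set.seed(17)
  th <- runif(1000, 0, 360); ta <- runif(1000, -60, 60)
  expect_equal(world_to_head(head_to_world(th, ta), ta), th, tolerance = 1e-9)
  expect_error(head_to_world(NA, 3), "finite")
})

test_that("the reference frame index matches its limiting cases", {
  expect_equal(rf_index(26.91, -26.91, 26.91)$value, 1)
  expect_equal(rf_index(0, 0, 26.91)$value, 0)
  r <- rf_index(12.01, -8.32, 26.91)
  expect_equal(round(r$value, 2), 0.38)
  expect_equal(r$signed, r$value)  # positive case keeps its sign
  expect_error(rf_index(1, -1, 0), "T must be > 0")
  # vectorised over subjects
  rv <- rf_index(c(10, -10), c(-10, 10), 10)
  expect_equal(rv$value, c(1, 1))
  expect_equal(rv$signed, c(1, -1))
})

test_that("counter-roll scaling hits its retinal and head limits", {
  expect_equal(ocr_scaled_rf_index(3, -3, 3, -3)$value, 1)
  expect_equal(ocr_scaled_rf_index(0, 0, 3, -3)$value, 0)
  z <- ocr_scaled_rf_index(c(3, 2), c(-3, -2), c(3, 0), c(-3, -2))
  expect_true(is.na(z$value[2]))
  expect_true(z$excluded[2])
  expect_false(z$excluded[1])
})

test_that("Earth-upright selection picks the cancelling cells", {
  grid <- expand.grid(subject = 1:2, head_tilt_nominal_deg = c(-30, 0, 30),
                      image_tilt_deg = c(-30, 0, 30),
                      image_type = c("fractal", "scene"),
                      stringsAsFactors = FALSE)
  sel <- select_earth_upright(grid)
  expect_equal(nrow(sel$cells), 3)
  expect_equal(length(sel$pairs), 2)
  expect_equal(sel$pairs[[1]]$test, c(head = -30, image = 30))
  expect_equal(sel$pairs[[2]]$test, c(head = 30, image = -30))
  expect_null(sel$missing)

  fr <- grid[grid$image_type == "fractal", ]
  expect_warning(sel2 <- select_earth_upright(fr), "no Earth-upright")
  expect_equal(nrow(sel2$cells), 0)

  # a subject missing a cell is reported
  drop <- !(grid$subject == 2 & grid$head_tilt_nominal_deg == 30 &
              grid$image_tilt_deg == -30 & grid$image_type == "scene")
  sel3 <- select_earth_upright(grid[drop, ])
  expect_equal(sel3$missing$subject, 2)
})

test_that("group summaries collapse correctly in degenerate cases", {
  g <- group_summary(rep(10, 5))
  expect_equal(g$mean, 10)
  expect_equal(c(g$ci_low, g$ci_high), c(10, 10))
  expect_equal(group_summary(c(-1, 1))$mean, 0)
  expect_error(group_summary(5), ">= 2")
})
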