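#' Fit the reference-frame displacement model to a saccade table
#'
#' The top-level estimator. For a chosen analysis it pools each subject's
#' saccade directions per condition, builds circular KDEs, estimates the
#' angular displacement of each tilted condition against upright by
#' circular cross-correlation, optionally bootstraps per-subject 95% CIs,
#' and summarises anchoring with the reference frame index.
#'
#' Analyses:
#' \describe{
#'   \item{`fractal_head_tilt`}{Fractal trials across head tilts.
#'     Displacements are computed in head/display coordinates (the
#'     measurement frame; the RFindex then contrasts head against
#'     world/retina anchoring) and additionally in world coordinates
#'     (by rotating each direction by the measured head tilt).}
#'   \item{`scene_earth_upright`}{Scene trials in which the image tilt
#'     cancels the head tilt, so the scene is Earth-upright throughout;
#'     displacements in world coordinates (measurement frame = image/world;
#'     RFindex contrasts image against head anchoring).}
#'   \item{`scene_tilt_upright`}{Scene trials with the head upright and
#'     the image tilted; displacements in display coordinates, scaled by
#'     the image tilt.}
#' }
#'
#' @param saccades saccade table as produced by [detect_study()] (columns
#'   `subject`, `direction_deg`, `head_tilt_nominal_deg`,
#'   `head_tilt_measured_deg`, `image_tilt_deg`, `image_type`).
#' @param analysis which condition contrast to fit (see Details).
#' @param kde a [kde_params()].
#' @param max_lag displacement search half-window, degrees.
#' @param stat per-lag correlation statistic, `"pearson"` or `"dot"`.
#' @param n_boot per-subject bootstrap replicates for displacement CIs
#'   (0 = skip; CIs are the expensive part).
#' @param seed integer seed governing all resampling.
#' @param tilt_scale how to choose the RFindex scale T: `"measured"`
#'   (group mean absolute measured head tilt; default), `"nominal"`
#'   (mean absolute nominal tilt), or a positive number.
#' @param torsion optional [torsion_summary()]; when supplied (and the
#'   analysis is `fractal_head_tilt`) the counter-roll-scaled reference
#'   frame index is computed as well.
#' @return an object of class `rf_fit`; see [print.rf_fit()],
#'   [summary.rf_fit()], [coef.rf_fit()], [confint.rf_fit()],
#'   [plot.rf_fit()].
#' @examples
#' cfg <- gaze_config(n_subjects = 3, trials_per_cell = 1, trial_duration = 5,
#'                    image_types = "fractal", anchor = "head", seed = 42)
#' sacc <- detect_study(generate_study(cfg))
#' fit <- rf_fit(sacc, "fractal_head_tilt")
#' fit
#' coef(fit)
#' @export
rf_fit <- function(saccades,
                   analysis = c("fractal_head_tilt", "scene_earth_upright",
                                "scene_tilt_upright"),
                   kde = kde_params(), max_lag = 45,
                   stat = c("pearson", "dot"), n_boot = 0, seed = 1,
                   tilt_scale = c("measured", "nominal"), torsion = NULL) {
  analysis <- match.arg(analysis)
  stat <- match.arg(stat)
  need <- c("subject", "direction_deg", "head_tilt_nominal_deg",
            "head_tilt_measured_deg", "image_tilt_deg", "image_type")
  miss <- setdiff(need, names(saccades))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  saccades <- saccades[is.finite(saccades$direction_deg), , drop = FALSE]

  spec <- switch(analysis,
    fractal_head_tilt = {
      d <- saccades[saccades$image_type == "fractal", , drop = FALSE]
      if (nrow(d) == 0) stop("no fractal trials in the saccade table")
      tl <- sort(unique(d$head_tilt_nominal_deg))
      if (length(tl) < 3 || !(0 %in% tl))
        stop("fractal_head_tilt needs head tilts {-T, 0, +T}")
      list(data = d, group_col = "head_tilt_nominal_deg",
           pos = max(tl), neg = min(tl), ref = 0, frames = c("head", "world"))
    },
    scene_earth_upright = {
      sel <- select_earth_upright(saccades)
      if (nrow(sel$cells) < 3)
        stop("scene_earth_upright needs the three Earth-upright cells")
      d <- saccades[sel$rows, , drop = FALSE]
      tl <- sort(unique(d$head_tilt_nominal_deg))
      list(data = d, group_col = "head_tilt_nominal_deg",
           pos = max(tl), neg = min(tl), ref = 0, frames = "world",
           selection = sel)
    },
    scene_tilt_upright = {
      d <- saccades[saccades$image_type == "scene" &
                      saccades$head_tilt_nominal_deg == 0, , drop = FALSE]
      if (nrow(d) == 0) stop("no head-upright scene trials")
      tl <- sort(unique(d$image_tilt_deg))
      if (length(tl) < 3 || !(0 %in% tl))
        stop("scene_tilt_upright needs image tilts {-T, 0, +T}")
      list(data = d, group_col = "image_tilt_deg",
           pos = max(tl), neg = min(tl), ref = 0, frames = "head")
    })

  d <- spec$data
  subjects <- sort(unique(d$subject))
  dir_in_frame <- function(rows, frame) {
    if (frame == "world") {
      head_to_world(d$direction_deg[rows], d$head_tilt_measured_deg[rows])
    } else {
      d$direction_deg[rows]
    }
  }
  one_contrast <- function(s, level, frame) {
    ref_rows <- which(d$subject == s & d[[spec$group_col]] == spec$ref)
    test_rows <- which(d$subject == s & d[[spec$group_col]] == level)
    if (length(ref_rows) == 0 || length(test_rows) == 0)
      return(list(delta = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                  n_ref = length(ref_rows), n_test = length(test_rows)))
    a_ref <- dir_in_frame(ref_rows, frame)
    a_test <- dir_in_frame(test_rows, frame)
    if (n_boot > 0) {
      dd <- bootstrap_displacement(a_ref, a_test, kde, n_boot = n_boot,
                                   seed = split_seed(seed, "boot", s, level, frame),
                                   max_lag = max_lag, stat = stat)
    } else {
      dd <- circular_xcorr_displacement(circular_kde(a_ref, kde),
                                        circular_kde(a_test, kde),
                                        max_lag = max_lag, method = "fft",
                                        stat = stat)
    }
    list(delta = dd$delta, ci_low = dd$ci_low, ci_high = dd$ci_high,
         n_ref = length(ref_rows), n_test = length(test_rows))
  }

  per_subject <- list()
  for (frame in spec$frames) {
    rows <- lapply(subjects, function(s) {
      p <- one_contrast(s, spec$pos, frame)
      n <- one_contrast(s, spec$neg, frame)
      data.frame(subject = s,
                 delta_pos = p$delta, ci_low_pos = p$ci_low, ci_high_pos = p$ci_high,
                 delta_neg = n$delta, ci_low_neg = n$ci_low, ci_high_neg = n$ci_high,
                 n_ref = p$n_ref, n_pos = p$n_test, n_neg = n$n_test)
    })
    per_subject[[frame]] <- do.call(rbind, rows)
  }
  primary_frame <- spec$frames[1]
  ps <- per_subject[[primary_frame]]

  # scale T for the reference frame index
  tilt_T <- if (is.numeric(tilt_scale)) {
    if (tilt_scale <= 0) stop("numeric tilt_scale must be > 0")
    tilt_scale
  } else {
    tilt_scale <- match.arg(tilt_scale)
    if (spec$group_col == "image_tilt_deg") {
      mean(abs(c(spec$pos, spec$neg)))
    } else if (tilt_scale == "measured") {
      tilted <- d[[spec$group_col]] != spec$ref
      mean(abs(d$head_tilt_measured_deg[!duplicated(
        paste(d$subject, d[[spec$group_col]])) &
          d[[spec$group_col]] != spec$ref]))
    } else {
      mean(abs(c(spec$pos, spec$neg)))
    }
  }

  ok <- complete.cases(ps[, c("delta_pos", "delta_neg")])
  rf_subj <- rf_index(ps$delta_pos[ok], ps$delta_neg[ok], tilt_T)
  group <- list(
    pos = group_summary(ps$delta_pos[ok], seed = split_seed(seed, "grp", "pos")),
    neg = group_summary(ps$delta_neg[ok], seed = split_seed(seed, "grp", "neg")))
  rf_group <- group_summary(rf_subj$signed, seed = split_seed(seed, "grp", "rf"))

  ocr <- NULL
  if (!is.null(torsion)) {
    if (analysis != "fractal_head_tilt")
      warning("counter-roll scaling is defined for the fractal_head_tilt analysis")
    merged <- merge(ps[, c("subject", "delta_pos", "delta_neg")],
                    torsion$per_subject, by = "subject")
    osc <- ocr_scaled_rf_index(merged$delta_pos, merged$delta_neg,
                               merged$d_ocr_pos, merged$d_ocr_neg)
    def <- is.finite(osc$signed)
    ocr <- list(per_subject = cbind(merged, rf_ocr_signed = osc$signed),
                excluded = merged$subject[!def],
                group = if (sum(def) >= 2)
                  group_summary(osc$signed[def],
                                seed = split_seed(seed, "grp", "ocr"))
                else NULL,
                table = ocr_displacement_table(ps, torsion))
    if (!is.null(ocr$group)) {
      ocr$value <- abs(ocr$group$mean)
      ocr$signed <- ocr$group$mean
    }
  }

  structure(list(
    analysis = analysis, frames = spec$frames, primary_frame = primary_frame,
    per_subject = ps, per_subject_by_frame = per_subject,
    group = group,
    group_by_frame = lapply(per_subject, function(tab) {
      okf <- complete.cases(tab[, c("delta_pos", "delta_neg")])
      list(pos = group_summary(tab$delta_pos[okf],
                               seed = split_seed(seed, "grpf", "pos")),
           neg = group_summary(tab$delta_neg[okf],
                               seed = split_seed(seed, "grpf", "neg")))
    }),
    rf = rf_subj, rf_group = rf_group,
    rf_value = abs(rf_group$mean), rf_signed = rf_group$mean,
    T = tilt_T, contrast = list(pos = spec$pos, neg = spec$neg, ref = spec$ref,
                                by = spec$group_col),
    ocr = ocr, kde = kde, stat = stat, max_lag = max_lag,
    n_boot = n_boot, seed = seed, n_subjects = length(subjects),
    data = d, call = match.call()),
    class = "rf_fit")
}

#' @describeIn rf_fit compact display of the fitted displacements and index.
#' @param x,object an `rf_fit` object.
#' @param ... unused.
#' @export
print.rf_fit <- function(x, ...) {
  cat("Reference-frame fit:", x$analysis, "\n")
  cat(sprintf("  %d subjects, %s frame, T = %.2f deg\n",
              x$n_subjects, x$primary_frame, x$T))
  for (side in c("pos", "neg")) {
    g <- x$group[[side]]
    cat(sprintf("  delta_%s: %+6.2f deg  (95%% CI [%.2f, %.2f], n = %d)\n",
                side, g$mean, g$ci_low, g$ci_high, g$n))
  }
  cat(sprintf("  RFindex: %.2f (signed %+0.2f)\n", x$rf_value, x$rf_signed))
  if (!is.null(x$ocr) && !is.null(x$ocr$group))
    cat(sprintf("  OCR-scaled RFindex: %.2f (%d subjects excluded)\n",
                x$ocr$value, length(x$ocr$excluded)))
  invisible(x)
}

#' @describeIn rf_fit per-subject and per-frame detail.
#' @export
summary.rf_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.rf_fit")
}

#' @export
print.summary.rf_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  cat("\nPer-subject displacements (", f$primary_frame, " frame):\n", sep = "")
  print(f$per_subject[, c("subject", "delta_pos", "delta_neg",
                          "n_ref", "n_pos", "n_neg")],
        row.names = FALSE, digits = 4)
  if (length(f$frames) > 1) {
    for (fr in setdiff(f$frames, f$primary_frame)) {
      g <- f$group_by_frame[[fr]]
      cat(sprintf("\n%s frame group displacements: %+0.2f / %+0.2f deg\n",
                  fr, g$pos$mean, g$neg$mean))
    }
  }
  invisible(x)
}

#' @describeIn rf_fit group-level estimates as a named vector:
#'   `delta_pos`, `delta_neg` (degrees) and `rf_index`.
#' @export
coef.rf_fit <- function(object, ...) {
  c(delta_pos = object$group$pos$mean, delta_neg = object$group$neg$mean,
    rf_index = object$rf_value)
}

#' @describeIn rf_fit bootstrap percentile confidence intervals for the
#'   group displacements and the (signed) reference frame index.
#' @param parm,level included for generic compatibility; the level is the
#'   2.5/97.5 percentile interval.
#' @export
confint.rf_fit <- function(object, parm, level = 0.95, ...) {
  out <- rbind(
    delta_pos = c(object$group$pos$ci_low, object$group$pos$ci_high),
    delta_neg = c(object$group$neg$ci_low, object$group$neg$ci_high),
    rf_signed = c(object$rf_group$ci_low, object$rf_group$ci_high))
  colnames(out) <- c("2.5 %", "97.5 %")
  if (!missing(parm)) out <- out[parm, , drop = FALSE]
  out
}

#' @describeIn rf_fit polar plot of the pooled direction densities for the
#'   upright reference against each tilted condition.
#' @export
plot.rf_fit <- function(x, ...) {
  d <- x$data
  frame <- x$primary_frame
  ang <- if (frame == "world") {
    head_to_world(d$direction_deg, d$head_tilt_measured_deg)
  } else d$direction_deg
  by <- d[[x$contrast$by]]
  dens <- lapply(c(x$contrast$ref, x$contrast$pos, x$contrast$neg),
                 function(lv) circular_kde(ang[by == lv], x$kde))
  rmax <- max(vapply(dens, function(z) max(z$density), 0))
  old <- par(mfrow = c(1, 2), mar = c(1, 1, 2, 1))
  on.exit(par(old))
  draw <- function(i, lab, col) {
    plot(NA, xlim = c(-1.1, 1.1), ylim = c(-1.1, 1.1), asp = 1, axes = FALSE,
         xlab = "", ylab = "", main = lab)
    th <- seq(0, 2 * pi, length.out = 181)
    lines(cos(th), sin(th), col = "grey80")
    segments(-1, 0, 1, 0, col = "grey90"); segments(0, -1, 0, 1, col = "grey90")
    for (j in seq_along(i)) {
      z <- dens[[i[j]]]
      r <- z$density / rmax
      lines(r * cos(z$grid * pi / 180), r * sin(z$grid * pi / 180),
            col = col[j], lwd = 1.5)
    }
  }
  draw(c(1, 2), sprintf("ref vs %s%+g", substr(x$contrast$by, 1, 4), x$contrast$pos),
       c("black", "red"))
  draw(c(1, 3), sprintf("ref vs %s%+g", substr(x$contrast$by, 1, 4), x$contrast$neg),
       c("black", "blue"))
  invisible(x)
}
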