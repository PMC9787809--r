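#' Reference frame index
#'
#' Combines the displacements measured for symmetric tilts into a single
#' scaled index: the left-tilt displacement is sign-reversed, the two are
#' averaged, and the mean is scaled by the tilt magnitude,
#' `(delta_pos - delta_neg) / (2 T)`. An index of 0 means the saccade
#' bias is anchored to the coordinate frame of measurement; 1 means it is
#' anchored to the alternative frame (it rotated fully with the tilt).
#' Because the literal formula can come out negative when the bias is
#' offset opposite to the tilt (as counter-roll predicts in head
#' coordinates), the magnitude is reported as `value` and the signed
#' number is retained as `signed`.
#'
#' @param delta_pos displacement for the +tilt condition versus upright,
#'   degrees (clockwise-positive).
#' @param delta_neg displacement for the -tilt condition versus upright,
#'   degrees.
#' @param tilt absolute average tilt T, degrees (> 0).
#' @return an object of class `rf_index`: list with `value` (magnitude),
#'   `signed`, and the inputs. Vectorised over subjects.
#' @examples
#' rf_index(12.01, -8.32, (27.14 + 26.68) / 2)$value  # 0.38 to 2 d.p.
#' @export
rf_index <- function(delta_pos, delta_neg, tilt) {
  if (any(!is.finite(tilt)) || any(tilt <= 0)) stop("tilt T must be > 0")
  signed <- (delta_pos - delta_neg) / (2 * tilt)
  structure(list(value = abs(signed), signed = signed,
                 delta_pos = delta_pos, delta_neg = delta_neg, tilt = tilt),
            class = "rf_index")
}

#' @export
print.rf_index <- function(x, ...) {
  if (length(x$value) == 1) {
    cat(sprintf("Reference frame index: %.2f (signed %.2f; T = %.2f deg)\n",
                x$value, x$signed, x$tilt))
  } else {
    cat(sprintf("Reference frame index for %d subjects: mean |.| = %.2f\n",
                length(x$value), mean(x$value)))
  }
  invisible(x)
}

#' Counter-roll-scaled reference frame index
#'
#' Scales the displacement for each tilt by the measured change in median
#' ocular counter-roll (OCR) instead of by the tilt magnitude, testing a
#' retinal anchoring account: 1 means the bias rotated exactly as far as
#' the eye counter-rolled, 0 means it stayed with the head. The per-tilt
#' ratios `delta / delta_ocr` are averaged and the magnitude reported.
#' Subjects with a zero or missing OCR change have no defined ratio and
#' return `NA` (flagged, excluded from group averages).
#'
#' @param delta_pos,delta_neg displacements versus upright for the + and -
#'   tilt, degrees.
#' @param d_ocr_pos,d_ocr_neg change in median OCR (upright minus tilted)
#'   for the + and - tilt, degrees.
#' @return list of class `rf_index` with `value` (magnitude), `signed`,
#'   and `excluded` (logical: undefined ratio). Vectorised over subjects.
#' @export
ocr_scaled_rf_index <- function(delta_pos, delta_neg, d_ocr_pos, d_ocr_neg) {
  bad <- !is.finite(d_ocr_pos) | !is.finite(d_ocr_neg) |
    d_ocr_pos == 0 | d_ocr_neg == 0
  r_pos <- ifelse(bad, NA_real_, delta_pos / d_ocr_pos)
  r_neg <- ifelse(bad, NA_real_, delta_neg / d_ocr_neg)
  signed <- (r_pos + r_neg) / 2
  structure(list(value = abs(signed), signed = signed, excluded = bad,
                 delta_pos = delta_pos, delta_neg = delta_neg,
                 d_ocr_pos = d_ocr_pos, d_ocr_neg = d_ocr_neg),
            class = "rf_index")
}

#' Group summary of per-subject displacements
#'
#' Mean across subjects with a bootstrap percentile 95% confidence
#' interval (resampling subjects with replacement), plus a one-sample t
#' statistic against zero as a routine convenience.
#'
#' @param deltas numeric vector of per-subject displacements (>= 2).
#' @param n_boot bootstrap replicates (default 2000).
#' @param seed seed for the resampling stream.
#' @return list with `mean`, `ci_low`, `ci_high`, `n`, `t`, `df`, `p`.
#' @export
group_summary <- function(deltas, n_boot = 2000, seed = 1) {
  deltas <- deltas[is.finite(deltas)]
  n <- length(deltas)
  if (n < 2) stop("need >= 2 subjects")
  reps <- with_seed(seed, vapply(seq_len(n_boot), function(b)
    mean(deltas[sample.int(n, replace = TRUE)]), 0))
  ci <- unname(quantile(reps, c(0.025, 0.975)))
  tt <- if (sd(deltas) > 0) t.test(deltas) else NULL
  list(mean = mean(deltas), ci_low = ci[1], ci_high = ci[2], n = n,
       t = if (is.null(tt)) NA_real_ else unname(tt$statistic),
       df = n - 1,
       p = if (is.null(tt)) NA_real_ else tt$p.value)
}

#' Select the Earth-upright scene conditions
#'
#' Picks out the three design cells in which a natural scene is upright in
#' the world: image tilt cancelling the head tilt (`image + head == 0`),
#' scenes only. Returns the two condition pairs contrasting each tilted
#' cell against the doubly-upright cell, and reports design cells missing
#' per subject.
#'
#' @param trials data frame carrying `subject`, `head_tilt_nominal_deg`,
#'   `image_tilt_deg`, `image_type` (one row per trial or per sample/event).
#' @return an object of class `condition_selection`: list with `cells`
#'   (selected head/image tilt combinations), `pairs` (the two tilt
#'   contrasts against upright), and `missing` (data frame of absent
#'   cells by subject). Warns when no scene trials exist.
#' @export
select_earth_upright <- function(trials) {
  need <- c("subject", "head_tilt_nominal_deg", "image_tilt_deg", "image_type")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  sel <- trials$image_type == "scene" &
    abs(trials$head_tilt_nominal_deg + trials$image_tilt_deg) < 1e-9
  cells <- unique(trials[sel, c("head_tilt_nominal_deg", "image_tilt_deg")])
  cells <- cells[order(cells$head_tilt_nominal_deg), , drop = FALSE]
  rownames(cells) <- NULL
  if (nrow(cells) == 0)
    warning("no Earth-upright scene trials found")
  tilts <- cells$head_tilt_nominal_deg
  pairs <- list()
  if (0 %in% tilts) {
    for (ht in sort(tilts[tilts != 0])) {
      pairs[[length(pairs) + 1L]] <- list(
        test = c(head = ht, image = -ht), ref = c(head = 0, image = 0))
    }
  }
  missing <- do.call(rbind, lapply(unique(trials$subject), function(s) {
    have <- unique(trials[sel & trials$subject == s,
                          c("head_tilt_nominal_deg", "image_tilt_deg")])
    absent <- cells[!paste(cells[[1]], cells[[2]]) %in%
                      paste(have[[1]], have[[2]]), , drop = FALSE]
    if (nrow(absent) == 0) return(NULL)
    cbind(subject = s, absent)
  }))
  structure(list(cells = cells, pairs = pairs,
                 missing = missing, rows = which(sel)),
            class = "condition_selection")
}

#' @export
print.condition_selection <- function(x, ...) {
  cat("Earth-upright condition selection:", nrow(x$cells), "cells,",
      length(x$pairs), "tilt contrasts\n")
  if (!is.null(x$missing) && nrow(x$missing) > 0)
    cat("  missing cells for", length(unique(x$missing$subject)), "subject(s)\n")
  invisible(x)
}
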