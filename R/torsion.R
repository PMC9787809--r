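#' Median ocular counter-roll of one trial
#'
#' The median of the trial's finite torsion samples, robust to the spikes
#' and dropouts typical of video-based torsion tracking. Trials with no
#' usable torsion (absent channel, all-`NA`, or fewer than
#' `min_finite_frac` finite samples) are flagged unavailable rather than
#' summarised as zero.
#'
#' @param trial data frame with a `torsion_deg` column (one trial).
#' @param min_finite_frac minimum fraction of finite samples required
#'   (default 0.25).
#' @return median torsion in degrees, or `NA` with attribute
#'   `available = FALSE` when the channel is unusable.
#' @export
median_ocr <- function(trial, min_finite_frac = 0.25) {
  v <- trial$torsion_deg
  if (is.null(v)) return(structure(NA_real_, available = FALSE))
  fin <- v[is.finite(v)]
  if (length(fin) == 0 || length(fin) < min_finite_frac * length(v))
    return(structure(NA_real_, available = FALSE))
  structure(median(fin), available = TRUE)
}

#' Change in counter-roll between head tilts
#'
#' `ocr_upright - ocr_tilted`, the OCR difference convention used for the
#' retinal-frame comparison.
#'
#' @param ocr_upright,ocr_tilted median OCR in the upright and tilted
#'   conditions, degrees.
#' @return difference in degrees; vectorised.
#' @export
delta_ocr <- function(ocr_upright, ocr_tilted) {
  if (any(!is.finite(ocr_upright)) || any(!is.finite(ocr_tilted)))
    stop("OCR values must be finite")
  ocr_upright - ocr_tilted
}

#' Summarise the torsion channel of a gaze table
#'
#' Computes the per-trial median OCR, averages it per subject x head tilt
#' x image type, and derives the per-subject OCR changes between upright
#' and each tilted condition (upright minus tilted), pooling image types
#' for the change scores. Subjects without a usable torsion channel are
#' flagged.
#'
#' @param gaze data frame in the gaze CSV dialect with a `torsion_deg`
#'   column.
#' @param min_finite_frac per-trial usability threshold, see
#'   [median_ocr()].
#' @return an object of class `torsion_summary`: list with `per_trial`
#'   (subject, trial, condition, median OCR), `per_condition` (mean OCR
#'   by subject x head tilt x image type), `per_subject` (columns
#'   `subject`, `d_ocr_pos`, `d_ocr_neg`: upright minus +tilt / -tilt),
#'   and `unavailable` (subjects lacking torsion).
#' @export
torsion_summary <- function(gaze, min_finite_frac = 0.25) {
  need <- c("subject", "trial", "head_tilt_nominal_deg", "image_type")
  miss <- setdiff(need, names(gaze))
  if (length(miss) > 0) stop("missing columns: ", paste(miss, collapse = ", "))
  if (is.null(gaze$torsion_deg)) stop("gaze table has no torsion_deg column")
  key <- paste(gaze$subject, gaze$trial, sep = "\r")
  idx <- split(seq_len(nrow(gaze)), key)
  per_trial <- do.call(rbind, lapply(idx, function(rows) {
    tr <- gaze[rows, , drop = FALSE]
    med <- median_ocr(tr, min_finite_frac)
    data.frame(subject = tr$subject[1], trial = tr$trial[1],
               head_tilt_nominal_deg = tr$head_tilt_nominal_deg[1],
               image_type = tr$image_type[1],
               median_ocr_deg = as.numeric(med),
               available = attr(med, "available"))
  }))
  rownames(per_trial) <- NULL
  ok <- per_trial[per_trial$available, , drop = FALSE]
  per_condition <- if (nrow(ok) > 0) {
    agg <- aggregate(median_ocr_deg ~ subject + head_tilt_nominal_deg + image_type,
                     data = ok, FUN = mean)
    names(agg)[names(agg) == "median_ocr_deg"] <- "mean_ocr_deg"
    agg[order(agg$subject, agg$head_tilt_nominal_deg), , drop = FALSE]
  } else {
    data.frame(subject = integer(0), head_tilt_nominal_deg = numeric(0),
               image_type = character(0), mean_ocr_deg = numeric(0))
  }
  subjects <- sort(unique(per_trial$subject))
  per_subject <- do.call(rbind, lapply(subjects, function(s) {
    d <- ok[ok$subject == s, , drop = FALSE]
    mean_at <- function(ht) {
      v <- d$median_ocr_deg[d$head_tilt_nominal_deg == ht]
      if (length(v) == 0) NA_real_ else mean(v)
    }
    up <- mean_at(0)
    tilts <- sort(unique(per_trial$head_tilt_nominal_deg))
    pos <- max(tilts); neg <- min(tilts)
    data.frame(subject = s,
               d_ocr_pos = if (is.finite(up)) up - mean_at(pos) else NA_real_,
               d_ocr_neg = if (is.finite(up)) up - mean_at(neg) else NA_real_)
  }))
  unavailable <- subjects[vapply(subjects, function(s)
    !any(per_trial$available[per_trial$subject == s]), TRUE)]
  structure(list(per_trial = per_trial, per_condition = per_condition,
                 per_subject = per_subject, unavailable = unavailable),
            class = "torsion_summary")
}

#' @export
print.torsion_summary <- function(x, ...) {
  n <- length(unique(x$per_trial$subject))
  cat(sprintf("Torsion summary: %d subjects (%d without usable torsion)\n",
              n, length(x$unavailable)))
  ps <- x$per_subject[complete.cases(x$per_subject), , drop = FALSE]
  if (nrow(ps) > 0)
    cat(sprintf("  mean delta-OCR: +tilt %.2f deg, -tilt %.2f deg\n",
                mean(ps$d_ocr_pos), mean(ps$d_ocr_neg)))
  invisible(x)
}

#' Pair per-subject displacements with counter-roll changes
#'
#' Aligns each subject's direction-distribution displacement with the
#' change in median OCR for the same tilt, sign-reversing the left-tilt
#' values so both tilts accumulate on a common axis, and reports the
#' Spearman rank correlation of the pairs as a descriptive.
#'
#' @param per_subject data frame with `subject`, `delta_pos`, `delta_neg`
#'   (e.g. the `per_subject` table of an [rf_fit()]).
#' @param torsion a [torsion_summary()].
#' @return list with `pairs` (subject, tilt, displacement, delta OCR; the
#'   left-tilt rows sign-reversed), `rho`, and `n_excluded` (subjects
#'   without torsion).
#' @export
ocr_displacement_table <- function(per_subject, torsion) {
  ts <- torsion$per_subject
  merged <- merge(per_subject[, c("subject", "delta_pos", "delta_neg")], ts,
                  by = "subject")
  ok <- merged[complete.cases(merged), , drop = FALSE]
  if (nrow(ok) == 0) stop("no subjects with both displacement and torsion")
  pairs <- rbind(
    data.frame(subject = ok$subject, tilt = "pos",
               displacement_deg = ok$delta_pos, d_ocr_deg = ok$d_ocr_pos),
    data.frame(subject = ok$subject, tilt = "neg",
               displacement_deg = -ok$delta_neg, d_ocr_deg = -ok$d_ocr_neg))
  rho <- if (nrow(pairs) >= 3 && sd(pairs$displacement_deg) > 0 &&
             sd(pairs$d_ocr_deg) > 0) {
    cor(pairs$displacement_deg, pairs$d_ocr_deg, method = "spearman")
  } else NA_real_
  list(pairs = pairs, rho = rho,
       n_excluded = nrow(merged) - nrow(ok))
}
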