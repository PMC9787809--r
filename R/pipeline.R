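# FNV-style content hash for run provenance (no external digest dependency).
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h <- 2166136261
  for (b in utf8ToInt(as.character(s))) {
    h <- ((h + b) * 65599) %% 4294967296  # exact in doubles (< 2^53)
  }
  sprintf("%04x%04x", h %/% 65536, h %% 65536)
}

pipeline_log <- function(verbose, ...) {
  if (verbose) message("[gazeframe] ", sprintf(...))
}

#' Run the full simulate/detect/analyze pipeline
#'
#' Orchestrates the whole analysis as one seeded, logged, file-based run:
#' simulate a synthetic study (or load a gaze CSV), validate it, detect
#' saccades, run the requested condition analyses, summarise torsion, and
#' write the saccade table, per-subject and group displacement tables,
#' and a versioned machine-readable JSON report. Identical configuration
#' (including seed) gives byte-identical outputs.
#'
#' @param config a named list (or a JSON/YAML file path) with elements:
#'   \describe{
#'     \item{`gaze_csv`}{optional path to an input gaze CSV; when absent,
#'       `synthetic` is used.}
#'     \item{`synthetic`}{optional list of [gaze_config()] arguments for
#'       the simulator.}
#'     \item{`analyses`}{character vector from `"fractal_head_tilt"`,
#'       `"scene_earth_upright"`, `"scene_tilt_upright"`; must be
#'       non-empty.}
#'     \item{`detection`}{optional list of [detection_params()] arguments.}
#'     \item{`kde`}{optional list of [kde_params()] arguments.}
#'     \item{`n_boot`}{per-subject bootstrap replicates (default 0).}
#'     \item{`seed`}{integer master seed (default 1).}
#'     \item{`out_dir`}{output directory (created if needed).}
#'   }
#' @param verbose log progress to stderr (default `TRUE`).
#' @return the report, invisibly: a list mirroring the written
#'   `report.json` (schema, config hash, seed, per-analysis group
#'   displacements and reference frame indices, torsion summary).
#' @export
run_pipeline <- function(config, verbose = TRUE) {
  if (is.character(config)) {
    path <- config
    if (!file.exists(path)) stop("config file not found: ", path)
    config <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
      yaml::read_yaml(path)
    } else {
      jsonlite::read_json(path, simplifyVector = TRUE)
    }
  }
  analyses <- config$analyses
  valid <- c("fractal_head_tilt", "scene_earth_upright", "scene_tilt_upright")
  if (length(analyses) == 0)
    stop("config error: 'analyses' must name at least one analysis")
  if (!all(analyses %in% valid))
    stop("config error: unknown analysis: ",
         paste(setdiff(analyses, valid), collapse = ", "))
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_boot <- if (is.null(config$n_boot)) 0L else as.integer(config$n_boot)
  out_dir <- if (is.null(config$out_dir)) "." else config$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  if (!is.null(config$gaze_csv)) {
    pipeline_log(verbose, "reading gaze samples from %s", config$gaze_csv)
    gaze <- read_gaze_csv(config$gaze_csv)
  } else {
    syn_args <- if (is.null(config$synthetic)) list() else config$synthetic
    if (is.null(syn_args$seed)) syn_args$seed <- seed
    cfg <- do.call(gaze_config, syn_args)
    pipeline_log(verbose, "simulating study (%d subjects, anchor=%s, seed=%d)",
                 cfg$n_subjects, cfg$anchor, cfg$seed)
    gaze <- generate_study(cfg)
  }

  val <- validate_input(gaze)
  if (!val$ok) {
    print(val)
    stop("input validation failed")
  }
  torsion_ok <- "torsion_deg" %in% names(gaze) && any(is.finite(gaze$torsion_deg))

  det_args <- if (is.null(config$detection)) list() else config$detection
  params <- do.call(detection_params, det_args)
  pipeline_log(verbose, "detecting saccades (lambda = %g)", params$lambda_sd)
  sacc <- detect_study(gaze, params)
  write_saccades_csv(sacc, file.path(out_dir, "saccades.csv"))
  pipeline_log(verbose, "%d saccades detected", nrow(sacc))

  kde_args <- if (is.null(config$kde)) list() else config$kde
  kde <- do.call(kde_params, kde_args)

  tors <- if (torsion_ok) torsion_summary(gaze) else NULL

  report <- list(
    schema = "gazeframe-report/1",
    # hash covers the scientific configuration, not the output location
    config_hash = config_hash(config[setdiff(names(config), "out_dir")]),
    seed = seed,
    package_version = as.character(utils::packageVersion("gazeframe")),
    n_saccades = nrow(sacc),
    analyses = list())

  for (an in analyses) {
    pipeline_log(verbose, "analysis: %s", an)
    fit <- rf_fit(sacc, an, kde = kde, n_boot = n_boot, seed = seed,
                  torsion = if (an == "fractal_head_tilt") tors else NULL)
    write.csv(fit$per_subject,
              file.path(out_dir, paste0(an, "_per_subject.csv")),
              row.names = FALSE)
    grp <- data.frame(
      contrast = c("pos", "neg"),
      delta_deg = c(fit$group$pos$mean, fit$group$neg$mean),
      ci_low = c(fit$group$pos$ci_low, fit$group$neg$ci_low),
      ci_high = c(fit$group$pos$ci_high, fit$group$neg$ci_high))
    write.csv(grp, file.path(out_dir, paste0(an, "_group.csv")),
              row.names = FALSE)
    report$analyses[[an]] <- list(
      frame = fit$primary_frame,
      n_subjects = fit$n_subjects,
      delta_pos = fit$group$pos$mean, delta_pos_ci = c(fit$group$pos$ci_low,
                                                       fit$group$pos$ci_high),
      delta_neg = fit$group$neg$mean, delta_neg_ci = c(fit$group$neg$ci_low,
                                                       fit$group$neg$ci_high),
      rf_index = fit$rf_value, rf_signed = fit$rf_signed, T = fit$T)
    if (!is.null(fit$ocr) && !is.null(fit$ocr$group)) {
      report$analyses[[an]]$rf_index_ocr <- fit$ocr$value
      report$analyses[[an]]$ocr_excluded_subjects <- length(fit$ocr$excluded)
    }
  }

  if (torsion_ok) {
    ps <- tors$per_subject[complete.cases(tors$per_subject), , drop = FALSE]
    report$torsion <- list(
      n_subjects_with_torsion =
        length(unique(tors$per_trial$subject)) - length(tors$unavailable),
      mean_d_ocr_pos = if (nrow(ps)) mean(ps$d_ocr_pos) else NA,
      mean_d_ocr_neg = if (nrow(ps)) mean(ps$d_ocr_neg) else NA)
    write.csv(tors$per_condition, file.path(out_dir, "ocr_per_condition.csv"),
              row.names = FALSE)
  }

  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  pipeline_log(verbose, "report written to %s", file.path(out_dir, "report.json"))
  invisible(report)
}
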