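#' ROI-mean decay curve from a 4D multi-echo volume
#'
#' Averages the in-mask voxels of each echo volume, giving one decay curve
#' per ROI. Echo volumes are stacked along the 4th dimension in acquisition
#' order (the row order of the schedule).
#'
#' @param volume_4d 4D numeric array (x, y, z, echo); e.g. as read by
#'   `RNifti::readNifti()`.
#' @param mask 3D array (logical or 0/1) matching the spatial dimensions.
#' @param schedule an [acq_schedule()] whose rows match the 4th dimension.
#' @param roi label stored on the curve.
#' @return a `decay_curve` data frame (te_ms, run, signal).
#' @export
roi_mean_curve <- function(volume_4d, mask, schedule, roi = "roi") {
  dv <- dim(volume_4d)
  if (length(dv) != 4) stop("volume must be a 4D array (x, y, z, echo)")
  schedule <- validate_schedule(as.data.frame(schedule))
  if (dv[4] != nrow(schedule)) {
    stop("4th dimension (", dv[4], ") does not match the schedule (",
         nrow(schedule), " echoes)")
  }
  mask <- array(as.logical(mask), dim = dim(mask))
  if (!identical(dim(mask), dv[1:3])) stop("mask shape does not match volume")
  if (!any(mask)) stop("empty mask")
  idx <- which(mask)
  flat <- matrix(volume_4d, nrow = prod(dv[1:3]), ncol = dv[4])
  sig <- colMeans(flat[idx, , drop = FALSE])
  curve <- data.frame(te_ms = schedule$te_ms, run = schedule$run, signal = sig)
  attr(curve, "source_id") <- roi
  class(curve) <- c("decay_curve", "data.frame")
  curve
}

#' Pipeline configuration
#'
#' Bundles everything one end-to-end run needs. In simulate mode the cohort
#' is generated by [simulate_cohort()]; in ingest mode `curves_csv` and
#' `phantom_csv` point at externally produced curve tables in the same CSV
#' dialect.
#'
#' @param seed integer seed, mandatory for any stochastic step.
#' @param mode `"simulate"` or `"ingest"`.
#' @param cohort a [cohort_config()] (simulate mode). Its seed is overridden
#'   by `seed`.
#' @param curves_csv,phantom_csv input CSV paths (ingest mode).
#' @param fit a [fit_options()] list.
#' @param calibration `"auto"`, `"per_subject"` or `"pooled"`.
#' @param ecf_reference extracellular reference concentration (mM).
#' @param family_alpha familywise alpha across the six metrics.
#' @param tissue_rois whole-tissue labels for the 2-level ANOVA.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed, mode = c("simulate", "ingest"),
                            cohort = cohort_config(seed = seed),
                            curves_csv = NULL, phantom_csv = NULL,
                            fit = fit_options(),
                            calibration = "auto",
                            ecf_reference = 140,
                            family_alpha = 0.05,
                            tissue_rois = c("GM", "WM")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(seed), length(seed) == 1)
  if (mode == "ingest") {
    if (is.null(curves_csv) || is.null(phantom_csv)) {
      stop("ingest mode needs curves_csv and phantom_csv")
    }
    if (!file.exists(curves_csv)) stop("curves_csv not found: ", curves_csv)
    if (!file.exists(phantom_csv)) stop("phantom_csv not found: ", phantom_csv)
  }
  cohort$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), mode = mode, cohort = cohort,
                 curves_csv = curves_csv, phantom_csv = phantom_csv,
                 fit = fit, calibration = calibration,
                 ecf_reference = ecf_reference, family_alpha = family_alpha,
                 tissue_rois = tissue_rois),
            class = "pipeline_config")
}

# polynomial rolling hash over the serialized config; stamps every output table
config_hash <- function(config) {
  s <- jsonlite::serializeJSON(unclass_deep(config))
  bytes <- utf8ToInt(s)
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

unclass_deep <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_deep)
  } else x
}

write_stamped_csv <- function(df, path, hash, seed) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# naquant config_hash=%s seed=%d", hash, seed), con)
  write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read or write a pipeline configuration file
#'
#' YAML or JSON (by file extension). Function-valued pieces (the tissue table,
#' schedule, fit options) round-trip as plain lists/data frames.
#'
#' @param config a [pipeline_config()].
#' @param path file path ending in .yaml/.yml or .json.
#' @return `read_pipeline_config()` returns a `pipeline_config`.
#' @export
write_pipeline_config <- function(config, path) {
  x <- unclass_deep(config)
  x$cohort$schedule <- as.data.frame(x$cohort$schedule)
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  x <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (is.null(x$seed)) stop("config must carry an explicit integer seed")
  coh <- x$cohort
  cohort <- cohort_config(
    n_subjects = coh$n_subjects, n_female = coh$n_female,
    age_range = unlist(coh$age_range),
    regions = unlist(coh$regions),
    tissue = as.data.frame(coh$tissue),
    phantom = do.call(phantom_spec, coh$phantom[c(
      "tube_concentrations", "tube_t2star", "signal_per_mM", "intercept")]),
    schedule = acq_schedule(unlist(as.data.frame(coh$schedule)$te_ms),
                            unlist(as.data.frame(coh$schedule)$run)),
    sigma = coh$sigma %||% 0, snr = coh$snr,
    spread_scale = coh$spread_scale %||% 1, seed = x$seed)
  fit <- do.call(fit_options, lapply(x$fit, function(v)
    if (is.list(v)) unlist(v) else v))
  pipeline_config(seed = x$seed, mode = x$mode %||% "simulate",
                  cohort = cohort,
                  curves_csv = x$curves_csv, phantom_csv = x$phantom_csv,
                  fit = fit, calibration = x$calibration %||% "auto",
                  ecf_reference = x$ecf_reference %||% 140,
                  family_alpha = x$family_alpha %||% 0.05,
                  tissue_rois = unlist(x$tissue_rois %||% c("GM", "WM")))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the end-to-end quantification pipeline
#'
#' simulate (or ingest) -> fit tubes -> calibrate -> fit ROIs -> quantify ->
#' group statistics. All intermediate tables are written to `out_dir` as CSV
#' stamped with the config hash and seed; a JSON report collects versions,
#' the config, and summary statistics. Idempotent under a fixed seed.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing); `NULL` skips writing.
#' @param quiet suppress stage logging.
#' @return (invisibly) list with `dataset` (simulate mode), `quantification`,
#'   `summary`, `tube_fits`, `calibrations`, `stats`, `report`.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  hash <- config_hash(config)
  say <- function(...) if (!quiet) message("[naquant] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)
    })
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  emit <- function(df, name) {
    if (!is.null(out_dir)) {
      write_stamped_csv(df, file.path(out_dir, name), hash, config$seed)
    }
  }

  dataset <- NULL
  if (config$mode == "simulate") {
    say("simulate: ", config$cohort$n_subjects, " subjects x ",
        length(config$cohort$regions), " regions, seed ", config$seed)
    dataset <- stage("simulate", simulate_cohort(config$cohort))
    curves <- dataset$curves
    phantom <- dataset$phantom_curves
    subjects <- dataset$subjects
  } else {
    say("ingest: ", config$curves_csv)
    curves <- stage("ingest", read_curves(config$curves_csv))
    phantom <- stage("ingest", read_curves(config$phantom_csv))
    subjects <- unique(curves[, intersect(c("subject_id", "sex", "age"),
                                          names(curves)), drop = FALSE])
    if (!"sex" %in% names(subjects)) subjects$sex <- NA_character_
    if (!"age" %in% names(subjects)) subjects$age <- NA_real_
  }
  emit(curves, "curves.csv")
  emit(phantom, "phantom_curves.csv")

  say("fit + calibrate + quantify: ",
      nrow(unique(curves[, c("subject_id", "roi")])), " curves")
  qc <- stage("quantify", quantify_cohort(
    curves, phantom, options = config$fit, calibration = config$calibration,
    ecf_reference = config$ecf_reference))
  n_flag <- sum(qc$quantification$degenerate | qc$quantification$negative_flag)
  if (n_flag > 0) say("warning: ", n_flag, " fits flagged degenerate/negative")
  emit(qc$tube_fits, "tube_fits.csv")
  cal_tab <- do.call(rbind, lapply(names(qc$calibrations), function(nm) {
    cal <- qc$calibrations[[nm]]
    data.frame(calibration = nm, slope = cal$slope, intercept = cal$intercept,
               r_squared = cal$fit_r_squared, n_tubes = cal$n_tubes)
  }))
  emit(cal_tab, "calibration.csv")
  emit(qc$quantification, "quantification.csv")
  summ <- summarize_quantification(qc$quantification)
  emit(summ, "summary.csv")

  say("group statistics")
  stats_res <- stage("stats", run_group_stats(
    qc$quantification, subjects, tissue_rois = config$tissue_rois,
    family_alpha = config$family_alpha))
  anova_tab <- do.call(rbind, lapply(
    c(stats_res$anova_tissue, stats_res$anova_region), function(a) {
      data.frame(metric = a$metric, term = c("whole_model", a$terms$term),
                 df = c(a$whole_model$df1, a$terms$df),
                 f = c(a$whole_model$f, a$terms$f),
                 p = c(a$whole_model$p, a$terms$p))
    }))
  if (!is.null(anova_tab)) {
    anova_tab$design <- rep(c("tissue", "region"),
                            c(sum(vapply(stats_res$anova_tissue, function(a)
                              nrow(a$terms) + 1L, 1L)),
                              sum(vapply(stats_res$anova_region, function(a)
                                nrow(a$terms) + 1L, 1L))))
    emit(anova_tab, "anova.csv")
  }
  posthoc_tab <- rbind(
    if (!is.null(stats_res$posthoc_tissue))
      cbind(design = "tissue", stats_res$posthoc_tissue),
    if (!is.null(stats_res$posthoc_region))
      cbind(design = "region", stats_res$posthoc_region))
  if (!is.null(posthoc_tab)) emit(posthoc_tab, "posthoc.csv")

  report <- list(
    package = "naquant",
    version = as.character(utils::packageVersion("naquant")),
    r_version = R.version.string,
    config_hash = hash, seed = config$seed, mode = config$mode,
    n_curves = nrow(unique(curves[, c("subject_id", "roi")])),
    n_flagged = n_flag,
    alpha = stats_res$alpha,
    calibration = lapply(qc$calibrations, function(cal)
      cal[c("slope", "intercept", "fit_r_squared", "n_tubes")])
  )
  if (!is.null(out_dir)) {
    jsonlite::write_json(report, file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    if (config$mode == "simulate") {
      jsonlite::write_json(dataset$truth, file.path(out_dir, "truth.json"),
                           auto_unbox = TRUE, digits = NA,
                           dataframe = "rows")
    }
  }
  say("done")
  invisible(list(dataset = dataset, quantification = qc$quantification,
                 summary = summ, tube_fits = qc$tube_fits,
                 calibrations = qc$calibrations, stats = stats_res,
                 report = report))
}
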