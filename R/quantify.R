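#' Fit the phantom signal-to-concentration calibration line
#'
#' Ordinary least squares of tube magnetization on known tube concentration:
#' `M0 = slope * C + intercept`. Because calibration uses the TE = 0
#' extrapolations (M0), differences in relaxation between agar tubes and
#' tissue do not bias the mapping. An intercept is included by default; a
#' through-origin mode is available for sensitivity analysis.
#'
#' @param tube_m0 fitted tube magnetizations (arbitrary units).
#' @param tube_concentrations known concentrations (mM), at least 2 distinct.
#' @param intercept include an intercept term (default `TRUE`).
#' @return object of class `na_calibration`: `slope`, `intercept`,
#'   `fit_r_squared`, `n_tubes`, and the underlying `lm` fit.
#' @export
fit_calibration <- function(tube_m0, tube_concentrations, intercept = TRUE) {
  stopifnot(length(tube_m0) == length(tube_concentrations))
  if (length(tube_m0) < 2) stop("need at least 2 tubes")
  if (length(unique(tube_concentrations)) < 2) {
    stop("tube concentrations must not all be equal")
  }
  d <- data.frame(m0 = tube_m0, conc = tube_concentrations)
  fit <- if (intercept) lm(m0 ~ conc, data = d) else lm(m0 ~ conc - 1, data = d)
  cf <- coef(fit)
  slope <- unname(cf[["conc"]])
  icpt <- if (intercept) unname(cf[["(Intercept)"]]) else 0
  if (slope <= 0) stop("calibration slope must be positive")
  ss_res <- sum(residuals(fit)^2)
  ss_tot <- if (intercept) sum((d$m0 - mean(d$m0))^2) else sum(d$m0^2)
  structure(
    list(slope = slope, intercept = icpt,
         fit_r_squared = 1 - ss_res / ss_tot,
         n_tubes = length(tube_m0), lm = fit),
    class = "na_calibration"
  )
}

#' @export
print.na_calibration <- function(x, ...) {
  cat(sprintf("sodium calibration: M0 = %.4g * C + %.4g  (r^2 = %.4f, %d tubes)\n",
              x$slope, x$intercept, x$fit_r_squared, x$n_tubes))
  invisible(x)
}

#' Convert magnetization to apparent concentration
#'
#' Inverts the calibration line: `C = (M0 - intercept) / slope`. Negative
#' results (magnetization below the calibration intercept) are returned as-is
#' and flagged in the `"negative"` attribute rather than silently clipped.
#'
#' @param m0 magnetization value(s), arbitrary units.
#' @param model an [fit_calibration()] result.
#' @return concentration(s) in mM, with attribute `negative` (logical).
#' @export
to_concentration <- function(m0, model) {
  stopifnot(inherits(model, "na_calibration"))
  conc <- (m0 - model$intercept) / model$slope
  neg <- conc < 0
  if (any(neg)) warning("negative apparent concentration; flagged, not clipped")
  structure(conc, negative = neg)
}

#' Quantify sodium concentrations for one ROI fit
#'
#' Maps the short- and long-fraction magnetizations of a biexponential fit
#' through the phantom calibration: `Na_SF`, `Na_LF` (mM), their sum TSC, and
#' the extracellular fraction `EcF = Na_LF / 140 mM` (140 mM being the
#' reference extracellular sodium concentration; configurable).
#'
#' @param fit a converged, non-degenerate biexponential `decay_fit`.
#' @param model an [fit_calibration()] result.
#' @param ecf_reference extracellular reference concentration (mM).
#' @param force quantify even degenerate fits (default `FALSE`).
#' @return one-row data frame: `na_sf`, `na_lf`, `tsc`, `ecf`,
#'   `t2star_short`, `t2star_long`, `short_fraction_f`, `r_squared`,
#'   `negative_flag` (any negative concentration), `degenerate`.
#' @export
quantify_roi <- function(fit, model, ecf_reference = 140, force = FALSE) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$model != "biexp") stop("quantification requires a biexponential fit")
  if (!fit$converged) stop("fit did not converge")
  if (fit$degenerate && !force) {
    stop("degenerate fit; pass force = TRUE to quantify anyway")
  }
  m0 <- magnetization_fractions(fit)
  na_sf <- to_concentration(m0$m0_sf, model)
  na_lf <- to_concentration(m0$m0_lf, model)
  neg <- any(attr(na_sf, "negative"), attr(na_lf, "negative"))
  na_sf <- as.numeric(na_sf); na_lf <- as.numeric(na_lf)
  data.frame(
    na_sf = na_sf, na_lf = na_lf,
    tsc = na_sf + na_lf, ecf = na_lf / ecf_reference,
    t2star_short = fit$params$t2s, t2star_long = fit$params$t2l,
    short_fraction_f = fit$params$f, r_squared = fit$r_squared,
    negative_flag = neg, degenerate = fit$degenerate
  )
}

#' Fit and quantify every curve of a cohort table
#'
#' Convenience wrapper over [fit_biexp()], [fit_monoexp()],
#' [fit_calibration()] and [quantify_roi()] for tidy curve tables in the
#' dialect of [simulate_cohort()].
#'
#' @param curves ROI curve table (subject_id, roi, run, te_ms, signal).
#' @param phantom_curves tube curve table (tube_id, concentration_mM, run,
#'   te_ms, signal); may carry a `subject_id` column for per-exam calibration.
#' @param options a [fit_options()] list.
#' @param calibration `"auto"` (per-subject when the phantom table has a
#'   `subject_id` column, pooled otherwise), `"per_subject"` or `"pooled"`.
#' @param ecf_reference extracellular reference concentration (mM).
#' @param force quantify degenerate fits instead of dropping them.
#' @return list with `quantification` (per subject x ROI data frame in the
#'   column order subject_id, roi, t2s_ms, t2l_ms, f, r2, na_sf_mM, na_lf_mM,
#'   tsc_mM, ecf), `tube_fits`, `calibrations`, and `fits` (the raw
#'   `decay_fit` objects).
#' @export
quantify_cohort <- function(curves, phantom_curves, options = fit_options(),
                            calibration = c("auto", "per_subject", "pooled"),
                            ecf_reference = 140, force = FALSE) {
  calibration <- match.arg(calibration)
  per_subject <- switch(calibration,
    auto = "subject_id" %in% names(phantom_curves),
    per_subject = {
      if (!"subject_id" %in% names(phantom_curves)) {
        stop("per-subject calibration needs a subject_id column in phantom_curves")
      }
      TRUE
    },
    pooled = FALSE)

  fit_tubes <- function(tab) {
    ids <- unique(tab$tube_id)
    fits <- lapply(ids, function(id) fit_monoexp(tab[tab$tube_id == id, ], options))
    data.frame(tube_id = ids,
               concentration_mM = vapply(ids, function(id)
                 tab$concentration_mM[tab$tube_id == id][1], 1),
               m0 = vapply(fits, function(f) f$params$m0, 1),
               t2star = vapply(fits, function(f) f$params$t2star, 1),
               ric = vapply(fits, function(f) f$params$ric, 1),
               r_squared = vapply(fits, function(f) f$r_squared, 1))
  }

  calibrations <- list()
  if (per_subject) {
    for (sid in unique(phantom_curves$subject_id)) {
      tf <- fit_tubes(phantom_curves[phantom_curves$subject_id == sid, ])
      calibrations[[sid]] <- fit_calibration(tf$m0, tf$concentration_mM)
      attr(calibrations[[sid]], "tube_fits") <- tf
    }
    tube_fits <- do.call(rbind, lapply(names(calibrations), function(sid)
      cbind(subject_id = sid, attr(calibrations[[sid]], "tube_fits"))))
  } else {
    tube_fits <- fit_tubes(phantom_curves)
    calibrations[["pooled"]] <- fit_calibration(tube_fits$m0,
                                                tube_fits$concentration_mM)
  }

  keys <- unique(curves[, c("subject_id", "roi")])
  fits <- vector("list", nrow(keys))
  rows <- vector("list", nrow(keys))
  for (i in seq_len(nrow(keys))) {
    sub <- curves[curves$subject_id == keys$subject_id[i] &
                    curves$roi == keys$roi[i], ]
    fit <- fit_biexp(sub, options)
    fits[[i]] <- fit
    cal <- if (per_subject) calibrations[[keys$subject_id[i]]] else
      calibrations[["pooled"]]
    q <- tryCatch(quantify_roi(fit, cal, ecf_reference, force = force),
                  error = function(e) NULL)
    if (is.null(q)) next
    rows[[i]] <- data.frame(
      subject_id = keys$subject_id[i], roi = keys$roi[i],
      t2s_ms = q$t2star_short, t2l_ms = q$t2star_long,
      f = q$short_fraction_f, r2 = q$r_squared,
      na_sf_mM = q$na_sf, na_lf_mM = q$na_lf, tsc_mM = q$tsc, ecf = q$ecf,
      negative_flag = q$negative_flag, degenerate = q$degenerate
    )
  }
  quant <- do.call(rbind, rows)
  rownames(quant) <- NULL
  list(quantification = quant, tube_fits = tube_fits,
       calibrations = calibrations, fits = fits)
}

#' Cohort summary in the layout of a region-by-metric table
#'
#' Mean and standard deviation of each metric per region, rounded to two
#' decimals at presentation only.
#'
#' @param quantification per subject x ROI table from [quantify_cohort()].
#' @param digits rounding applied to the output (default 2); use `NA` for
#'   full precision.
#' @return data frame with one row per (region, statistic) pair across the
#'   six metrics t2s_ms, t2l_ms, na_sf_mM, na_lf_mM, tsc_mM, ecf.
#' @export
summarize_quantification <- function(quantification, digits = 2) {
  metrics <- c("t2s_ms", "t2l_ms", "na_sf_mM", "na_lf_mM", "tsc_mM", "ecf")
  rois <- unique(quantification$roi)
  out <- do.call(rbind, lapply(rois, function(r) {
    sub <- quantification[quantification$roi == r, metrics, drop = FALSE]
    mn <- vapply(sub, mean, 1); s <- vapply(sub, sd, 1)
    rbind(data.frame(roi = r, stat = "mean", t(mn)),
          data.frame(roi = r, stat = "sd", t(s)))
  }))
  if (!is.na(digits)) out[metrics] <- lapply(out[metrics], round, digits = digits)
  rownames(out) <- NULL
  out
}
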