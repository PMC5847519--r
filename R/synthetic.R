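#' Default tissue parameters for the synthetic cohort
#'
#' Region-level means and between-subject spreads of the biexponential decay
#' parameters for the ten brain regions the pipeline quantifies: whole
#' grey-matter (GM) and white-matter (WM) segmentations plus eight bilateral
#' sub-regions. T2* means and spreads, and the total sodium concentrations
#' used to scale the amplitudes, are cohort means reported for healthy adults
#' at 7 T; the short signal fraction `f` uses the region values reported for
#' GM, caudate, pons and centrum semiovale and the literature short:long
#' ratio of roughly 60:40 elsewhere.
#'
#' @return data frame with one row per region: `region`, `t2star_short`,
#'   `t2star_long` (ms) and their between-subject s.d., `short_fraction_f`
#'   and its s.d., and `tsc_mM` (mM) with its s.d. (used to set the signal
#'   amplitude through the calibration slope).
#' @export
tissue_defaults <- function() {
  df <- data.frame(
    region = c("GM", "WM", "thalamus", "putamen", "pallidum", "caudate",
               "corpus_callosum", "cerebellar_WM", "centrum_semiovale", "pons"),
    t2star_short = c(4.99, 4.44, 3.70, 3.72, 2.82, 4.00, 3.48, 3.57, 4.37, 2.43),
    t2s_sd       = c(0.41, 0.34, 0.41, 0.61, 0.44, 0.61, 0.42, 0.81, 0.43, 0.58),
    t2star_long  = c(31.51, 38.25, 40.13, 32.66, 31.62, 34.79, 39.82, 35.51, 54.74, 31.52),
    t2l_sd       = c(1.78, 2.45, 7.50, 7.00, 6.87, 6.37, 9.16, 7.26, 14.98, 11.45),
    short_fraction_f = c(0.46, 0.60, 0.60, 0.60, 0.60, 0.52, 0.60, 0.60, 0.70, 0.52),
    f_sd         = c(0.03, 0.07, 0.07, 0.07, 0.07, 0.06, 0.07, 0.07, 0.04, 0.10),
    tsc_mM       = c(46.92, 38.15, 40.30, 36.29, 33.24, 37.06, 35.52, 28.60, 32.39, 25.18),
    tsc_sd       = c(2.83, 1.97, 2.33, 1.76, 2.62, 2.09, 3.35, 2.88, 2.74, 3.17),
    stringsAsFactors = FALSE
  )
  df
}

#' Reference-phantom specification
#'
#' Six agar-gel tubes spanning 10--75 mM sodium, imaged in the field of view
#' with the subject, calibrate magnitude signal to concentration. Tube signal
#' decays monoexponentially; the default tube T2* of 12 ms is a simulation
#' choice for 2% agar, not a measured value.
#'
#' @param tube_concentrations tube sodium concentrations in mM.
#' @param tube_t2star apparent T2* per tube (ms); recycled.
#' @param signal_per_mM calibration slope (arbitrary units per mM).
#' @param intercept calibration intercept (arbitrary units).
#' @return a list of class `phantom_spec`.
#' @export
phantom_spec <- function(tube_concentrations = c(10, 23, 36, 49, 62, 75),
                         tube_t2star = 12,
                         signal_per_mM = 2,
                         intercept = 0) {
  stopifnot(length(tube_concentrations) >= 2,
            all(tube_concentrations > 0),
            all(tube_t2star > 0),
            signal_per_mM > 0)
  structure(
    list(
      tube_concentrations = tube_concentrations,
      tube_t2star = rep_len(tube_t2star, length(tube_concentrations)),
      signal_per_mM = signal_per_mM,
      intercept = intercept
    ),
    class = "phantom_spec"
  )
}

#' Draw Rician-distributed magnitude samples
#'
#' Magnitude MRI signal with complex Gaussian noise of s.d. `sigma` follows a
#' Rician distribution: `sqrt((S + n1)^2 + n2^2)` with `n1`, `n2` independent
#' zero-mean Gaussians. At zero true signal this is a Rayleigh distribution
#' with mean `sigma * sqrt(pi/2)`; at high SNR the mean approaches
#' `S + sigma^2 / (2 S)`, which is the noise floor the `Ric` fit parameter
#' absorbs.
#'
#' @param true_signal vector of noiseless signal values (arbitrary units).
#' @param sigma Gaussian noise s.d. per channel; must be >= 0.
#' @return vector of magnitude samples, same length as `true_signal`.
#' @export
rician_sample <- function(true_signal, sigma) {
  if (length(sigma) != 1L || is.na(sigma) || sigma < 0) {
    stop("sigma must be a single non-negative number")
  }
  if (sigma == 0) return(abs(true_signal))
  n <- length(true_signal)
  sqrt((true_signal + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2)
}

#' Simulate one ROI-mean decay curve
#'
#' The noiseless mean is the biexponential
#' `A * (f * exp(-TE/T2*short) + (1-f) * exp(-TE/T2*long))`; each echo is then
#' Rician-corrupted with noise s.d. `sigma`.
#'
#' @param spec a list or one-row data frame with fields `amplitude_A`,
#'   `short_fraction_f`, `t2star_short`, `t2star_long`.
#' @param schedule an [acq_schedule()]; defaults to the 24-echo schedule.
#' @param sigma Rician noise s.d. (same arbitrary units as `amplitude_A`).
#' @param source_id label stored on the curve.
#' @return a `decay_curve` data frame with columns `te_ms`, `run`, `signal`;
#'   the generating parameters are attached as attribute `"truth"`.
#' @export
simulate_roi_curve <- function(spec, schedule = make_default_schedule(),
                               sigma = 0, source_id = "roi") {
  spec <- as.list(spec)
  stopifnot(spec$short_fraction_f >= 0, spec$short_fraction_f <= 1,
            spec$t2star_short > 0, spec$t2star_short < spec$t2star_long)
  schedule <- validate_schedule(as.data.frame(schedule))
  mu <- biexp_signal(schedule$te_ms,
                     A = spec$amplitude_A, f = spec$short_fraction_f,
                     t2s = spec$t2star_short, t2l = spec$t2star_long, ric = 0)
  curve <- data.frame(te_ms = schedule$te_ms, run = schedule$run,
                      signal = rician_sample(mu, sigma))
  attr(curve, "truth") <- spec[c("amplitude_A", "short_fraction_f",
                                 "t2star_short", "t2star_long")]
  attr(curve, "source_id") <- source_id
  class(curve) <- c("decay_curve", "data.frame")
  curve
}

#' Simulate reference-tube decay curves
#'
#' Tube `t` has noiseless signal `(signal_per_mM * C_t + intercept) *
#' exp(-TE / T2*_t)`, Rician-corrupted with s.d. `sigma`.
#'
#' @param spec a [phantom_spec()].
#' @param schedule an [acq_schedule()].
#' @param sigma Rician noise s.d.
#' @return data frame with columns `tube_id`, `concentration_mM`, `run`,
#'   `te_ms`, `signal`; generating `m0` and `t2star` per tube attached as
#'   attribute `"truth"` (a data frame).
#' @export
simulate_phantom <- function(spec = phantom_spec(),
                             schedule = make_default_schedule(), sigma = 0) {
  stopifnot(inherits(spec, "phantom_spec"))
  schedule <- validate_schedule(as.data.frame(schedule))
  n_tube <- length(spec$tube_concentrations)
  m0 <- spec$signal_per_mM * spec$tube_concentrations + spec$intercept
  out <- do.call(rbind, lapply(seq_len(n_tube), function(t) {
    mu <- monoexp_signal(schedule$te_ms, m0 = m0[t],
                         t2star = spec$tube_t2star[t], ric = 0)
    data.frame(tube_id = sprintf("tube%02d", t),
               concentration_mM = spec$tube_concentrations[t],
               run = schedule$run, te_ms = schedule$te_ms,
               signal = rician_sample(mu, sigma))
  }))
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(
    tube_id = sprintf("tube%02d", seq_len(n_tube)),
    concentration_mM = spec$tube_concentrations,
    m0 = m0, t2star = spec$tube_t2star
  )
  out
}

#' Cohort simulation configuration
#'
#' @param n_subjects number of subjects (default 13).
#' @param n_female number of female subjects (default 5).
#' @param age_range sampling range for subject age in years (default 20--32).
#' @param regions subset of `tissue_defaults()$region` to simulate.
#' @param tissue tissue parameter table (see [tissue_defaults()]).
#' @param phantom a [phantom_spec()].
#' @param schedule an [acq_schedule()].
#' @param sigma Rician noise s.d. in signal units; ignored when `snr` is set.
#' @param snr convenience signal-to-noise specification: per curve,
#'   `sigma = amplitude / snr` (for tubes, `sigma = M0_tube / snr`).
#' @param spread_scale multiplier on all between-subject spreads; 0 makes
#'   every subject equal to the region mean.
#' @param seed integer seed; mandatory.
#' @return a list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 13, n_female = min(5, n_subjects),
                          age_range = c(20, 32),
                          regions = tissue_defaults()$region,
                          tissue = tissue_defaults(),
                          phantom = phantom_spec(),
                          schedule = make_default_schedule(),
                          sigma = 0, snr = NULL,
                          spread_scale = 1, seed = 1L) {
  stopifnot(n_subjects >= 1, n_female >= 0, n_female <= n_subjects,
            length(age_range) == 2, age_range[1] <= age_range[2],
            spread_scale >= 0, is.numeric(seed), length(seed) == 1)
  if (!all(regions %in% tissue$region)) {
    stop("unknown region(s): ",
         paste(setdiff(regions, tissue$region), collapse = ", "))
  }
  structure(
    list(n_subjects = as.integer(n_subjects), n_female = as.integer(n_female),
         age_range = age_range, regions = regions, tissue = tissue,
         phantom = phantom, schedule = schedule, sigma = sigma, snr = snr,
         spread_scale = spread_scale, seed = as.integer(seed)),
    class = "cohort_config"
  )
}

#' Simulate a full synthetic cohort
#'
#' Draws per-subject decay parameters around the region means — T2* values and
#' amplitude multiplicatively (log-normal, coefficient of variation from the
#' tissue table), the short fraction additively on the logit scale — then
#' simulates one Rician-corrupted 24-echo curve per subject x region plus the
#' six reference-tube curves. Deterministic under `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return a list of class `cohort_dataset` with elements `subjects`
#'   (subject_id, sex, age), `curves` (subject_id, roi, run, te_ms, signal),
#'   `phantom_curves` (tube_id, concentration_mM, run, te_ms, signal),
#'   `truth` (generating parameters and implied concentrations per curve),
#'   `phantom_truth`, `noise_sigma`, `seed`, `config`.
#' @export
simulate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  if (exists(".Random.seed", envir = globalenv())) {
    old_seed <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old_seed, envir = globalenv()))
  }
  set.seed(config$seed)

  subjects <- data.frame(
    subject_id = sprintf("S%02d", seq_len(config$n_subjects)),
    sex = sample(rep(c("female", "male"),
                     c(config$n_female, config$n_subjects - config$n_female))),
    age = round(runif(config$n_subjects, config$age_range[1],
                      config$age_range[2]), 1)
  )

  tis <- config$tissue[match(config$regions, config$tissue$region), ]
  slope <- config$phantom$signal_per_mM
  icpt <- config$phantom$intercept

  curves <- vector("list", nrow(subjects) * nrow(tis))
  truth <- vector("list", length(curves))
  k <- 0L
  for (s in seq_len(nrow(subjects))) {
    for (r in seq_len(nrow(tis))) {
      k <- k + 1L
      row <- tis[r, ]
      sc <- config$spread_scale
      # multiplicative spread on T2* and amplitude, logit-additive on f
      t2s <- row$t2star_short * exp(rnorm(1, 0, sc * row$t2s_sd / row$t2star_short))
      t2l <- row$t2star_long * exp(rnorm(1, 0, sc * row$t2l_sd / row$t2star_long))
      if (t2l <= 1.05 * t2s) t2l <- 1.05 * t2s  # keep components ordered
      f_mean <- row$short_fraction_f
      sd_logit <- sc * row$f_sd / (f_mean * (1 - f_mean))
      f <- plogis(qlogis(f_mean) + rnorm(1, 0, sd_logit))
      f <- min(max(f, 0.01), 0.99)
      tsc <- row$tsc_mM * exp(rnorm(1, 0, sc * row$tsc_sd / row$tsc_mM))
      A <- slope * tsc + 2 * icpt  # so both component M0s map back to f*tsc, (1-f)*tsc
      sig <- if (!is.null(config$snr)) A / config$snr else config$sigma
      spec <- list(amplitude_A = A, short_fraction_f = f,
                   t2star_short = t2s, t2star_long = t2l)
      cv <- simulate_roi_curve(spec, config$schedule, sig,
                               source_id = paste(subjects$subject_id[s],
                                                 row$region, sep = ":"))
      curves[[k]] <- data.frame(subject_id = subjects$subject_id[s],
                                roi = row$region, cv[, c("run", "te_ms", "signal")])
      truth[[k]] <- data.frame(
        subject_id = subjects$subject_id[s], roi = row$region,
        amplitude_A = A, short_fraction_f = f,
        t2star_short = t2s, t2star_long = t2l, sigma = sig,
        na_sf = (A * f - icpt) / slope,
        na_lf = (A * (1 - f) - icpt) / slope
      )
    }
  }
  curves <- do.call(rbind, curves)
  truth <- do.call(rbind, truth)
  truth$tsc <- truth$na_sf + truth$na_lf
  rownames(curves) <- rownames(truth) <- NULL

  ph_sigma <- if (!is.null(config$snr)) {
    (config$phantom$signal_per_mM * config$phantom$tube_concentrations +
       config$phantom$intercept) / config$snr
  } else rep(config$sigma, length(config$phantom$tube_concentrations))
  sch <- validate_schedule(as.data.frame(config$schedule))
  tube_m0 <- config$phantom$signal_per_mM * config$phantom$tube_concentrations +
    config$phantom$intercept
  ph <- do.call(rbind, lapply(seq_along(ph_sigma), function(t) {
    mu <- monoexp_signal(sch$te_ms, m0 = tube_m0[t],
                         t2star = config$phantom$tube_t2star[t], ric = 0)
    data.frame(tube_id = sprintf("tube%02d", t),
               concentration_mM = config$phantom$tube_concentrations[t],
               run = sch$run, te_ms = sch$te_ms,
               signal = rician_sample(mu, ph_sigma[t]))
  }))
  rownames(ph) <- NULL
  phantom_truth <- data.frame(
    tube_id = sprintf("tube%02d", seq_along(ph_sigma)),
    concentration_mM = config$phantom$tube_concentrations,
    m0 = tube_m0,
    t2star = config$phantom$tube_t2star, sigma = ph_sigma
  )

  structure(
    list(subjects = subjects, curves = curves, phantom_curves = ph,
         truth = truth, phantom_truth = phantom_truth,
         noise_sigma = if (!is.null(config$snr)) NA_real_ else config$sigma,
         seed = config$seed, config = config),
    class = "cohort_dataset"
  )
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("Synthetic sodium-MRI cohort\n")
  cat("  subjects:", nrow(x$subjects),
      sprintf("(%d female)", sum(x$subjects$sex == "female")), "\n")
  cat("  regions: ", length(unique(x$curves$roi)), "\n")
  cat("  curves:  ", length(unique(paste(x$curves$subject_id, x$curves$roi))),
      "ROI +", length(unique(x$phantom_curves$tube_id)), "tubes\n")
  cat("  echoes:  ", length(unique(x$curves$te_ms)), " seed:", x$seed, "\n")
  invisible(x)
}

#' Write / read tidy curve tables
#'
#' ROI curves use columns (subject_id, roi, run, te_ms, signal); tube curves
#' use (tube_id, concentration_mM, run, te_ms, signal). Lines starting with
#' `#` are treated as comments on read.
#'
#' @param curves data frame in one of the two dialects.
#' @param path CSV file path.
#' @return `read_curves` returns the data frame; writers return `path`
#'   invisibly.
#' @export
write_curves <- function(curves, path) {
  write.csv(as.data.frame(curves), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_curves
#' @export
read_curves <- function(path) {
  read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}
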