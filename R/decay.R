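#' Rician-floored biexponential decay signal
#'
#' Magnitude signal of a two-compartment transverse decay observed on
#' magnitude images:
#' `sqrt( [A * (f * exp(-TE/T2s) + (1-f) * exp(-TE/T2l))]^2 + Ric^2 )`.
#' The `Ric` term models the Rician noise floor that magnitude data approach
#' at long echo times instead of zero.
#'
#' @param te echo time(s), milliseconds; must be non-negative.
#' @param A amplitude scaling (signal at TE = 0 when Ric = 0).
#' @param f short-component signal fraction, in `[0, 1]`.
#' @param t2s,t2l short and long apparent transverse relaxation times (ms),
#'   `0 < t2s <= t2l`.
#' @param ric Rician noise-floor parameter, >= 0.
#' @return signal values, same length as `te`.
#' @export
biexp_signal <- function(te, A, f, t2s, t2l, ric = 0) {
  if (any(te < 0)) stop("echo times must be non-negative")
  decay <- A * (f * exp(-te / t2s) + (1 - f) * exp(-te / t2l))
  sqrt(decay^2 + ric^2)
}

#' Rician-floored monoexponential decay signal
#'
#' `sqrt( (M0 * exp(-TE/T2*))^2 + Ric^2 )` — the single-compartment model
#' used for the agar reference tubes.
#'
#' @param te echo time(s), milliseconds, non-negative.
#' @param m0 magnetization at TE = 0 (arbitrary units).
#' @param t2star apparent transverse relaxation time (ms), > 0.
#' @param ric Rician noise-floor parameter, >= 0.
#' @return signal values, same length as `te`.
#' @export
monoexp_signal <- function(te, m0, t2star, ric = 0) {
  if (any(te < 0)) stop("echo times must be non-negative")
  sqrt((m0 * exp(-te / t2star))^2 + ric^2)
}

#' Coefficient of determination of a fit
#'
#' `1 - SS_res / SS_tot`, computed on the raw (not log-transformed) signal
#' values, matching the domain in which the least-squares fit is performed.
#'
#' @param observed observed signal values (non-constant, length >= 2).
#' @param fitted model-predicted values of the same length.
#' @return scalar r-squared (can be negative for fits worse than the mean).
#' @export
r_squared <- function(observed, fitted) {
  if (length(observed) != length(fitted)) stop("unequal lengths")
  if (length(observed) < 2) stop("need at least 2 points")
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("observed values are constant; r-squared undefined")
  1 - sum((observed - fitted)^2) / ss_tot
}

#' Fitting options for the decay models
#'
#' Bounds bracket literature T2* values (short component ~0.5--5 ms, long
#' ~15--55 ms in parenchyma, CSF up to ~64 ms). Multi-start initialisation
#' covers both sides of the typical short:long fraction and both decay
#' regimes; the best sum of squared errors wins, ties broken by the smaller
#' long T2*.
#'
#' @param f_starts starting values for the short fraction.
#' @param t2s_starts,t2l_starts starting values for the two T2* components (ms).
#' @param t2s_bounds,t2l_bounds box constraints on the T2* components (ms).
#' @param amplitude_factor upper bound on A as a multiple of the peak signal.
#' @param ftol relative SSE convergence tolerance.
#' @param maxfev maximum residual evaluations per start.
#' @param degenerate_f_tol fits with `f` within this distance of 0 or 1 are
#'   flagged degenerate.
#' @param degenerate_ratio fits with `t2l / t2s` below this are flagged
#'   degenerate (the two components are not separable).
#' @param include_ric estimate the Rician floor term (set `FALSE` for pure
#'   exponentials, e.g. noiseless data or floor-subtracted signal).
#' @return list of class `fit_options`.
#' @export
fit_options <- function(f_starts = c(0.4, 0.6, 0.8),
                        t2s_starts = c(2, 5),
                        t2l_starts = c(25, 45),
                        t2s_bounds = c(0.2, 15),
                        t2l_bounds = c(10, 150),
                        amplitude_factor = 10,
                        ftol = 1e-10,
                        maxfev = 2000,
                        degenerate_f_tol = 1e-3,
                        degenerate_ratio = 1.5,
                        include_ric = TRUE) {
  structure(as.list(environment()), class = "fit_options")
}

as_curve_df <- function(curve) {
  curve <- as.data.frame(curve)
  if (!all(c("te_ms", "signal") %in% names(curve))) {
    stop("curve needs columns te_ms and signal")
  }
  if (any(!is.finite(curve$te_ms)) || any(!is.finite(curve$signal))) {
    stop("non-finite values in curve")
  }
  if (any(curve$signal < 0)) stop("magnitude signals must be non-negative")
  curve[order(curve$te_ms), , drop = FALSE]
}

#' Fit the biexponential model to a decay curve
#'
#' Bounded nonlinear least squares (Levenberg-Marquardt) on the
#' [biexp_signal()] model over parameters `(A, f, t2s, t2l, ric)`, restarted
#' from a small grid of initial values. The returned solution is
#' canonicalised so that `t2s <= t2l` (swapping the components and replacing
#' `f` by `1 - f` if needed). Fits where `f` collapses to 0/1 or the two time
#' constants are within a factor `degenerate_ratio` are flagged `degenerate`:
#' the curve carries no evidence of two components.
#'
#' @param curve a data frame with columns `te_ms` and `signal` (a
#'   `decay_curve`); at least 6 distinct echo times. Curves that do not
#'   sample both the early (< 3 ms) and late (> 30 ms) parts of the decay
#'   give unreliable component estimates and raise a warning.
#' @param options a [fit_options()] list.
#' @return object of class `decay_fit`: list with `model = "biexp"`, `params`
#'   (A, f, t2s, t2l, ric), `r_squared`, `rss`, `converged`, `degenerate`,
#'   `n_starts_used`, `fitted`, and the inputs.
#' @export
fit_biexp <- function(curve, options = fit_options()) {
  curve <- as_curve_df(curve)
  te <- curve$te_ms; y <- curve$signal
  if (length(unique(te)) < 6) stop("biexponential fit needs >= 6 distinct echo times")
  if (!any(te < 3) || !any(te > 30)) {
    warning("echo times do not span both early (<3 ms) and late (>30 ms) decay")
  }
  ymax <- max(y)
  if (ymax <= 0) stop("all-zero signals cannot be fitted")

  with_ric <- options$include_ric
  lower <- c(A = 1e-8, f = 0, t2s = options$t2s_bounds[1],
             t2l = options$t2l_bounds[1], ric = 0)
  upper <- c(A = options$amplitude_factor * ymax, f = 1,
             t2s = options$t2s_bounds[2], t2l = options$t2l_bounds[2],
             ric = ymax)
  if (!with_ric) {
    lower <- lower[names(lower) != "ric"]
    upper <- upper[names(upper) != "ric"]
  }
  resid_fn <- function(p) {
    ric <- if (with_ric) p[["ric"]] else 0
    biexp_signal(te, p[["A"]], p[["f"]], p[["t2s"]], p[["t2l"]], ric) - y
  }

  starts <- expand.grid(f = options$f_starts, t2s = options$t2s_starts,
                        t2l = options$t2l_starts)
  best <- NULL
  n_used <- 0L
  for (i in seq_len(nrow(starts))) {
    p0 <- c(A = ymax, f = starts$f[i], t2s = starts$t2s[i],
            t2l = starts$t2l[i])
    if (with_ric) p0 <- c(p0, ric = min(y))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = options$ftol, maxfev = options$maxfev,
                           maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_used <- n_used + 1L
    par <- unlist(fit$par)
    if (!with_ric) par <- c(par, ric = 0)
    cand <- list(par = par, rss = fit$deviance,
                 converged = fit$info %in% 1:4)
    cand$par <- canonical_biexp(cand$par)
    if (is.null(best) ||
        cand$rss < best$rss * (1 - 1e-12) ||
        (abs(cand$rss - best$rss) <= 1e-12 * max(best$rss, 1) &&
         cand$par[["t2l"]] < best$par[["t2l"]])) {
      best <- cand
    }
  }
  if (is.null(best)) stop("all starts failed")

  p <- best$par
  fitted <- biexp_signal(te, p[["A"]], p[["f"]], p[["t2s"]], p[["t2l"]], p[["ric"]])
  degenerate <- p[["f"]] <= options$degenerate_f_tol ||
    p[["f"]] >= 1 - options$degenerate_f_tol ||
    p[["t2l"]] / p[["t2s"]] < options$degenerate_ratio
  structure(
    list(model = "biexp",
         params = as.list(p),
         r_squared = r_squared(y, fitted),
         rss = best$rss,
         converged = best$converged,
         degenerate = degenerate,
         n_starts_used = n_used,
         fitted = fitted,
         curve = curve,
         options = options),
    class = "decay_fit"
  )
}

canonical_biexp <- function(p) {
  if (p[["t2s"]] > p[["t2l"]]) {
    p[c("t2s", "t2l")] <- p[c("t2l", "t2s")]
    p[["f"]] <- 1 - p[["f"]]
  }
  p
}

#' Fit the monoexponential model to a decay curve
#'
#' Bounded least-squares fit of [monoexp_signal()]; `m0` is the TE = 0
#' extrapolation used for phantom calibration.
#'
#' @param curve data frame with `te_ms` and `signal`; >= 4 distinct echoes.
#' @param options a [fit_options()] list (`include_ric` controls the floor
#'   term; other bounds reused where meaningful).
#' @return `decay_fit` with `model = "monoexp"` and params `(m0, t2star, ric)`.
#' @export
fit_monoexp <- function(curve, options = fit_options()) {
  curve <- as_curve_df(curve)
  te <- curve$te_ms; y <- curve$signal
  if (length(unique(te)) < 4) stop("monoexponential fit needs >= 4 distinct echo times")
  ymax <- max(y)
  if (ymax <= 0) stop("all-zero signals cannot be fitted")

  with_ric <- options$include_ric
  lower <- c(m0 = 1e-8, t2star = 0.2)
  upper <- c(m0 = options$amplitude_factor * ymax, t2star = 200)
  if (with_ric) {
    lower <- c(lower, ric = 0)
    upper <- c(upper, ric = ymax)
  }
  resid_fn <- function(p) {
    ric <- if (with_ric) p[["ric"]] else 0
    monoexp_signal(te, p[["m0"]], p[["t2star"]], ric) - y
  }
  best <- NULL
  n_used <- 0L
  for (t2_0 in c(5, 12, 40)) {
    p0 <- c(m0 = ymax, t2star = t2_0)
    if (with_ric) p0 <- c(p0, ric = min(y))
    fit <- tryCatch(
      minpack.lm::nls.lm(p0, lower = lower, upper = upper, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           ftol = options$ftol, maxfev = options$maxfev,
                           maxiter = 1000)),
      error = function(e) NULL)
    if (is.null(fit)) next
    n_used <- n_used + 1L
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) stop("all starts failed")
  p <- unlist(best$par)
  if (!with_ric) p <- c(p, ric = 0)
  fitted <- monoexp_signal(te, p[["m0"]], p[["t2star"]], p[["ric"]])
  structure(
    list(model = "monoexp",
         params = as.list(p),
         r_squared = r_squared(y, fitted),
         rss = best$deviance,
         converged = best$info %in% 1:4,
         degenerate = FALSE,
         n_starts_used = n_used,
         fitted = fitted,
         curve = curve,
         options = options),
    class = "decay_fit"
  )
}

#' Magnetizations of the short and long signal fractions
#'
#' Extrapolates each component to TE = 0: `M0_SF = A * f`,
#' `M0_LF = A * (1 - f)`. These are the quantities mapped through the phantom
#' calibration to concentrations.
#'
#' @param fit a converged biexponential `decay_fit`.
#' @return list with `m0_sf` and `m0_lf` (their sum equals `A` exactly).
#' @export
magnetization_fractions <- function(fit) {
  stopifnot(inherits(fit, "decay_fit"))
  if (fit$model != "biexp") stop("magnetization fractions require a biexponential fit")
  if (!fit$converged) stop("fit did not converge")
  A <- fit$params$A; f <- fit$params$f
  list(m0_sf = A * f, m0_lf = A * (1 - f))
}

#' @export
print.decay_fit <- function(x, digits = 4, ...) {
  cat(sprintf("%s decay fit (%d echoes)\n", x$model, nrow(x$curve)))
  print(round(unlist(x$params), digits))
  cat(sprintf("r^2 = %.4f  rss = %.4g  converged = %s%s\n",
              x$r_squared, x$rss, x$converged,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Serialize a fit to a JSON record
#'
#' @param fit a `decay_fit`.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return JSON string (invisibly, when written to `path`).
#' @export
fit_to_json <- function(fit, path = NULL) {
  rec <- list(model = fit$model, params = fit$params,
              r_squared = fit$r_squared, rss = fit$rss,
              converged = fit$converged, degenerate = fit$degenerate,
              n_starts_used = fit$n_starts_used,
              options = unclass(fit$options))
  json <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(json))
  }
  json
}
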