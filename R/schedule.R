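#' Multi-echo acquisition schedules
#'
#' The default acquisition interleaves three 8-echo runs of a density-adapted
#' radial sequence, giving 24 echo times from 0.3 to 100 ms. Logarithmic-like
#' spacing of the earliest echoes (0.3, 0.8, 2.3 ms) gives sensitivity to the
#' short T2* component; later echoes are roughly evenly spaced. An alternate
#' 23-echo variant over the same range is provided as `"alt23"`.
#'
#' @param name schedule variant: `"default24"` (three runs of 8 echoes) or
#'   `"alt23"` (23 echoes across three runs).
#' @return An object of class `acq_schedule`: a data frame with columns
#'   `te_ms` (echo time, milliseconds) and `run` (run index 1..3), in
#'   acquisition order (run by run). Use [sort()] semantics on `te_ms` for a
#'   merged view.
#' @examples
#' sch <- make_default_schedule()
#' nrow(sch)            # 24
#' head(sort(sch$te_ms), 3)  # 0.3 0.8 2.3
#' @export
make_default_schedule <- function(name = c("default24", "alt23")) {
  name <- match.arg(name)
  runs <- switch(name,
    default24 = list(
      c(0.3, 6.3, 13, 19, 25, 31, 54, 89),
      c(0.8, 7, 12, 17, 23, 35, 45, 80),
      c(2.3, 9.7, 15, 21, 28, 40, 66, 100)
    ),
    alt23 = list(
      c(0.3, 6.3, 13, 19, 25, 31, 50, 100),
      c(2, 7, 12, 17, 23, 40, 45, 80),
      c(3, 9, 15, 22, 28, 34, 70)
    )
  )
  sch <- data.frame(
    te_ms = unlist(runs),
    run = rep(seq_along(runs), vapply(runs, length, 1L))
  )
  validate_schedule(sch)
}

#' Build a schedule from explicit echo times
#'
#' @param te_ms echo times in milliseconds, strictly positive.
#' @param run optional run label per echo (defaults to a single run).
#' @return an `acq_schedule` data frame.
#' @export
acq_schedule <- function(te_ms, run = rep(1L, length(te_ms))) {
  validate_schedule(data.frame(te_ms = te_ms, run = as.integer(run)))
}

validate_schedule <- function(sch) {
  stopifnot(is.data.frame(sch), all(c("te_ms", "run") %in% names(sch)))
  if (nrow(sch) == 0L) stop("schedule is empty")
  if (any(sch$te_ms <= 0)) stop("echo times must be strictly positive")
  te_sorted <- sort(sch$te_ms)
  if (any(diff(te_sorted) <= 0)) {
    stop("merged echo times must be strictly increasing (duplicate TE)")
  }
  class(sch) <- c("acq_schedule", "data.frame")
  sch
}
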