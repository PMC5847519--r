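#' Factorial ANOVA for one quantification metric
#'
#' Fixed-effects linear model of a metric on a grouping factor (tissue type
#' with 2 levels, or region with 8 levels) plus sex and continuous age, with
#' Type II sums of squares for the per-factor F tests (no interactions are
#' modelled). The whole-model F comes from the overall regression test.
#'
#' @param table long-format data frame with columns `subject_id`, `sex`,
#'   `age`, `group_label`, `metric_name`, `value`.
#' @param metric metric to analyse, one of the `metric_name` values
#'   (conventionally t2s, t2l, na_sf, na_lf, tsc, ecf).
#' @param group name of the factor of interest column (default
#'   `"group_label"`).
#' @param covariates additional model terms (default sex and age).
#' @return object of class `na_anova`: `metric`, `whole_model` (F, df1, df2,
#'   p) and `terms` (data frame of per-factor F, df, p).
#' @export
run_anova <- function(table, metric, group = "group_label",
                      covariates = c("sex", "age")) {
  stopifnot(all(c("metric_name", "value", group, covariates) %in% names(table)))
  d <- table[table$metric_name == metric, , drop = FALSE]
  if (nrow(d) == 0) stop("no rows for metric ", metric)
  d[[group]] <- factor(d[[group]])
  if (nlevels(d[[group]]) < 2) stop("grouping factor needs >= 2 levels")
  if (anyNA(d$value)) stop("missing metric values")
  fml <- stats::reformulate(c(group, covariates), response = "value")
  fit <- lm(fml, data = d)
  if (any(is.na(coef(fit)))) stop("rank-deficient design")
  sm <- summary(fit)
  fstat <- sm$fstatistic
  whole <- list(f = unname(fstat[1]), df1 = unname(fstat[2]),
                df2 = unname(fstat[3]),
                p = unname(pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)))
  a2 <- car::Anova(fit, type = 2)
  keep <- rownames(a2) != "Residuals"
  terms <- data.frame(
    term = rownames(a2)[keep],
    df = a2$Df[keep],
    f = a2$`F value`[keep],
    p = a2$`Pr(>F)`[keep]
  )
  structure(list(metric = metric, whole_model = whole, terms = terms,
                 lm = fit),
            class = "na_anova")
}

#' @export
print.na_anova <- function(x, ...) {
  cat(sprintf("ANOVA for %s: whole model F(%d,%d) = %.3f, p = %.4g\n",
              x$metric, x$whole_model$df1, x$whole_model$df2,
              x$whole_model$f, x$whole_model$p))
  print(x$terms, row.names = FALSE)
  invisible(x)
}

#' Steel-Dwass all-pairs nonparametric comparison
#'
#' For every pair of groups, joint mid-ranks are computed over the two
#' samples alone; the Mann-Whitney-type rank-sum statistic is standardized
#' with the tie-corrected variance `n1*n2/12 * ((N+1) - sum(t^3-t)/(N*(N-1)))`
#' and a continuity correction of 0.5, and referred to the studentized-range
#' distribution with `k` groups (`sqrt(2)*|z|` compared to the range
#' quantile), which adjusts for all `k(k-1)/2` comparisons among the levels.
#' With `k = 2` this reduces to the normal-approximation Wilcoxon rank-sum
#' test.
#'
#' @param x either a named list of numeric samples, or a numeric vector
#'   (then `g` gives group labels).
#' @param g optional group labels when `x` is a vector.
#' @return data frame of class `steel_dwass`: one row per unordered pair with
#'   `group_a`, `group_b`, `z` (sign: positive when `group_a` ranks higher),
#'   and `p_adjusted`.
#' @export
steel_dwass <- function(x, g = NULL) {
  groups <- if (is.null(g)) x else split(x, g)
  if (!is.list(groups) || length(groups) < 2) stop("need >= 2 groups")
  if (is.null(names(groups)) || any(names(groups) == "")) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  sizes <- vapply(groups, length, 1L)
  if (any(sizes < 3)) stop("every group needs >= 3 observations")
  k <- length(groups)
  pairs <- utils::combn(k, 2)
  out <- data.frame(group_a = character(0), group_b = character(0),
                    z = numeric(0), p_adjusted = numeric(0))
  for (j in seq_len(ncol(pairs))) {
    i1 <- pairs[1, j]; i2 <- pairs[2, j]
    x1 <- groups[[i1]]; x2 <- groups[[i2]]
    n1 <- length(x1); n2 <- length(x2); N <- n1 + n2
    r <- rank(c(x1, x2))          # mid-ranks over the two samples only
    w <- sum(r[seq_len(n1)])      # rank sum of the first group
    e <- n1 * (N + 1) / 2
    ties <- table(c(x1, x2))
    v <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    if (v <= 0) stop("zero variance (all pooled values tied) for pair ",
                     names(groups)[i1], " vs ", names(groups)[i2])
    d <- w - e
    z <- sign(d) * max(abs(d) - 0.5, 0) / sqrt(v)
    p <- ptukey(sqrt(2) * abs(z), nmeans = k, df = Inf, lower.tail = FALSE)
    out[j, ] <- list(names(groups)[i1], names(groups)[i2], z, p)
  }
  class(out) <- c("steel_dwass", "data.frame")
  attr(out, "k") <- k
  out
}

#' Bonferroni-corrected significance level
#'
#' Splits a familywise alpha across `n_tests` dependent variables:
#' `alpha / n_tests`. The printed value is rounded to three decimals (0.05/6
#' prints as 0.008); the full-precision value is what comparisons should use.
#'
#' @param n_tests number of tests in the family (>= 1).
#' @param family_alpha familywise error rate (default 0.05).
#' @return list with `alpha` (full precision), `alpha_printed` (3 decimals),
#'   `n_tests`, `family_alpha`.
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  stopifnot(n_tests >= 1, family_alpha > 0, family_alpha < 1)
  a <- family_alpha / n_tests
  list(alpha = a, alpha_printed = round(a, 3),
       n_tests = as.integer(n_tests), family_alpha = family_alpha)
}

#' Long-format cohort table for group statistics
#'
#' Reshapes the per subject x ROI quantification into the long format that
#' [run_anova()] and [steel_dwass()] consume, with metric names t2s, t2l,
#' na_sf, na_lf, tsc, ecf.
#'
#' @param quantification table from [quantify_cohort()].
#' @param subjects data frame with `subject_id`, `sex`, `age`.
#' @param rois subset of regions to keep (default: all present).
#' @return data frame (subject_id, sex, age, group_label, metric_name, value).
#' @export
cohort_table <- function(quantification, subjects,
                         rois = unique(quantification$roi)) {
  metric_cols <- c(t2s = "t2s_ms", t2l = "t2l_ms", na_sf = "na_sf_mM",
                   na_lf = "na_lf_mM", tsc = "tsc_mM", ecf = "ecf")
  q <- quantification[quantification$roi %in% rois, , drop = FALSE]
  q <- merge(q, subjects, by = "subject_id")
  out <- do.call(rbind, lapply(names(metric_cols), function(m) {
    data.frame(subject_id = q$subject_id, sex = q$sex, age = q$age,
               group_label = q$roi, metric_name = m,
               value = q[[metric_cols[[m]]]])
  }))
  rownames(out) <- NULL
  out
}

#' Run the full group-statistics stage
#'
#' For each of the six metrics: a tissue-type ANOVA (GM vs WM), a region
#' ANOVA (the eight sub-regions), and Steel-Dwass all-pairs post-hoc
#' comparisons for both designs. Significance across the six metrics is
#' controlled with a Bonferroni-corrected alpha.
#'
#' @param quantification per subject x ROI table from [quantify_cohort()].
#' @param subjects data frame with `subject_id`, `sex`, `age`.
#' @param tissue_rois the two whole-tissue labels (default GM, WM).
#' @param family_alpha familywise alpha across metrics (default 0.05).
#' @return list with `anova_tissue`, `anova_region` (lists of `na_anova`),
#'   `posthoc_tissue`, `posthoc_region` (data frames with metric column),
#'   and `alpha` (the [bonferroni_alpha()] record).
#' @export
run_group_stats <- function(quantification, subjects,
                            tissue_rois = c("GM", "WM"),
                            family_alpha = 0.05) {
  tab <- cohort_table(quantification, subjects)
  metrics <- unique(tab$metric_name)
  alpha <- bonferroni_alpha(length(metrics), family_alpha)
  tissue_tab <- tab[tab$group_label %in% tissue_rois, ]
  region_tab <- tab[!tab$group_label %in% tissue_rois, ]

  # degenerate inputs (e.g. a zero-variance metric from a noiseless,
  # zero-spread simulation) are skipped with a warning, not fatal
  run_all <- function(sub) {
    if (nrow(sub) == 0) return(NULL)
    res <- setNames(lapply(metrics, function(m)
      tryCatch(run_anova(sub, m), error = function(e) {
        warning("ANOVA skipped for ", m, ": ", conditionMessage(e),
                call. = FALSE)
        NULL
      })), metrics)
    Filter(Negate(is.null), res)
  }
  posthoc_all <- function(sub) {
    if (nrow(sub) == 0) return(NULL)
    do.call(rbind, lapply(metrics, function(m) {
      d <- sub[sub$metric_name == m, ]
      res <- tryCatch(steel_dwass(split(d$value, d$group_label)),
                      error = function(e) {
                        warning("post-hoc skipped for ", m, ": ",
                                conditionMessage(e), call. = FALSE)
                        NULL
                      })
      if (is.null(res)) NULL else cbind(metric = m, as.data.frame(res))
    }))
  }
  list(anova_tissue = run_all(tissue_tab),
       anova_region = run_all(region_tab),
       posthoc_tissue = posthoc_all(tissue_tab),
       posthoc_region = posthoc_all(region_tab),
       alpha = alpha)
}
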