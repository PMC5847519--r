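make_cohort_table <- function(values_by_group, sexes = NULL, ages = NULL,
                              metric = "tsc") {
  n <- length(values_by_group[[1]])
  do.call(rbind, lapply(names(values_by_group), function(g) {
    data.frame(subject_id = sprintf("S%02d", seq_len(n)),
               sex = sexes %||% rep(c("female", "male"), length.out = n),
               age = ages %||% seq(20, 32, length.out = n),
               group_label = g, metric_name = metric,
               value = values_by_group[[g]])
  }))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("ANOVA F matches a hand-computed balanced two-factor oracle", {
  # balanced 2x2 (group x sex), 4 replicates per cell, additive model
  set.seed(21)
  cells <- expand.grid(g = c("GM", "WM"), sex = c("female", "male"),
                       rep = 1:4)
  mu <- c(GM = 10, WM = 13)
  eff <- c(female = 0, male = 1.5)
  cells$value <- mu[cells$g] + eff[cells$sex] + rnorm(nrow(cells), 0, 1)
  tab <- data.frame(subject_id = sprintf("S%02d", seq_len(nrow(cells))),
                    sex = cells$sex, age = 25, group_label = cells$g,
                    metric_name = "tsc", value = cells$value)
  res <- run_anova(tab, "tsc", covariates = "sex")

  # hand computation: balanced design, so Type II SS equal the classic
  # between-level sums of squares for each factor
  y <- cells$value; grand <- mean(y); n <- length(y)
  ss_g <- sum(tapply(y, cells$g, function(v) length(v) * (mean(v) - grand)^2))
  ss_s <- sum(tapply(y, cells$sex, function(v) length(v) * (mean(v) - grand)^2))
  sse <- sum((y - grand)^2) - ss_g - ss_s
  df_e <- n - 3
  expect_equal(res$terms$f[res$terms$term == "group_label"],
               (ss_g / 1) / (sse / df_e), tolerance = 1e-8)
  expect_equal(res$terms$f[res$terms$term == "sex"],
               (ss_s / 1) / (sse / df_e), tolerance = 1e-8)
  expect_equal(res$whole_model$f,
               ((ss_g + ss_s) / 2) / (sse / df_e), tolerance = 1e-8)
})

test_that("ANOVA degrees of freedom match the design", {
  set.seed(22)
  groups <- setNames(lapply(1:8, function(i) rnorm(13, i)), paste0("R", 1:8))
  tab <- make_cohort_table(groups)
  res <- run_anova(tab, "tsc")
  expect_equal(res$terms$df[res$terms$term == "group_label"], 7)
  expect_equal(res$terms$df[res$terms$term == "sex"], 1)
  expect_equal(res$terms$df[res$terms$term == "age"], 1)
  expect_equal(res$whole_model$df1, 9)
})

test_that("null and injected effects behave as expected", {
  set.seed(23)
  # identical group means: factor F near zero, far from significance
  v <- rnorm(13)
  tab0 <- make_cohort_table(list(GM = v, WM = v))
  res0 <- run_anova(tab0, "tsc")
  expect_lt(res0$terms$f[res0$terms$term == "group_label"], 1e-20)

  # large injected tissue effect at n = 13: survives the corrected alpha
  tab1 <- make_cohort_table(list(GM = rnorm(13, 47, 2.8),
                                 WM = rnorm(13, 38, 2.0)))
  res1 <- run_anova(tab1, "tsc")
  expect_lt(res1$terms$p[res1$terms$term == "group_label"],
            bonferroni_alpha(6)$alpha)
})

test_that("permuted labels give a null whole-model F", {
  set.seed(24)
  v <- rnorm(26, 40, 3)
  p_vals <- replicate(200, {
    g <- sample(rep(c("GM", "WM"), 13))
    tab <- make_cohort_table(split(v, g))
    run_anova(tab, "tsc")$whole_model$p
  })
  expect_gt(mean(p_vals < 0.05), 0.005)
  expect_lt(mean(p_vals < 0.05), 0.15)
})

test_that("steel_dwass handles symmetry, saturation and antisymmetry", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(steel_dwass(list(a = x, b = x))$z, 0)

  # complete separation of two n = 13 samples saturates the statistic
  sat <- steel_dwass(list(lo = 1:13, hi = 14:26))
  expect_equal(abs(sat$z), (260 - 175.5 - 0.5) / sqrt(13 * 13 * 27 / 12))
  expect_equal(round(abs(sat$z), 2), 4.31)

  set.seed(25)
  g <- list(a = rnorm(6), b = rnorm(7, 1), c = rnorm(5, -1))
  res_ab <- steel_dwass(g[c("a", "b")])
  res_ba <- steel_dwass(g[c("b", "a")])
  expect_equal(res_ab$z, -res_ba$z)

  expect_error(steel_dwass(list(a = 1:2, b = 1:5)), ">= 3")
  expect_error(steel_dwass(list(a = 1:5)), ">= 2 groups")
})

test_that("steel_dwass z matches a brute-force enumeration oracle on 3 vs 3", {
  cases <- list(
    list(x1 = c(1.2, 3.4, 2.2), x2 = c(0.5, 4.1, 5.0)),
    list(x1 = c(1, 2, 3), x2 = c(4, 5, 6)),
    list(x1 = c(1, 2, 2), x2 = c(2, 3, 4)),   # ties across groups
    list(x1 = c(5, 6, 9), x2 = c(1, 2, 3))
  )
  for (cs in cases) {
    z_pkg <- steel_dwass(list(a = cs$x1, b = cs$x2))$z
    z_oracle <- brute_force_pair_z(cs$x1, cs$x2)
    expect_equal(z_pkg, z_oracle, tolerance = 1e-12)
  }
})

test_that("with two groups the p-value is the Wilcoxon normal approximation", {
  set.seed(26)
  for (i in 1:20) {
    a <- rnorm(8 + i %% 5); b <- rnorm(10, 0.6)
    if (i %% 3 == 0) { a <- round(a, 1); b <- round(b, 1) }  # force ties
    p_sd <- steel_dwass(list(a = a, b = b))$p_adjusted
    p_w <- suppressWarnings(
      wilcox.test(a, b, exact = FALSE, correct = TRUE))$p.value
    expect_equal(p_sd, p_w, tolerance = 1e-6)
  }
})

test_that("bonferroni_alpha splits the familywise level", {
  b <- bonferroni_alpha(6, 0.05)
  expect_equal(b$alpha, 0.05 / 6)
  expect_equal(b$alpha_printed, 0.008)
  expect_equal(bonferroni_alpha(1)$alpha, 0.05)
  expect_equal(bonferroni_alpha(2)$alpha, 0.025)
})

test_that("run_group_stats assembles both designs", {
  set.seed(27)
  ds <- simulate_cohort(cohort_config(seed = 27, snr = 40))
  qc <- quantify_cohort(ds$curves, ds$phantom_curves)
  res <- run_group_stats(qc$quantification, ds$subjects)
  expect_equal(sort(names(res$anova_tissue)),
               sort(c("t2s", "t2l", "na_sf", "na_lf", "tsc", "ecf")))
  expect_equal(res$anova_region$tsc$terms$df[
    res$anova_region$tsc$terms$term == "group_label"], 7)
  # 8 regions -> 28 pairs per metric
  expect_equal(nrow(res$posthoc_region), 6 * 28)
  expect_equal(nrow(res$posthoc_tissue), 6)
  expect_equal(res$alpha$alpha_printed, 0.008)
})
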