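test_that("marginal slopes agree with per-group OLS on near-noise-free data", {
  tab <- simulate_metrics_cohort(n_per_group = 4, n_trials = 40,
                                 vigour_slope_sd = 0, fi_slope_sd = 0,
                                 mt_slope_sd = 0,
                                 vigour0_sd = 0, resid_vmax = 1e-4,
                                 seed = 2)
  tab$analysis_trial <- tab$trial
  fit <- suppressWarnings(fit_trial_lmm(tab, "vmax_mean"))
  sl <- marginal_slopes(fit, c("Reward", "Drug"))
  ols <- ols_group_slopes(tab, "vmax_mean")
  key <- c("NoRew:Ctrl" = "CtrlNR", "Rew:Ctrl" = "CtrlR",
           "NoRew:Halo" = "HaloNR", "Rew:Halo" = "HaloR")
  for (i in seq_len(nrow(sl)))
    expect_equal(sl$beta[i], unname(ols[key[[sl$group[i]]]]),
                 tolerance = 1e-6, label = sl$group[i])
})

test_that("marginal slopes match an independent marginal-trends routine", {
  skip_if_not_installed("emmeans")
  tab <- simulate_metrics_cohort(n_per_group = 6, n_trials = 40, seed = 3)
  tab$analysis_trial <- tab$trial
  fit <- suppressWarnings(fit_trial_lmm(tab, "fi_sum"))
  sl <- marginal_slopes(fit, c("Reward", "Drug"))
  em <- as.data.frame(suppressMessages(
    emmeans::emtrends(fit$model, ~ Reward * Drug, var = "Trial")))
  em$group <- paste0(em$Reward, ":", em$Drug)
  em <- em[match(sl$group, em$group), ]
  expect_equal(sl$beta, em$Trial.trend / fit$trial_scale, tolerance = 1e-8)
  expect_equal(sl$se, em$SE / fit$trial_scale, tolerance = 1e-8)
})

test_that("the model uses the stated reference coding and Satterthwaite df", {
  tab <- simulate_metrics_cohort(n_per_group = 4, n_trials = 30, seed = 4)
  tab$analysis_trial <- tab$trial
  fit <- suppressWarnings(fit_trial_lmm(tab, "vmax_mean"))
  d <- fit$data
  expect_equal(levels(d$Reward)[1], "NoRew")
  expect_equal(levels(d$Drug)[1], "Halo")
  expect_equal(levels(d$WM)[1], "low")
  cf <- fit$coefficients
  expect_equal(nrow(cf), 16) # full factorial of 4 two-level terms
  expect_true(all(c("estimate", "se", "df", "t", "p") %in% colnames(cf)))
  expect_true(all(is.finite(cf[, "df"])))
  expect_true(all(cf[, "df"] < nrow(tab))) # denominator df, not N
})

test_that("shifting the dv by a constant moves only the intercept", {
  tab <- simulate_metrics_cohort(n_per_group = 3, n_trials = 30, seed = 6)
  tab$analysis_trial <- tab$trial
  f1 <- suppressWarnings(fit_trial_lmm(tab, "vmax_mean"))
  tab$vmax_mean <- tab$vmax_mean + 100
  f2 <- suppressWarnings(fit_trial_lmm(tab, "vmax_mean"))
  e1 <- f1$coefficients[, "estimate"]
  e2 <- f2$coefficients[, "estimate"]
  expect_equal(unname(e2["(Intercept)"] - e1["(Intercept)"]), 100,
               tolerance = 1e-4)
  expect_equal(e1[names(e1) != "(Intercept)"],
               e2[names(e2) != "(Intercept)"], tolerance = 1e-4)
})

test_that("pairwise z-tests follow the closed form and Bonferroni count", {
  # identical slopes: z = 0, p = 1
  s0 <- data.frame(group = c("a", "b"), beta = c(1, 1), se = c(0.2, 0.2))
  z0 <- pairwise_slope_ztests(s0)
  expect_equal(z0$z, 0)
  expect_equal(z0$p, 1)
  # printed-CI oracle: beta 2.4 CI [1.0, 3.7] vs beta -0.46 CI [-1.76, 0.85]
  se1 <- ci_to_se(1.0, 3.7)
  se2 <- ci_to_se(-1.76, 0.85)
  s <- data.frame(group = c("CtrlR", "HaloR"), beta = c(2.4, -0.46),
                  se = c(se1, se2))
  z <- pairwise_slope_ztests(s)
  expect_equal(z$z, (2.4 + 0.46) / sqrt(se1^2 + se2^2))
  expect_equal(round(z$z, 2), 2.99)
  # four groups: six pairs, adjusted p = min(1, 6p)
  s4 <- data.frame(group = letters[1:4], beta = c(1, 2, 3, 4),
                   se = rep(0.5, 4))
  z4 <- pairwise_slope_ztests(s4)
  expect_equal(nrow(z4), 6)
  expect_equal(z4$p_bonferroni, pmin(1, z4$p * 6))
  expect_error(pairwise_slope_ztests(data.frame(group = c("a", "b"),
                                                beta = c(1, 2),
                                                se = c(0, 1))), "positive")
})

test_that("adjusted p-values are monotone in raw p-values", {
  set.seed(8)
  p <- runif(12)
  bonf <- pmin(1, p * length(p))
  fdr <- p.adjust(p, "BH")
  o <- order(p)
  expect_true(all(diff(bonf[o]) >= 0))
  expect_true(all(diff(fdr[o]) >= 0))
})
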