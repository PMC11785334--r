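# Mixed-model analysis of training trials: full-factorial fixed effects of
# Reward x Drug x WM x TrialNumber with a random intercept and random trial
# slope per participant, fitted by REML with Satterthwaite degrees of
# freedom.

#' Fit the trial-level linear mixed model
#'
#' Fits `dv ~ Reward * Drug * WM * Trial + (Trial | Participant)` by REML.
#' Factors use treatment coding with NoReward, haloperidol and low WM as
#' reference levels. Term tests use the Satterthwaite method. If the maximal
#' model fails to converge (or is singular), the random slope is dropped and
#' the fallback is flagged in the result, never silent.
#'
#' Trial number enters the model divided by `trial_scale` (default 100),
#' purely for numerical conditioning of the random-slope covariance; the
#' coefficient table is therefore in dv-units per `trial_scale` trials,
#' while [marginal_slopes()] reports per-trial slopes.
#'
#' @param table Analysis trial table: one row per retained trial with
#'   columns `participant_id`, `reward_group` ("Rew"/"NoRew"), `drug_group`
#'   ("Halo"/"Ctrl"), `wm_class` ("high"/"low"), a trial-number column and
#'   the dependent variable.
#' @param dv Name of the dependent variable column (e.g. `"vmax_mean"`,
#'   `"fi_sum"`, `"mt"`).
#' @param trial_col Name of the trial-number column.
#' @param trial_scale Divisor applied to the trial number before fitting.
#' @return Object of class `reach_lmm`: list with `model` (the fitted
#'   `lmerModLmerTest`), `coefficients` (estimates, SE, Satterthwaite df, t,
#'   p per fixed term), `ranef_var`, `fit_info` (REML criterion, AIC, BIC),
#'   `dv`, `fallback` (`"none"` or `"intercept_only"`), `converged`.
#' @export
fit_trial_lmm <- function(table, dv, trial_col = "analysis_trial",
                          trial_scale = 100) {
  need <- c("participant_id", "reward_group", "drug_group", "wm_class",
            trial_col, dv)
  miss <- setdiff(need, names(table))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  d <- data.frame(
    y = table[[dv]],
    Reward = stats::relevel(factor(table$reward_group,
                                   levels = c("NoRew", "Rew")), "NoRew"),
    Drug = stats::relevel(factor(table$drug_group,
                                 levels = c("Halo", "Ctrl")), "Halo"),
    WM = stats::relevel(factor(table$wm_class,
                               levels = c("low", "high")), "low"),
    Trial = as.numeric(table[[trial_col]]) / trial_scale,
    Participant = factor(table$participant_id))

  ctrl <- lme4::lmerControl(optimizer = "bobyqa",
                            optCtrl = list(maxfun = 1e5))
  fallback <- "none"
  fit <- suppressMessages(suppressWarnings(
    lmerTest::lmer(y ~ Reward * Drug * WM * Trial + (Trial | Participant),
                   data = d, REML = TRUE, control = ctrl)))
  if (!is.null(fit@optinfo$conv$lme4$code)) {
    # documented fallback: drop the random slope, flagged, never silent
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(y ~ Reward * Drug * WM * Trial + (1 | Participant),
                     data = d, REML = TRUE, control = ctrl)))
    fallback <- "intercept_only"
    warning("random trial slope dropped: maximal model did not converge")
  }
  cf <- stats::coef(summary(fit))
  colnames(cf) <- c("estimate", "se", "df", "t", "p")
  vc <- as.data.frame(lme4::VarCorr(fit))
  structure(list(model = fit,
                 coefficients = cf,
                 ranef_var = vc,
                 fit_info = c(REML = stats::deviance(fit, REML = TRUE),
                              AIC = stats::AIC(fit), BIC = stats::BIC(fit)),
                 dv = dv, trial_col = trial_col, trial_scale = trial_scale,
                 fallback = fallback,
                 converged = is.null(fit@optinfo$conv$lme4$code),
                 data = d),
            class = "reach_lmm")
}

#' @export
print.reach_lmm <- function(x, ...) {
  cat(sprintf("trial-level LMM for %s (REML, Satterthwaite df)%s\n", x$dv,
              if (x$fallback != "none")
                sprintf(" [fallback: %s]", x$fallback) else ""))
  stats::printCoefmat(x$coefficients, digits = 3, P.values = TRUE,
                      has.Pvalue = TRUE)
  invisible(x)
}

#' @export
summary.reach_lmm <- function(object, ...) {
  print(object)
  cat("\nrandom effects:\n")
  print(object$ranef_var, digits = 3)
  cat(sprintf("\nREML %.1f, AIC %.1f, BIC %.1f\n", object$fit_info["REML"],
              object$fit_info["AIC"], object$fit_info["BIC"]))
  invisible(object)
}

#' Marginal per-trial slopes by group
#'
#' The marginal effect of trial number for each level combination of the
#' requested grouping factors: the linear combination of fixed effects that
#' gives that group's slope of the dependent variable across trials, with
#' factors not in the grouping averaged over (equal weights). Standard
#' errors come from the corresponding quadratic form of the fixed-effect
#' covariance matrix; 95% CIs are beta +/- 1.96 SE.
#'
#' @param fit A [fit_trial_lmm()] result.
#' @param grouping Character vector of factor names among `"Reward"`,
#'   `"Drug"`, `"WM"`.
#' @return data.frame of class `slope_estimates`: one row per group with
#'   `beta`, `se`, `ci_lo`, `ci_hi`, `z`, `p` (Wald test of slope = 0).
#' @export
marginal_slopes <- function(fit, grouping = c("Reward", "Drug")) {
  all_factors <- c("Reward", "Drug", "WM")
  if (!all(grouping %in% all_factors))
    stop("grouping must be among ", paste(all_factors, collapse = ", "))
  d <- fit$data
  levs <- lapply(all_factors, function(f) levels(d[[f]]))
  names(levs) <- all_factors
  grid <- expand.grid(levs, stringsAsFactors = FALSE)
  tt <- stats::delete.response(stats::terms(fit$model))
  mm_at <- function(trial) {
    nd <- grid
    nd$Trial <- trial
    for (f in all_factors) nd[[f]] <- factor(nd[[f]], levels = levs[[f]])
    stats::model.matrix(tt, nd)
  }
  dmat <- mm_at(1) - mm_at(0) # per-row derivative wrt the fitted Trial term
  key <- interaction(grid[grouping], sep = ":", drop = TRUE)
  V <- as.matrix(stats::vcov(fit$model))
  b <- lme4::fixef(fit$model)
  # rank-deficient designs (empty cells) drop fixed-effect columns
  dmat <- dmat[, names(b), drop = FALSE]
  sc <- if (is.null(fit$trial_scale)) 1 else fit$trial_scale
  out <- do.call(rbind, lapply(levels(key), function(kk) {
    cvec <- colMeans(dmat[key == kk, , drop = FALSE])
    beta <- sum(cvec * b) / sc
    se <- sqrt(drop(t(cvec) %*% V %*% cvec)) / sc
    data.frame(group = kk, beta = beta, se = se,
               ci_lo = beta - 1.96 * se, ci_hi = beta + 1.96 * se,
               z = beta / se, p = 2 * stats::pnorm(-abs(beta / se)))
  }))
  rownames(out) <- NULL
  class(out) <- c("slope_estimates", "data.frame")
  out
}

#' Pairwise z-tests between group slopes
#'
#' Compares every pair of marginal slopes with
#' `z = (beta1 - beta2) / sqrt(se1^2 + se2^2)`, two-sided normal p-values,
#' Bonferroni-corrected over the number of pairs.
#'
#' @param slopes A `slope_estimates` data.frame (or any data.frame with
#'   `group`, `beta`, `se`).
#' @return data.frame: `group1`, `group2`, `z`, `p`, `p_bonferroni`.
#' @export
pairwise_slope_ztests <- function(slopes) {
  stopifnot(nrow(slopes) >= 2)
  if (any(slopes$se <= 0)) stop("slope standard errors must be positive")
  pr <- utils::combn(nrow(slopes), 2)
  out <- data.frame(
    group1 = slopes$group[pr[1, ]],
    group2 = slopes$group[pr[2, ]],
    z = (slopes$beta[pr[1, ]] - slopes$beta[pr[2, ]]) /
      sqrt(slopes$se[pr[1, ]]^2 + slopes$se[pr[2, ]]^2))
  out$p <- 2 * stats::pnorm(-abs(out$z))
  out$p_bonferroni <- pmin(1, out$p * nrow(out))
  out
}

#' Convert a printed 95% confidence interval to a standard error
#'
#' Assumes a normal interval: `se = width / (2 * 1.96)`.
#'
#' @param ci_lo,ci_hi Interval bounds.
#' @return Standard error.
#' @export
ci_to_se <- function(ci_lo, ci_hi) (ci_hi - ci_lo) / (2 * stats::qnorm(0.975))
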