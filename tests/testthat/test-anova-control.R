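test_that("working-memory median split assigns classes around the cohort median", {
  s <- data.frame(participant_id = c("a", "b"), score = c(40, 60))
  cl <- wm_median_split(s)
  expect_equal(cl$wm_class, c("low", "high"))
  expect_equal(attr(cl, "cohort_median"), 50)
  # ties at the median go high by default, low when configured
  s2 <- data.frame(participant_id = letters[1:4], score = rep(55, 4))
  expect_true(all(wm_median_split(s2)$wm_class == "high"))
  expect_true(all(wm_median_split(s2, ties = "low")$wm_class == "low"))
  # full-cohort split: 44 below the median out of 92 gives a 44/48 split
  set.seed(3)
  sc <- c(runif(44, 20, 59), rep(60, 4), runif(44, 61, 100))
  big <- data.frame(participant_id = sprintf("p%02d", 1:92), score = sc)
  cl2 <- wm_median_split(big)
  expect_equal(sum(cl2$wm_class == "low"), 44)
  expect_equal(sum(cl2$wm_class == "high"), 48)
})

test_that("response accuracy counts Go and No-Go per stimulus association", {
  # hand-built 40-trial log: 7/10 Go per reward rune, 6/10 No-Go per loss rune
  log <- data.frame(
    stim_type = rep(c("reward", "loss"), each = 20),
    go = c(rep(c(TRUE, FALSE), c(7, 3)), rep(c(TRUE, FALSE), c(7, 3)),
           rep(c(FALSE, TRUE), c(6, 4)), rep(c(FALSE, TRUE), c(6, 4))))
  ra <- response_accuracy(log)
  expect_equal(ra$learn_plus, 70)
  expect_equal(ra$learn_minus, 60)
  expect_equal(ra$delta, 10)
  # always-Go responder
  log$go <- TRUE
  ra2 <- response_accuracy(log)
  expect_equal(ra2$learn_plus, 100)
  expect_equal(ra2$learn_minus, 0)
})

test_that("Go/NoGo simulation respects the task structure", {
  p <- quiet_profile()
  log <- simulate_gonogo(p, sim_config(), seed = 5)
  expect_equal(nrow(log), 40)
  expect_equal(as.integer(table(log$stimulus)), rep(10L, 4))
  expect_true(all(is.na(log$outcome[!log$go])))
  expect_true(all(log$outcome[log$go] %in% c(-1, 1)))
  # degenerate always-Go policy: accuracy on loss stimuli is zero
  cfg <- sim_config(gonogo = list(p_win_reward = 0.8, p_win_loss = 0.2,
                                  lr_win = 0.3, lr_loss = 0.3,
                                  beta = 0, go_bias = 100))
  ra <- response_accuracy(simulate_gonogo(p, cfg, seed = 6))
  expect_equal(ra$learn_minus, 0)
  expect_equal(ra$learn_plus, 100)
})

test_that("asymmetric learning rates produce the Learn+/Learn- asymmetry", {
  cfg <- sim_config(gonogo = list(p_win_reward = 0.8, p_win_loss = 0.2,
                                  lr_win = 0.5, lr_loss = 0.05,
                                  beta = 4, go_bias = 0.3))
  p <- quiet_profile()
  deltas <- vapply(1:200, function(i) {
    response_accuracy(simulate_gonogo(p, cfg, seed = i))$delta
  }, numeric(1))
  expect_gt(mean(deltas), 0) # Learn+ exceeds Learn- in expectation
})

test_that("verbal memory simulation scales with ability and length", {
  p <- quiet_profile()
  vw <- simulate_vwm(p, seed = 4)
  expect_equal(nrow(vw$trials), 60)
  expect_equal(as.integer(table(vw$trials$length)), rep(12L, 5))
  # ceiling: extreme ability is always correct
  p_inf <- participant_profile("g", "Rew", "Ctrl", wm_true = 50)
  vw_inf <- simulate_vwm(p_inf, seed = 4)
  expect_equal(vw_inf$score, 100)
  expect_true(all(vw_inf$by_length == 100))
  # latent ability ranks with the 7-9 score across a cohort
  wm_true <- seq(-2, 2, length.out = 100)
  scores <- vapply(seq_along(wm_true), function(i) {
    simulate_vwm(participant_profile(i, "Rew", "Ctrl",
                                     wm_true = wm_true[i]),
                 seed = 300 + i)$score
  }, numeric(1))
  expect_gt(cor(wm_true, scores, method = "spearman"), 0.5)
})

test_that("post-assessment medians match a direct median oracle", {
  set.seed(21)
  ids <- sprintf("p%02d", 1:16)
  grp <- rep(c("Rew", "NoRew"), each = 8)
  drg <- rep(c("Halo", "Ctrl"), times = 8)
  tab <- do.call(rbind, lapply(seq_along(ids), function(i) {
    data.frame(participant_id = ids[i], reward_group = grp[i],
               drug_group = drg[i], wm_class = "low",
               phase = rep(c("PostRew", "PostNoRew"), each = 9),
               vmax_mean = rnorm(18, 20, 3))
  }))
  res <- post_assessment_anova(tab, "vmax_mean")
  for (i in sample(nrow(res$medians), 5)) {
    row <- res$medians[i, ]
    raw <- tab$vmax_mean[tab$participant_id == row$participant_id &
                           tab$phase == row$timepoint]
    expect_equal(row$dv_median, median(raw))
  }
  expect_equal(nrow(res$normality), 2)
  expect_true(all(c("term", "df", "F", "p") %in% names(res$anova)))
  expect_true(all(res$followups$p_fdr >= res$followups$p - 1e-12,
                  na.rm = TRUE))
  # exchangeable data: between factors show no effect at this seed
  betw <- res$anova[res$anova$term %in% c("reward_group", "drug_group"), ]
  expect_true(all(betw$p > 0.05))
})

test_that("a timepoint shift in one group drives the three-way interaction", {
  detect <- 0
  for (s in 1:20) {
    set.seed(1000 + s)
    n <- 23
    rows <- list()
    for (g in c("HaloR", "CtrlR", "HaloNR", "CtrlNR")) {
      rg <- if (grepl("NR$", g)) "NoRew" else "Rew"
      dg <- if (grepl("^Halo", g)) "Halo" else "Ctrl"
      for (k in 1:n) {
        base <- rnorm(1, 20, 2)
        shift <- if (g == "HaloR") 1.5 else 0
        rows[[length(rows) + 1]] <- data.frame(
          participant_id = paste0(g, k), reward_group = rg,
          drug_group = dg, wm_class = sample(c("low", "high"), 1),
          phase = rep(c("PostRew", "PostNoRew"), each = 5),
          vmax_mean = c(rnorm(5, base + shift, 1), rnorm(5, base, 1)))
      }
    }
    res <- post_assessment_anova(do.call(rbind, rows), "vmax_mean")
    p3 <- res$anova$p[res$anova$term ==
                        "reward_group:drug_group:timepoint"]
    if (length(p3) == 1 && is.finite(p3) && p3 < 0.05) detect <- detect + 1
  }
  expect_gte(detect, 18) # >= 90% detection at full-cohort n
})

test_that("the positive-control analysis flags the drug-by-feedback asymmetry", {
  set.seed(14)
  n <- 22
  ra <- data.frame(
    participant_id = sprintf("p%02d", 1:(2 * n)),
    drug_group = rep(c("Halo", "Ctrl"), each = n),
    wm_class = "low",
    learn_plus = c(rnorm(n, 80, 8), rnorm(n, 70, 8)),
    learn_minus = c(rnorm(n, 55, 8), rnorm(n, 70, 8)))
  res <- positive_control_anova(ra, "low")
  inter <- res$anova[res$anova$term == "drug_group:feedback", ]
  expect_lt(inter$p, 0.05)
  expect_lt(res$wilcoxon$p, 0.05)
  expect_equal(res$n, 2 * n)
})
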