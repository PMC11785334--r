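# Median-based mixed ANOVA for the post assessments, plus the
# positive-control analyses (working-memory median split, Go/NoGo response
# accuracy and the Drug x Feedback mixed ANOVA).

#' Working-memory median split
#'
#' Classifies participants as low or high working memory by the cohort
#' median of their verbal-memory score (% correct over the three hardest
#' array lengths, 7-9). Scores strictly below the median are low; ties at
#' the median go high (configurable).
#'
#' @param scores data.frame with `participant_id` and `score` (%).
#' @param ties `"high"` (default) or `"low"`: class for scores equal to the
#'   median.
#' @return data.frame: `participant_id`, `score`, `wm_class`, plus
#'   attribute `cohort_median`.
#' @export
wm_median_split <- function(scores, ties = c("high", "low")) {
  ties <- match.arg(ties)
  stopifnot(nrow(scores) >= 2)
  med <- stats::median(scores$score)
  low <- if (ties == "high") scores$score < med else scores$score <= med
  out <- data.frame(participant_id = scores$participant_id,
                    score = scores$score,
                    wm_class = ifelse(low, "low", "high"))
  attr(out, "cohort_median") <- med
  out
}

#' Go/NoGo response accuracy
#'
#' Learning-phase accuracy split by feedback association: `learn_plus` is
#' the percentage of Go responses on reward-associated stimuli (positive
#' feedback learning), `learn_minus` the percentage of No-Go responses on
#' loss-associated stimuli (negative feedback learning).
#'
#' @param log A Go/NoGo trial log as from [simulate_gonogo()]: columns
#'   `stim_type` ("reward"/"loss") and `go` (logical).
#' @return List of class `response_accuracy`: `learn_plus`, `learn_minus`,
#'   `delta` (both %, delta = plus - minus).
#' @export
response_accuracy <- function(log) {
  stopifnot(all(c("stim_type", "go") %in% names(log)))
  lp <- 100 * mean(log$go[log$stim_type == "reward"])
  lm_ <- 100 * mean(!log$go[log$stim_type == "loss"])
  structure(list(learn_plus = lp, learn_minus = lm_, delta = lp - lm_),
            class = "response_accuracy")
}

#' @export
print.response_accuracy <- function(x, ...) {
  cat(sprintf("response accuracy: Learn+ %.1f%%, Learn- %.1f%% (delta %.1f)\n",
              x$learn_plus, x$learn_minus, x$delta))
  invisible(x)
}

# Mixed (split-plot) ANOVA via aov() with an Error stratum for the within
# factor. One row per participant x within-level.
mixed_anova <- function(data, dv, between, within, id = "participant_id") {
  for (f in c(between, within, id)) data[[f]] <- factor(data[[f]])
  # between factors constant in the data carry no information
  between <- between[vapply(between, function(f)
    nlevels(data[[f]]) >= 2, logical(1))]
  if (!length(between)) stop("no between factor with 2+ levels")
  rhs <- paste(paste(c(between, within), collapse = " * "))
  form <- stats::as.formula(
    sprintf("%s ~ %s + Error(%s/%s)", dv, rhs, id, within))
  fit <- stats::aov(form, data = data)
  sm <- summary(fit)
  tabs <- lapply(sm, function(s) as.data.frame(s[[1]]))
  tab <- do.call(rbind, tabs)
  tab <- tab[!grepl("Residuals", rownames(tab)), , drop = FALSE]
  names(tab) <- c("df", "sum_sq", "mean_sq", "F", "p")[seq_along(tab)]
  tab$term <- trimws(sub(".*\\.", "", rownames(tab)))
  rownames(tab) <- NULL
  list(table = tab[, c("term", "df", "F", "p")], fit = fit)
}

cohens_d <- function(x, y) {
  sp <- sqrt(((length(x) - 1) * stats::var(x) +
                (length(y) - 1) * stats::var(y)) /
               (length(x) + length(y) - 2))
  (mean(x) - mean(y)) / sp
}

#' Post-assessment mixed ANOVA with Wilcoxon follow-ups
#'
#' Analyses the two post-assessment phases of one day. Trial-level data are
#' first reduced to per-participant medians per Timepoint (post-Rew vs
#' post-NoRew) because the trial distributions are typically non-normal
#' (one-sample Kolmogorov-Smirnov checks are reported per Timepoint). The
#' medians enter a mixed ANOVA with Reward, Drug and WM as between factors
#' and Timepoint within. Follow-up Wilcoxon rank-sum tests compare the
#' per-participant post-Rew minus post-NoRew difference between group
#' pairings, corrected by false discovery rate, with Cohen's d effect
#' sizes.
#'
#' @param table Post-phase trial table: columns `participant_id`,
#'   `reward_group`, `drug_group`, `wm_class`, `phase` ("PostRew"/
#'   "PostNoRew") and the dependent variable.
#' @param dv Dependent-variable column name.
#' @param pairings `"adjacent"` (the 4 pairings differing in one factor) or
#'   `"all"` (all 6 group pairs).
#' @return Object of class `post_anova`: `medians` (per participant x
#'   Timepoint), `normality` (KS tests), `anova` (term table), `followups`
#'   (Wilcoxon z, p, FDR-adjusted p, Cohen's d per pairing).
#' @export
post_assessment_anova <- function(table, dv,
                                  pairings = c("adjacent", "all")) {
  pairings <- match.arg(pairings)
  stopifnot(all(c("participant_id", "reward_group", "drug_group",
                  "wm_class", "phase", dv) %in% names(table)))
  ph <- unique(table$phase)
  if (!all(c("PostRew", "PostNoRew") %in% ph))
    stop("both post phases (PostRew, PostNoRew) must be present")
  tab <- table[table$phase %in% c("PostRew", "PostNoRew"), , drop = FALSE]
  agg <- stats::aggregate(tab[[dv]],
                          by = list(participant_id = tab$participant_id,
                                    reward_group = tab$reward_group,
                                    drug_group = tab$drug_group,
                                    wm_class = tab$wm_class,
                                    timepoint = tab$phase),
                          FUN = stats::median)
  names(agg)[names(agg) == "x"] <- "dv_median"
  if (any(table(agg$participant_id) != 2))
    stop("each participant needs both post phases")

  normality <- do.call(rbind, lapply(split(tab[[dv]], tab$phase),
                                     function(x) {
    x <- x[is.finite(x)]
    ks <- suppressWarnings(stats::ks.test(scale(x), "pnorm"))
    data.frame(statistic = unname(ks$statistic), p = ks$p.value)
  }))
  normality$timepoint <- rownames(normality)
  rownames(normality) <- NULL

  an <- mixed_anova(agg, "dv_median",
                    between = c("reward_group", "drug_group", "wm_class"),
                    within = "timepoint")

  wide <- stats::reshape(agg[, c("participant_id", "reward_group",
                                 "drug_group", "timepoint", "dv_median")],
                         idvar = "participant_id",
                         timevar = "timepoint", direction = "wide",
                         v.names = "dv_median")
  wide$delta <- wide$dv_median.PostRew - wide$dv_median.PostNoRew
  wide$group <- group_key(wide$reward_group, wide$drug_group)
  pair_set <- if (pairings == "adjacent")
    list(c("HaloR", "CtrlR"), c("HaloNR", "CtrlNR"),
         c("HaloR", "HaloNR"), c("CtrlR", "CtrlNR"))
  else utils::combn(c("HaloR", "CtrlR", "HaloNR", "CtrlNR"), 2,
                    simplify = FALSE)
  fu <- do.call(rbind, lapply(pair_set, function(pp) {
    x <- wide$delta[wide$group == pp[1]]
    y <- wide$delta[wide$group == pp[2]]
    if (!length(x) || !length(y))
      return(data.frame(group1 = pp[1], group2 = pp[2], W = NA, p = NA,
                        d = NA))
    wt <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
    data.frame(group1 = pp[1], group2 = pp[2],
               W = unname(wt$statistic), p = wt$p.value,
               d = cohens_d(x, y))
  }))
  fu$p_fdr <- stats::p.adjust(fu$p, method = "BH")
  structure(list(medians = agg, normality = normality, anova = an$table,
                 followups = fu, dv = dv),
            class = "post_anova")
}

#' @export
print.post_anova <- function(x, ...) {
  cat(sprintf("post-assessment mixed ANOVA on per-participant medians of %s\n",
              x$dv))
  print(x$anova, digits = 3, row.names = FALSE)
  cat("\nWilcoxon follow-ups on post-Rew - post-NoRew (FDR-corrected):\n")
  print(x$followups, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Positive-control analysis of Go/NoGo accuracy
#'
#' Mixed ANOVA of response accuracy with Drug as the between factor and
#' Feedback Condition (positive vs negative feedback learning) within,
#' run separately for low and high working-memory participants; Wilcoxon
#' rank-sum comparison of the Learn+ minus Learn- difference between drug
#' groups.
#'
#' @param ra_table data.frame: `participant_id`, `drug_group`, `wm_class`,
#'   `learn_plus`, `learn_minus` (%).
#' @param wm_class Which WM class to analyse (`"low"`, `"high"` or
#'   `"all"`).
#' @return List: `anova` (term table), `wilcoxon` (delta comparison),
#'   `n`.
#' @export
positive_control_anova <- function(ra_table, wm_class = "low") {
  d <- if (wm_class == "all") ra_table
       else ra_table[ra_table$wm_class == wm_class, , drop = FALSE]
  if (nrow(d) < 4) stop("too few participants for the positive control")
  long <- rbind(
    data.frame(participant_id = d$participant_id,
               drug_group = d$drug_group, feedback = "positive",
               ra = d$learn_plus),
    data.frame(participant_id = d$participant_id,
               drug_group = d$drug_group, feedback = "negative",
               ra = d$learn_minus))
  an <- mixed_anova(long, "ra", between = "drug_group", within = "feedback")
  delta <- d$learn_plus - d$learn_minus
  wt <- suppressWarnings(
    stats::wilcox.test(delta[d$drug_group == "Halo"],
                       delta[d$drug_group == "Ctrl"], exact = FALSE))
  list(anova = an$table,
       wilcoxon = data.frame(W = unname(wt$statistic), p = wt$p.value),
       n = nrow(d))
}
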