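#' Quality filtering of a trial-level dataset
#'
#' A participant's entire dataset is excluded when they failed to choose the
#' mutually more profitable option in at least 2 of the 6 control trials, or
#' when their mean decision-phase response time is below 0.5 s. Practice and
#' control trials are then dropped from the analysis table.
#'
#' @param trials trial-level data.frame from [simulate_study()] (or
#'   [read_trials()]).
#' @return List with `data` (the clean analysis table) and `qc` (one row per
#'   participant: control failures, mean RT, exclusion flag and reason).
#'   When the dataset contains no control trials the control criterion is
#'   skipped and flagged in attribute `"qc_skipped"`.
#' @export
apply_quality_filters <- function(trials) {
  stopifnot(all(c("participant_id", "is_control", "decision") %in%
                  names(trials)))
  dec <- trials[is.na(trials$phase) | trials$phase != "practice", ]
  ctrl <- dec[dec$is_control %in% TRUE, ]
  no_controls <- nrow(ctrl) == 0
  if (no_controls) warning("no control trials found; control QC skipped")

  ids <- unique(trials$participant_id)
  failures <- setNames(rep(0L, length(ids)), ids)
  if (!no_controls) {
    # the dominant option is the one weakly better for BOTH players
    opt1_dom <- ctrl$points_self_opt1 >= ctrl$points_self_opt2 &
      ctrl$points_other_opt1 >= ctrl$points_other_opt2
    dominant <- ifelse(opt1_dom, "favour_self", "favour_other")
    fail <- ctrl$decision != dominant
    tab <- tapply(fail, ctrl$participant_id, sum)
    failures[names(tab)] <- as.integer(tab)
  }
  mean_rt <- vapply(ids, function(id) {
    r <- dec$rt_s[dec$participant_id == id]
    if (all(is.na(r))) NA_real_ else mean(r, na.rm = TRUE)
  }, numeric(1))

  excluded <- failures >= 2 | (!is.na(mean_rt) & mean_rt < 0.5)
  reason <- ifelse(failures >= 2, "control_failures",
                   ifelse(!is.na(mean_rt) & mean_rt < 0.5, "fast_rt", ""))
  qc <- data.frame(participant_id = ids, control_failures = failures,
                   mean_rt = mean_rt, excluded = excluded, reason = reason,
                   stringsAsFactors = FALSE, row.names = NULL)

  keep <- !(dec$participant_id %in% ids[excluded]) & !dec$is_control
  out <- list(data = dec[keep, , drop = FALSE], qc = qc)
  attr(out, "qc_skipped") <- no_controls
  out
}

# tidy fixed-effect table from a (g)lmer or glm fit
.glmm_result <- function(fit, model_name) {
  co <- coef(summary(fit))
  res <- data.frame(term = rownames(co), estimate = co[, 1], se = co[, 2],
                    z = co[, 3], p = co[, 4], model = model_name,
                    n = stats::nobs(fit), stringsAsFactors = FALSE,
                    row.names = NULL)
  conv <- TRUE
  singular <- FALSE
  if (inherits(fit, "merMod")) {
    conv <- length(fit@optinfo$conv$lme4$messages) == 0
    singular <- lme4::isSingular(fit)
  }
  attr(res, "converged") <- conv
  attr(res, "singular") <- singular
  res
}

.prep_factors <- function(d) {
  d$conflict_degree <- factor(d$conflict_degree,
                              levels = c("aligned", "conflict"))
  d$fairness_domain <- factor(d$fairness_domain,
                              levels = c("compensation", "punishment"))
  d$incentive <- d$incentive_level / 100 # coded 0-5, one unit = 100 points
  d
}

#' Confirmatory logistic mixed model
#'
#' Fits `response ~ conflict_degree * fairness_domain +
#' conflict_degree * incentive + (1 | participant_id)` by Laplace-
#' approximate maximum likelihood on the fairness-partner trials of the
#' QC-filtered analysis table. Incentive level enters in units of 100 points
#' (coded 0--5), so its coefficient is a log-odds change per 100 points.
#'
#' @param data clean analysis table from [apply_quality_filters()].
#' @param nAGQ passed to [lme4::glmer()] (0 gives a faster, slightly cruder
#'   fit).
#' @return Data.frame of fixed effects (`term`, `estimate`, `se`, `z`, `p`,
#'   `model`, `n`) with attributes `converged` and `singular`.
#' @export
fit_confirmatory_glmm <- function(data, nAGQ = 1) {
  d <- .prep_factors(data[data$partner == "fairness_partner", ])
  fit <- lme4::glmer(
    response ~ conflict_degree * fairness_domain +
      conflict_degree * incentive + (1 | participant_id),
    data = d, family = stats::binomial, nAGQ = nAGQ)
  .glmm_result(fit, "confirmatory")
}

#' Manipulation-check logistic mixed models
#'
#' Three model families on the QC-filtered table (both partners included):
#' * `partner_conflict` — per fairness domain,
#'   `response ~ partner * conflict_degree` with a random slope over the
#'   distribution pairing and a random intercept per participant; a singular
#'   random-slope fit is refitted with an intercept-only random structure
#'   and flagged.
#' * `domain_partner` — `favour_other ~ fairness_domain * partner` with a
#'   random intercept.
#' * `incentive_type` — `favour_other ~ fairness_domain * incentive_type`
#'   (the group's incentivised decision type) with a random intercept.
#'
#' @param data clean analysis table from [apply_quality_filters()].
#' @param nAGQ passed to [lme4::glmer()].
#' @return Named list of fixed-effect tables (see [fit_confirmatory_glmm()]).
#' @export
fit_manipulation_glmms <- function(data, nAGQ = 1) {
  d <- .prep_factors(data)
  d$partner <- factor(d$partner, levels = c("baseline", "fairness_partner"))
  d$favour_other <- as.integer(d$decision == "favour_other")
  d$incentive_type <- vapply(seq_len(nrow(d)), function(i) {
    group_condition(as.character(d$fairness_domain[i]),
                    as.character(d$conflict_degree[i]))$incentivized_decision
  }, character(1))
  d$incentive_type <- factor(d$incentive_type,
                             levels = c("favour_self", "favour_other"))
  out <- list()
  for (dom in levels(droplevels(d$fairness_domain))) {
    dd <- d[d$fairness_domain == dom, ]
    fit <- suppressMessages(lme4::glmer(
      response ~ partner * conflict_degree + (1 + pairing | participant_id),
      data = dd, family = stats::binomial, nAGQ = nAGQ))
    if (lme4::isSingular(fit)) {
      fit <- lme4::glmer(response ~ partner * conflict_degree +
                           (1 | participant_id),
                         data = dd, family = stats::binomial, nAGQ = nAGQ)
      res <- .glmm_result(fit, paste0("partner_conflict_", dom))
      attr(res, "random_slope_dropped") <- TRUE
    } else {
      res <- .glmm_result(fit, paste0("partner_conflict_", dom))
      attr(res, "random_slope_dropped") <- FALSE
    }
    out[[paste0("partner_conflict_", dom)]] <- res
  }
  fit2 <- lme4::glmer(favour_other ~ fairness_domain * partner +
                        (1 | participant_id),
                      data = d, family = stats::binomial, nAGQ = nAGQ)
  out$domain_partner <- .glmm_result(fit2, "domain_partner")
  fit3 <- lme4::glmer(favour_other ~ fairness_domain * incentive_type +
                        (1 | participant_id),
                      data = d, family = stats::binomial, nAGQ = nAGQ)
  out$incentive_type <- .glmm_result(fit3, "incentive_type")
  out
}

#' Correlations between behaviour and trait scores
#'
#' Correlates the per-participant congruent-choice rate with each of the
#' five trait scales, separately per experimental group. P-values are
#' reported uncorrected and Bonferroni-adjusted for the 5 scales tested
#' within each group (adjusted p = 5 x uncorrected, capped at 1).
#'
#' @param participants participant-level table from [simulate_study()]
#'   (columns `group`, `congruent_rate` and the five trait scales).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data.frame with columns `group`, `scale`, `r`, `p`,
#'   `p_bonferroni`, `n`. Zero-variance traits yield `NA` correlations.
#' @export
trait_correlations <- function(participants, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  scales <- c("anger", "altruism", "js_observer", "js_victim",
              "js_perpetrator")
  stopifnot(all(c("group", "congruent_rate", scales) %in% names(participants)))
  rows <- list()
  for (g in unique(participants$group)) {
    d <- participants[participants$group == g, ]
    if (nrow(d) < 3) stop("at least 3 participants per group are required")
    for (sc in scales) {
      x <- d[[sc]]; y <- d$congruent_rate
      if (sd(x) < .Machine$double.eps || sd(y) < .Machine$double.eps) {
        rows[[length(rows) + 1]] <- data.frame(
          group = g, scale = sc, r = NA_real_, p = NA_real_,
          p_bonferroni = NA_real_, n = nrow(d), stringsAsFactors = FALSE)
        next
      }
      ct <- cor.test(x, y, method = method, exact = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        group = g, scale = sc, r = unname(ct$estimate), p = ct$p.value,
        p_bonferroni = min(1, length(scales) * ct$p.value), n = nrow(d),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
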