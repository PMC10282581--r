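#' Configuration of the simulation-based power analysis
#'
#' Defaults reproduce the design the study was powered for: four groups of
#' 30 participants, 120 fairness-partner trials per participant (6 incentive
#' levels x 2 distribution pairings x 10 repetitions), baseline
#' probabilities of a favour-other decision of 0.65 (compensation) and 0.45
#' (punishment), a logit-scale incentive weight per coded level (points/100)
#' of 0.25 in the conflict punishment group and 0.15 elsewhere, and a normal
#' participant random intercept with standard deviation 1.
#'
#' @param n_per_group participants per group.
#' @param trials_per_cell repetitions of each incentive level x pairing cell
#'   (10 gives the 120-trial analysis set).
#' @param base_prob named baseline probabilities per fairness domain.
#' @param weight named incentive weights per group label.
#' @param sigma_u standard deviation of the participant random intercept.
#' @param alpha significance level.
#' @param n_sims number of simulated studies.
#' @param seed integer seed.
#' @param nAGQ integration setting passed to [lme4::glmer()].
#' @return A `power_config` list.
#' @export
power_config <- function(n_per_group = 30, trials_per_cell = 10,
                         base_prob = c(punishment = 0.45,
                                       compensation = 0.65),
                         weight = c(aligned_punishment = 0.15,
                                    conflict_punishment = 0.25,
                                    aligned_compensation = 0.15,
                                    conflict_compensation = 0.15),
                         sigma_u = 1, alpha = 0.05, n_sims = 100,
                         seed = 1, nAGQ = 1) {
  stopifnot(all(base_prob > 0 & base_prob < 1), n_sims >= 1, alpha > 0,
            alpha < 1)
  structure(list(n_per_group = n_per_group,
                 trials_per_cell = trials_per_cell, base_prob = base_prob,
                 weight = weight, sigma_u = sigma_u, alpha = alpha,
                 n_sims = n_sims, seed = seed, nAGQ = nAGQ),
            class = "power_config")
}

# fixed design table for one simulated study (fairness-partner trials only)
.power_design <- function(config) {
  groups <- all_groups()
  per <- expand.grid(incentive_level = seq(0L, 500L, by = 100L),
                     pairing = c("unfair_vs_equal", "hyperfair_vs_equal"),
                     rep = seq_len(config$trials_per_cell),
                     stringsAsFactors = FALSE)
  rows <- list()
  pid <- 0L
  for (g in groups) {
    sgn <- if (g$incentivized_decision == "favour_other") 1 else -1
    for (j in seq_len(config$n_per_group)) {
      pid <- pid + 1L
      rows[[pid]] <- data.frame(
        id = pid, conflict_degree = g$conflict_degree,
        fairness_domain = g$fairness_domain,
        incentive = per$incentive_level / 100,
        base = config$base_prob[[g$fairness_domain]],
        w = config$weight[[g$label]], sgn = sgn,
        congruent_self = g$fairness_domain == "punishment",
        stringsAsFactors = FALSE)
    }
  }
  d <- do.call(rbind, rows)
  d$conflict_degree <- factor(d$conflict_degree,
                              levels = c("aligned", "conflict"))
  d$fairness_domain <- factor(d$fairness_domain,
                              levels = c("compensation", "punishment"))
  d$id <- factor(d$id)
  d
}

#' Simulation-based power of the confirmatory logistic mixed model
#'
#' For each simulated study, draws per-trial favour-other decisions from the
#' logistic generative model (baseline probability plus a signed incentive
#' weight towards the group's incentivised option plus a participant random
#' intercept), recodes them to fairness congruence, fits
#' `response ~ conflict_degree * fairness_domain + conflict_degree *
#' incentive + (1 | id)`, and records which fixed effects reach
#' significance. Power per effect is the significant fraction with a
#' Clopper-Pearson 95% interval. Simulations whose fit fails to converge
#' are dropped from the denominator and counted.
#'
#' @param config a [power_config()].
#' @return A `power_result`: `results` (term, power, ci_lo, ci_hi, n_used),
#'   `n_dropped`, and the `config`. Fully reproducible under the config
#'   seed.
#' @export
run_power <- function(config = power_config()) {
  stopifnot(inherits(config, "power_config"))
  set.seed(config$seed)
  d <- .power_design(config)
  n_id <- nlevels(d$id)
  id_idx <- as.integer(d$id)
  eta_fixed <- qlogis(d$base) + d$w * d$incentive * d$sgn
  sig <- NULL
  dropped <- 0L
  for (s in seq_len(config$n_sims)) {
    u <- config$sigma_u * rnorm(n_id)
    p_other <- plogis(eta_fixed + u[id_idx])
    favour_other <- rbinom(nrow(d), 1, p_other)
    d$response <- ifelse(d$congruent_self, 1L - favour_other, favour_other)
    fit <- tryCatch(
      suppressWarnings(suppressMessages(lme4::glmer(
        response ~ conflict_degree * fairness_domain +
          conflict_degree * incentive + (1 | id),
        data = d, family = stats::binomial, nAGQ = config$nAGQ))),
      error = function(e) NULL)
    bad <- is.null(fit) ||
      length(fit@optinfo$conv$lme4$messages) > 0 ||
      (!is.null(fit@optinfo$conv$opt) && fit@optinfo$conv$opt != 0)
    if (bad) {
      dropped <- dropped + 1L
      next
    }
    co <- coef(summary(fit))
    pv <- setNames(co[, 4], rownames(co))
    sig <- rbind(sig, pv < config$alpha)
  }
  if (is.null(sig)) stop("all simulated fits failed")
  n_used <- nrow(sig)
  res <- do.call(rbind, lapply(colnames(sig), function(term) {
    k <- sum(sig[, term])
    ci <- binom.test(k, n_used)$conf.int
    data.frame(term = term, power = k / n_used, ci_lo = ci[1],
               ci_hi = ci[2], n_used = n_used, stringsAsFactors = FALSE)
  }))
  structure(list(results = res, n_dropped = dropped, config = config),
            class = "power_result")
}

#' @exportS3Method base::print
print.power_result <- function(x, ...) {
  cat(sprintf("Simulation-based power (%d studies, %d dropped)\n",
              x$config$n_sims, x$n_dropped))
  print(x$results, row.names = FALSE, digits = 3)
  invisible(x)
}
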