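#' Default diffusion generative parameters for the four groups
#'
#' Condition-level drift rates follow the qualitative pattern of interest:
#' higher drift towards the congruent option under aligned than conflicting
#' incentives, and higher drift in the punishment than the compensation
#' domain. Subject-level parameters scatter around these values.
#'
#' @return List with fields `v` (named per group label), `sd_v`, `a`, `sd_a`,
#'   `z`, `sd_zeta` (logit-scale subject scatter of the start point), `t0`,
#'   `sd_t0`, and `z_incentive_slope` (logit-scale effect of the coded
#'   incentive level 0--5 on the start point; 0 by default).
#' @export
ddm_gen_defaults <- function() {
  list(
    v = c(aligned_punishment = 1.0, conflict_punishment = 0.2,
          aligned_compensation = 0.7, conflict_compensation = -0.1),
    sd_v = 0.3,
    a = 1.8, sd_a = 0.2,
    z = 0.5, sd_zeta = 0.3,
    t0 = 0.35, sd_t0 = 0.05,
    z_incentive_slope = 0
  )
}

#' Default logistic generative parameters
#'
#' Baseline probabilities of deciding in favour of the other are 0.65 in the
#' compensation groups and 0.45 in the punishment groups; the incentive
#' weight per coded level (points/100, i.e. 0--5) on the logit scale is 0.25
#' in the conflict punishment group and 0.15 in all other groups, pushing
#' towards the group's incentivised option. Participants carry a normal
#' random intercept with standard deviation `sigma_u`.
#'
#' @return List with `base_prob` (per domain), `weight` (per group label),
#'   and `sigma_u`.
#' @export
logistic_gen_defaults <- function() {
  list(
    base_prob = c(punishment = 0.45, compensation = 0.65),
    weight = c(aligned_punishment = 0.15, conflict_punishment = 0.25,
               aligned_compensation = 0.15, conflict_compensation = 0.15),
    sigma_u = 1
  )
}

#' Simulate one participant's responses from the diffusion model
#'
#' One Wiener first passage per trial; absorption at the upper boundary maps
#' to the congruent response (1). Responses slower than the 4 s deadline are
#' redrawn, mirroring the task's repeat loop for missed trials. On control
#' trials evidence is assumed to accumulate rapidly towards the dominant
#' (favour-self slot) option with drift `v_control`.
#'
#' @param group a [group_condition].
#' @param trials a trial table from [generate_decision_trials()].
#' @param params a [ddm_params] for the experimental trials.
#' @param z_incentive_slope logit-scale shift of the start point per coded
#'   incentive level (0--5); 0 for a level-independent start point.
#' @param v_control drift magnitude towards the dominant option on control
#'   trials.
#' @param deadline response window in seconds.
#' @param dt Euler step of the simulator.
#' @return The trial table with added columns `decision`, `response`, `rt_s`.
#' @export
simulate_participant_ddm <- function(group, trials, params,
                                     z_incentive_slope = 0,
                                     v_control = 3, deadline = 4,
                                     dt = 1e-3) {
  stopifnot(inherits(group, "group_condition"), inherits(params, "ddm_params"))
  n <- nrow(trials)
  response <- integer(n)
  rt <- numeric(n)
  draw_until <- function(n, p) {
    out <- rwiener_fp(n, p, dt = dt)
    while (any(bad <- out$rt > deadline)) {
      redo <- rwiener_fp(sum(bad), p, dt = dt)
      out[bad, ] <- redo
    }
    out
  }
  ctrl <- trials$is_control
  if (any(!ctrl)) {
    idx <- which(!ctrl)
    lev <- trials$incentive_level[idx] / 100
    for (l in unique(lev)) {
      sel <- idx[lev == l]
      z_l <- plogis(qlogis(params$z) + z_incentive_slope * l)
      p_l <- ddm_params(params$v, params$a, z_l, params$t0)
      sim <- draw_until(length(sel), p_l)
      response[sel] <- sim$boundary
      rt[sel] <- sim$rt
    }
  }
  if (any(ctrl)) {
    sim <- draw_until(sum(ctrl), ddm_params(v_control, params$a, 0.5, params$t0))
    # upper boundary = dominant option (the favour-self slot) chosen
    dec_ctrl <- ifelse(sim$boundary == 1, "favour_self", "favour_other")
    response[ctrl] <- code_congruence(dec_ctrl, group)
    rt[ctrl] <- sim$rt
  }
  decision <- character(n)
  decision[!ctrl] <- decode_congruence(response[!ctrl], group)
  if (any(ctrl)) decision[ctrl] <- dec_ctrl
  trials$decision <- decision
  trials$response <- response
  trials$rt_s <- rt
  trials
}

#' Simulate one participant's binary choices from the logistic model
#'
#' The probability of deciding in favour of the other is
#' `plogis(qlogis(base_prob) + w * level * sign + subject_effect)` where
#' `level` is the incentive in units of 100 points (0--5) and `sign` is +1
#' when the group's incentivised decision is `favour_other` and -1 when it
#' is `favour_self`. Control trials pick the dominant option with
#' probability `p_control`.
#'
#' @param group a [group_condition].
#' @param trials trial table from [generate_decision_trials()].
#' @param base_prob baseline probability of `favour_other` at incentive 0.
#' @param incentive_weight logit-scale weight per coded incentive level.
#' @param subject_effect the participant's random intercept (logit scale).
#' @param p_control probability of choosing the dominant control option.
#' @return The trial table with added columns `decision`, `response`, and
#'   `rt_s` (all `NA`: this generative model has no response-time process).
#' @export
simulate_participant_logistic <- function(group, trials, base_prob,
                                          incentive_weight = 0.15,
                                          subject_effect = 0,
                                          p_control = 0.98) {
  stopifnot(inherits(group, "group_condition"),
            base_prob > 0, base_prob < 1)
  sgn <- if (group$incentivized_decision == "favour_other") 1 else -1
  lev <- trials$incentive_level / 100
  eta <- qlogis(base_prob) + incentive_weight * lev * sgn + subject_effect
  p_other <- plogis(eta)
  dec <- ifelse(rbinom(nrow(trials), 1, p_other) == 1,
                "favour_other", "favour_self")
  ctrl <- trials$is_control
  if (any(ctrl)) {
    dom <- rbinom(sum(ctrl), 1, p_control)
    dec[ctrl] <- ifelse(dom == 1, "favour_self", "favour_other")
  }
  trials$decision <- dec
  trials$response <- code_congruence(dec, group)
  trials$rt_s <- NA_real_
  trials
}

#' Simulate questionnaire trait scores
#'
#' Produces five trait scores per participant (trait anger, altruism, and
#' the observer / victim / perpetrator justice-sensitivity subscales). Scale
#' locations and spreads mimic the named instruments but are not validated
#' psychometrics. The perpetrator justice-sensitivity score can be coupled
#' to behaviour through a Gaussian copula: its latent normal score is
#' `coupling` times the normal score of the participant's congruent-choice
#' rate plus independent noise, so the population correlation with the rate
#' approaches `coupling`.
#'
#' @param n number of participants.
#' @param coupling copula correlation between `js_perpetrator` and the
#'   behaviour summary, in `[-1, 1]`.
#' @param behaviour_summary per-participant congruent-choice rates (length
#'   `n`); required when `coupling != 0`.
#' @return Data.frame of `n` rows with columns `anger`, `altruism`,
#'   `js_observer`, `js_victim`, `js_perpetrator`.
#' @export
simulate_traits <- function(n, coupling = 0, behaviour_summary = NULL) {
  stopifnot(n >= 1, abs(coupling) <= 1)
  latent <- rnorm(n)
  if (coupling != 0) {
    stopifnot(!is.null(behaviour_summary), length(behaviour_summary) == n)
    zr <- qnorm(rank(behaviour_summary, ties.method = "random") / (n + 1))
    latent <- coupling * zr + sqrt(1 - coupling^2) * rnorm(n)
  }
  data.frame(
    anger = 18 + 5 * rnorm(n),
    altruism = 3.5 + 0.6 * rnorm(n),
    js_observer = 3 + 1 * rnorm(n),
    js_victim = 3 + 1 * rnorm(n),
    js_perpetrator = 3 + 1 * latent
  )
}

#' Simulate a complete multi-participant study
#'
#' Generates sessions for `n_per_group` participants in each of the four
#' groups and simulates their decision-phase responses under the diffusion
#' or the logistic generative model, plus trait scores coupled to behaviour.
#'
#' @param n_per_group participants per group (default 30, i.e. 120 total).
#' @param model `"ddm"` or `"logistic"`.
#' @param gen generative parameter list ([ddm_gen_defaults()] or
#'   [logistic_gen_defaults()]); defaults to the matching one.
#' @param trait_coupling copula correlation between `js_perpetrator` and the
#'   congruent-choice rate.
#' @param seed optional integer seed.
#' @return List with `trials` (trial-level table, one row per decision-phase
#'   trial including practice and control trials, with a `phase` column) and
#'   `participants` (one row per participant: group, generative parameters
#'   used, congruent-choice rate, trait scores).
#' @export
simulate_study <- function(n_per_group = 30, model = c("ddm", "logistic"),
                           gen = NULL, trait_coupling = 0.3, seed = NULL) {
  model <- match.arg(model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(gen)) {
    gen <- if (model == "ddm") ddm_gen_defaults() else logistic_gen_defaults()
  }
  groups <- all_groups()
  trial_rows <- list()
  part_rows <- list()
  pid <- 0L
  for (g in groups) {
    for (j in seq_len(n_per_group)) {
      pid <- pid + 1L
      id <- sprintf("p%03d", pid)
      session <- generate_session(g)
      prac <- session$practice$decision
      prac$phase <- "practice"
      dec <- session$decision
      dec$phase <- "decision"
      tab <- rbind(prac, dec)
      if (model == "ddm") {
        par_i <- ddm_params(
          v = gen$v[[g$label]] + gen$sd_v * rnorm(1),
          a = max(0.5, gen$a + gen$sd_a * rnorm(1)),
          z = plogis(qlogis(gen$z) + gen$sd_zeta * rnorm(1)),
          t0 = max(0.1, gen$t0 + gen$sd_t0 * rnorm(1))
        )
        tab <- simulate_participant_ddm(g, tab, par_i,
                                        z_incentive_slope = gen$z_incentive_slope)
        par_info <- data.frame(v = par_i$v, a = par_i$a, z = par_i$z,
                               t0 = par_i$t0)
      } else {
        u <- gen$sigma_u * rnorm(1)
        tab <- simulate_participant_logistic(
          g, tab, base_prob = gen$base_prob[[g$fairness_domain]],
          incentive_weight = gen$weight[[g$label]], subject_effect = u)
        par_info <- data.frame(subject_effect = u)
      }
      tab <- cbind(
        data.frame(participant_id = id, group = g$label,
                   fairness_domain = g$fairness_domain,
                   conflict_degree = g$conflict_degree,
                   stringsAsFactors = FALSE),
        tab
      )
      trial_rows[[pid]] <- tab
      analysed <- tab$phase == "decision" & !tab$is_control &
        tab$partner == "fairness_partner"
      part_rows[[pid]] <- cbind(
        data.frame(participant_id = id, group = g$label,
                   fairness_domain = g$fairness_domain,
                   conflict_degree = g$conflict_degree,
                   congruent_rate = mean(tab$response[analysed]),
                   stringsAsFactors = FALSE),
        par_info
      )
    }
  }
  trials <- do.call(rbind, trial_rows)
  participants <- do.call(rbind, part_rows)
  traits <- simulate_traits(nrow(participants), coupling = trait_coupling,
                            behaviour_summary = participants$congruent_rate)
  participants <- cbind(participants, traits)
  rownames(trials) <- rownames(participants) <- NULL
  cols <- c("participant_id", "group", "fairness_domain", "conflict_degree",
            "partner", "trial_index", "incentive_level", "pairing",
            "points_self_opt1", "points_other_opt1", "points_self_opt2",
            "points_other_opt2", "is_control", "decision", "response",
            "rt_s", "phase")
  list(trials = trials[, cols], participants = participants)
}

#' Write / read the trial-level table as CSV
#'
#' Missing response times are written as empty fields.
#'
#' @param trials trial-level data.frame from [simulate_study()].
#' @param path file path.
#' @return `write_trials` returns `path` invisibly; `read_trials` returns
#'   the data.frame with the column types restored.
#' @export
write_trials <- function(trials, path) {
  write.csv(trials, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE,
                colClasses = c(participant_id = "character"))
  d$rt_s <- suppressWarnings(as.numeric(d$rt_s))
  d$is_control <- as.logical(d$is_control)
  d
}
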