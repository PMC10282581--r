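#' Experimental group condition
#'
#' The study crosses fairness domain (punishment: allocating towards a prior
#' norm violator; compensation: allocating towards a prior victim) with
#' conflict degree (whether the monetary incentive rewards the
#' fairness-congruent or the fairness-incongruent choice). The incentivised
#' decision type follows from the two factors: in the punishment domain the
#' congruent choice is `favour_self`, so an aligned incentive pays for
#' `favour_self` and a conflicting one for `favour_other`; in the
#' compensation domain it is the reverse.
#'
#' @param fairness_domain `"punishment"` or `"compensation"`.
#' @param conflict_degree `"aligned"` or `"conflict"`.
#' @return A `group_condition` object with fields `fairness_domain`,
#'   `conflict_degree`, `incentivized_decision` and a `label`.
#' @examples
#' group_condition("punishment", "conflict")$incentivized_decision
#' @export
group_condition <- function(fairness_domain = c("punishment", "compensation"),
                            conflict_degree = c("aligned", "conflict")) {
  fairness_domain <- match.arg(fairness_domain)
  conflict_degree <- match.arg(conflict_degree)
  congruent <- if (fairness_domain == "punishment") "favour_self" else "favour_other"
  incent <- if (conflict_degree == "aligned") {
    congruent
  } else {
    setdiff(c("favour_self", "favour_other"), congruent)
  }
  structure(list(fairness_domain = fairness_domain,
                 conflict_degree = conflict_degree,
                 incentivized_decision = incent,
                 label = paste(conflict_degree, fairness_domain, sep = "_")),
            class = "group_condition")
}

#' All four experimental groups
#' @return Named list of the four [group_condition] objects.
#' @export
all_groups <- function() {
  gs <- list(
    group_condition("punishment", "aligned"),
    group_condition("punishment", "conflict"),
    group_condition("compensation", "aligned"),
    group_condition("compensation", "conflict")
  )
  setNames(gs, vapply(gs, `[[`, character(1), "label"))
}

.alloc_bands <- list(
  unfair = c(0.65, 0.75),
  equal = c(0.45, 0.55),
  hyperfair = c(0.25, 0.35)
)

#' Generate one allocation option
#'
#' Splits `total` points (a multiple of 10 in 500--700) between self and
#' other. The self-share is the category's target ratio (70:30 unfair,
#' 50:50 equal, 30:70 hyperfair) jittered uniformly by +/- 5 percentage
#' points, then rounded to integer points that sum to `total` and clamped
#' into the category band.
#'
#' @param category `"unfair"`, `"equal"` or `"hyperfair"`.
#' @param total pot size in points; one of 500, 510, ..., 700. Drawn
#'   uniformly from that grid when `NULL`.
#' @return List with `points_self`, `points_other`, `category`, `total`.
#' @examples
#' set.seed(1)
#' generate_allocation_option("unfair", 650)
#' @export
generate_allocation_option <- function(category = c("unfair", "equal", "hyperfair"),
                                       total = NULL) {
  category <- match.arg(category)
  grid <- seq(500L, 700L, by = 10L)
  if (is.null(total)) total <- sample(grid, 1L)
  if (!total %in% grid) {
    stop("'total' must be a multiple of 10 between 500 and 700")
  }
  target <- c(unfair = 0.70, equal = 0.50, hyperfair = 0.30)[[category]]
  share <- target + runif(1, -0.05, 0.05)
  ps <- round(share * total)
  band <- .alloc_bands[[category]]
  ps <- min(max(ps, ceiling(band[1] * total)), floor(band[2] * total))
  list(points_self = as.integer(ps),
       points_other = as.integer(total - ps),
       category = category, total = as.integer(total))
}

#' Check an allocation option against its category band
#'
#' @param points_self,points_other integer point values.
#' @param category allocation category.
#' @return `TRUE` when the pot is a multiple of 10 in 500--700, both values
#'   are non-negative integers, and the self-share lies in the category band
#'   (unfair `[0.65, 0.75]`, equal `[0.45, 0.55]`, hyperfair `[0.25, 0.35]`).
#' @export
validate_allocation <- function(points_self, points_other,
                                category = c("unfair", "equal", "hyperfair")) {
  category <- match.arg(category)
  total <- points_self + points_other
  band <- .alloc_bands[[category]]
  share <- points_self / total
  points_self >= 0 && points_other >= 0 &&
    points_self == round(points_self) && points_other == round(points_other) &&
    total %in% seq(500, 700, by = 10) &&
    share >= band[1] && share <= band[2]
}

.pairing_categories <- function(pairing) {
  # opt1 is always the favour-self option, opt2 the favour-other option
  if (pairing == "unfair_vs_equal") c(opt1 = "unfair", opt2 = "equal")
  else c(opt1 = "equal", opt2 = "hyperfair")
}

#' Generate the decision-phase trial list for one participant
#'
#' 240 experimental trials — for each of the two partners (the fairness
#' partner and an uninvolved baseline partner), each incentive level (0--500
#' in steps of 100) crossed with each distribution pairing (unfair vs equal,
#' hyperfair vs equal) exactly 10 times — plus 6 randomly interspersed
#' control trials in which one option weakly dominates for both players.
#' Each option's pot is drawn independently from the 500--700 grid.
#'
#' @param group a [group_condition].
#' @return A data.frame of 246 rows with columns `partner`,
#'   `incentive_level`, `pairing`, `points_self_opt1`, `points_other_opt1`,
#'   `points_self_opt2`, `points_other_opt2`, `is_control`, `trial_index`.
#'   Option 1 is the favour-self option, option 2 the favour-other option;
#'   on control trials option 1 weakly dominates.
#' @export
generate_decision_trials <- function(group) {
  stopifnot(inherits(group, "group_condition"))
  design <- expand.grid(partner = c("fairness_partner", "baseline"),
                        incentive_level = seq(0L, 500L, by = 100L),
                        pairing = c("unfair_vs_equal", "hyperfair_vs_equal"),
                        rep = 1:10,
                        stringsAsFactors = FALSE)
  n <- nrow(design) # 240
  opt <- function(cat) generate_allocation_option(cat)
  o1 <- o2 <- matrix(0L, n, 2)
  for (i in seq_len(n)) {
    cats <- .pairing_categories(design$pairing[i])
    a1 <- opt(cats[["opt1"]]); a2 <- opt(cats[["opt2"]])
    o1[i, ] <- c(a1$points_self, a1$points_other)
    o2[i, ] <- c(a2$points_self, a2$points_other)
  }
  trials <- data.frame(
    partner = design$partner,
    incentive_level = design$incentive_level,
    pairing = design$pairing,
    points_self_opt1 = o1[, 1], points_other_opt1 = o1[, 2],
    points_self_opt2 = o2[, 1], points_other_opt2 = o2[, 2],
    is_control = FALSE,
    stringsAsFactors = FALSE
  )
  # control trials: (x_self, x_other) vs (x_self - delta, x_other - delta)
  ctrl <- vector("list", 6L)
  for (i in 1:6) {
    base <- generate_allocation_option("equal")
    delta <- sample(seq(50L, 150L, by = 10L), 1L)
    ctrl[[i]] <- data.frame(
      partner = sample(c("fairness_partner", "baseline"), 1L),
      incentive_level = sample(seq(0L, 500L, by = 100L), 1L),
      pairing = NA_character_,
      points_self_opt1 = base$points_self,
      points_other_opt1 = base$points_other,
      points_self_opt2 = base$points_self - delta,
      points_other_opt2 = base$points_other - delta,
      is_control = TRUE,
      stringsAsFactors = FALSE
    )
  }
  trials <- rbind(trials, do.call(rbind, ctrl))
  trials <- trials[sample.int(nrow(trials)), , drop = FALSE]
  trials$trial_index <- seq_len(nrow(trials))
  rownames(trials) <- NULL
  trials
}

#' Generate the observation phase
#'
#' 20 allocator decisions the participant passively observes: 10 trials per
#' distribution pairing, and within each pairing 8 decisions in favour of
#' the self and 2 in favour of the other (16 self-favouring overall, 80%),
#' in randomised order.
#'
#' @return Data.frame with columns `pairing`, `allocator_decision`,
#'   `trial_index`.
#' @export
generate_observation_phase <- function() {
  one <- function(pairing) {
    data.frame(pairing = pairing,
               allocator_decision = c(rep("favour_self", 8),
                                      rep("favour_other", 2)),
               stringsAsFactors = FALSE)
  }
  obs <- rbind(one("unfair_vs_equal"), one("hyperfair_vs_equal"))
  obs <- obs[sample.int(nrow(obs)), , drop = FALSE]
  obs$trial_index <- seq_len(nrow(obs))
  rownames(obs) <- NULL
  obs
}

#' Generate the practice block
#'
#' 12 practice trials: 6 for the observation phase and 6 for the decision
#' task. Practice trials are flagged and always excluded from analysis.
#'
#' @param group a [group_condition].
#' @return List with data.frames `observation` (6 rows) and `decision`
#'   (6 rows, same columns as [generate_decision_trials()]).
#' @export
generate_practice_trials <- function(group) {
  obs <- generate_observation_phase()[1:6, ]
  obs$trial_index <- 1:6
  dec <- generate_decision_trials(group)
  dec <- dec[!dec$is_control, ][1:6, ]
  dec$trial_index <- 1:6
  rownames(obs) <- rownames(dec) <- NULL
  list(observation = obs, decision = dec)
}

#' Congruence coding of a decision
#'
#' A response of 1 marks the fairness-congruent choice: `favour_self` in the
#' punishment domain, `favour_other` in the compensation domain.
#'
#' @param decision character vector of `"favour_self"` / `"favour_other"`.
#' @param group a [group_condition].
#' @return Integer vector of 0/1 congruence codes.
#' @examples
#' g <- group_condition("punishment", "aligned")
#' code_congruence(c("favour_self", "favour_other"), g)
#' @export
code_congruence <- function(decision, group) {
  stopifnot(inherits(group, "group_condition"),
            all(decision %in% c("favour_self", "favour_other")))
  congruent <- if (group$fairness_domain == "punishment") "favour_self" else "favour_other"
  as.integer(decision == congruent)
}

#' Inverse of the congruence coding
#'
#' @param response 0/1 congruence codes.
#' @param group a [group_condition].
#' @return Character vector of decisions.
#' @export
decode_congruence <- function(response, group) {
  stopifnot(inherits(group, "group_condition"), all(response %in% c(0, 1)))
  congruent <- if (group$fairness_domain == "punishment") "favour_self" else "favour_other"
  incongruent <- setdiff(c("favour_self", "favour_other"), congruent)
  ifelse(response == 1, congruent, incongruent)
}

#' Payout for drawn trials
#'
#' Per drawn trial, the participant earns the self-points of the chosen
#' distribution, plus the trial incentive when the decision type matches the
#' group's incentivised decision type, converted at 0.005 EUR per point
#' (100 points = 0.50 EUR).
#'
#' @param points_self self-points of the chosen distribution (vector).
#' @param incentive trial incentive in points (vector).
#' @param decision_type `"favour_self"`/`"favour_other"` per trial.
#' @param incentivized_type the group's incentivised decision type
#'   (scalar or vector).
#' @return Numeric vector of per-trial payouts in EUR.
#' @examples
#' compute_payout(449, 500, "favour_other", "favour_other") # 4.745
#' @export
compute_payout <- function(points_self, incentive, decision_type,
                           incentivized_type) {
  stopifnot(all(decision_type %in% c("favour_self", "favour_other")),
            all(incentivized_type %in% c("favour_self", "favour_other")))
  if (any(points_self < 0) || any(incentive < 0)) {
    stop("points and incentives must be non-negative")
  }
  n <- max(length(points_self), length(incentive), length(decision_type),
           length(incentivized_type))
  points_self <- rep_len(points_self, n)
  incentive <- rep_len(incentive, n)
  matched <- rep_len(decision_type, n) == rep_len(incentivized_type, n)
  (points_self + ifelse(matched, incentive, 0)) * 0.005
}

#' Total payout including the show-up fee
#'
#' @param per_trial vector of per-trial payouts from [compute_payout()].
#' @param show_up show-up fee in EUR.
#' @return Total payout in EUR.
#' @export
payout_total <- function(per_trial, show_up = 3) {
  sum(per_trial) + show_up
}

#' Generate one full experimental session
#'
#' Assembles practice (12 trials), observation phase (20 trials) and the
#' decision phase (240 experimental + 6 control = 246 trials), 278 trials in
#' total.
#'
#' @param group a [group_condition].
#' @param seed optional integer seed for reproducible sessions.
#' @return List with elements `group`, `practice`, `observation`,
#'   `decision`, and `n_trials` (the total trial count).
#' @export
generate_session <- function(group, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  practice <- generate_practice_trials(group)
  observation <- generate_observation_phase()
  decision <- generate_decision_trials(group)
  n <- nrow(practice$observation) + nrow(practice$decision) +
    nrow(observation) + nrow(decision)
  list(group = group, practice = practice, observation = observation,
       decision = decision, n_trials = n)
}
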