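# hand-built miniature dataset with known QC outcomes
make_qc_fixture <- function() {
  mk <- function(id, ctrl_fail, rt) {
    n_ctrl <- 6
    ctrl <- data.frame(
      participant_id = id, group = "aligned_punishment",
      fairness_domain = "punishment", conflict_degree = "aligned",
      partner = "fairness_partner", trial_index = 1:n_ctrl,
      incentive_level = 0, pairing = NA_character_,
      points_self_opt1 = 300, points_other_opt1 = 300,
      points_self_opt2 = 200, points_other_opt2 = 200,
      is_control = TRUE,
      decision = c(rep("favour_other", ctrl_fail),
                   rep("favour_self", n_ctrl - ctrl_fail)),
      response = 0L, rt_s = rt, phase = "decision",
      stringsAsFactors = FALSE)
    exper <- ctrl
    exper$is_control <- FALSE
    exper$pairing <- "unfair_vs_equal"
    exper$trial_index <- 7:12
    prac <- exper[1, ]
    prac$phase <- "practice"
    rbind(prac, ctrl, exper)
  }
  rbind(mk("p1", ctrl_fail = 2, rt = 1.0),
        mk("p2", ctrl_fail = 0, rt = 0.4),
        mk("p3", ctrl_fail = 1, rt = 1.2))
}

test_that("quality filters exclude on control failures and fast responding", {
  d <- make_qc_fixture()
  out <- apply_quality_filters(d)
  qc <- out$qc
  expect_true(qc$excluded[qc$participant_id == "p1"])
  expect_equal(qc$reason[qc$participant_id == "p1"], "control_failures")
  expect_true(qc$excluded[qc$participant_id == "p2"])
  expect_equal(qc$reason[qc$participant_id == "p2"], "fast_rt")
  expect_false(qc$excluded[qc$participant_id == "p3"])
  # only p3's non-control decision trials survive
  expect_setequal(unique(out$data$participant_id), "p3")
  expect_false(any(out$data$is_control))
  expect_false(any(out$data$phase == "practice"))
  # dataset without controls: QC skipped with a warning flag
  d2 <- d[!d$is_control, ]
  expect_warning(out2 <- apply_quality_filters(d2), "control")
  expect_true(attr(out2, "qc_skipped"))
})

test_that("the mixed model collapses to plain logistic regression without
           subject variance", {
  gen <- logistic_gen_defaults()
  gen$sigma_u <- 0
  study <- simulate_study(n_per_group = 6, model = "logistic", gen = gen,
                          seed = 31)
  clean <- apply_quality_filters(study$trials)$data
  res <- fit_confirmatory_glmm(clean)
  d <- clean[clean$partner == "fairness_partner", ]
  d <- fairddm:::.prep_factors(d)
  ref <- stats::glm(response ~ conflict_degree * fairness_domain +
                      conflict_degree * incentive,
                    data = d, family = stats::binomial)
  expect_equal(res$estimate, unname(coef(ref)), tolerance = 1e-2)
  expect_equal(res$n[1], nrow(d))
  # Wald z is the estimate/se ratio
  expect_equal(res$z, res$estimate / res$se, tolerance = 1e-6)
})

test_that("the confirmatory model recovers the negative conflict-incentive
           interaction", {
  study <- simulate_study(n_per_group = 15, model = "logistic", seed = 8)
  clean <- apply_quality_filters(study$trials)$data
  res <- fit_confirmatory_glmm(clean, nAGQ = 0)
  term <- res[res$term == "conflict_degreeconflict:incentive", ]
  expect_lt(term$estimate, 0)
  expect_lt(term$p, 0.05)
})

test_that("manipulation models detect a strong incentive-type effect", {
  gen <- logistic_gen_defaults()
  gen$base_prob <- c(punishment = 0.5, compensation = 0.5)
  gen$weight <- c(aligned_punishment = 1, conflict_punishment = 1,
                  aligned_compensation = 1, conflict_compensation = 1)
  gen$sigma_u <- 0.3
  study <- simulate_study(n_per_group = 8, model = "logistic", gen = gen,
                          seed = 12)
  clean <- apply_quality_filters(study$trials)$data
  res <- fit_manipulation_glmms(clean, nAGQ = 0)
  expect_named(res, c("partner_conflict_compensation",
                      "partner_conflict_punishment",
                      "domain_partner", "incentive_type"),
               ignore.order = TRUE)
  it <- res$incentive_type
  main <- it[it$term == "incentive_typefavour_other", ]
  expect_gt(main$estimate, 0)
  expect_lt(main$p, 0.05)
  for (r in res) {
    expect_true(all(c("term", "estimate", "se", "z", "p", "model", "n")
                    %in% names(r)))
  }
})

test_that("a full-size synthetic study yields 14400 confirmatory
           observations", {
  study <- simulate_study(n_per_group = 30, model = "logistic", seed = 400)
  clean <- apply_quality_filters(study$trials)$data
  res <- fit_confirmatory_glmm(clean, nAGQ = 0)
  expect_equal(res$n[1], 14400) # 120 participants x 120 fairness trials
})

test_that("trait correlations apply the fivefold Bonferroni factor", {
  set.seed(17)
  sig <- 0
  for (r in 1:10) {
    rate <- runif(30, 0.2, 0.95)
    traits <- simulate_traits(30, coupling = 0.6, behaviour_summary = rate)
    parts <- cbind(data.frame(group = "conflict_compensation",
                              congruent_rate = rate), traits)
    tab <- trait_correlations(parts)
    expect_equal(nrow(tab), 5)
    expect_equal(tab$p_bonferroni, pmin(1, 5 * tab$p))
    jp <- tab[tab$scale == "js_perpetrator", ]
    if (jp$p_bonferroni < 0.05) sig <- sig + 1
  }
  # a 0.6 coupling at n = 30 survives the correction in most replicates
  expect_gte(sig, 6)
  # zero-variance trait reported as undefined
  parts$anger <- 1
  tab2 <- trait_correlations(parts)
  expect_true(is.na(tab2$r[tab2$scale == "anger"]))
  # calibration: independent traits are significant at roughly alpha
  set.seed(18)
  hits <- 0
  for (r in 1:40) {
    p2 <- cbind(data.frame(group = "g", congruent_rate = runif(40)),
                simulate_traits(40))
    t2 <- trait_correlations(p2)
    hits <- hits + sum(t2$p < 0.05)
  }
  expect_lt(hits / (40 * 5), 0.12)
})
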