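test_that("allocation options respect category bands and the pot grid", {
  set.seed(101)
  for (cat in c("unfair", "equal", "hyperfair")) {
    for (i in 1:150) {
      o <- generate_allocation_option(cat)
      expect_true(validate_allocation(o$points_self, o$points_other, cat))
      expect_equal(o$points_self + o$points_other, o$total)
    }
  }
  # published example splits sit inside the bands
  expect_true(validate_allocation(449, 201, "unfair"))
  expect_true(validate_allocation(283, 277, "equal"))
  expect_true(validate_allocation(192, 488, "hyperfair"))
  expect_error(generate_allocation_option("unfair", 505), "multiple of 10")
  expect_error(generate_allocation_option("weird", 500))
})

test_that("group conditions map factors to the incentivised decision", {
  expect_equal(group_condition("punishment", "conflict")$incentivized_decision,
               "favour_other")
  expect_equal(group_condition("punishment", "aligned")$incentivized_decision,
               "favour_self")
  expect_equal(group_condition("compensation", "aligned")$incentivized_decision,
               "favour_other")
  expect_equal(group_condition("compensation", "conflict")$incentivized_decision,
               "favour_self")
  expect_length(all_groups(), 4)
})

test_that("decision-phase trial lists have the published structure", {
  set.seed(7)
  for (g in all_groups()[c(1, 4)]) {
    tr <- generate_decision_trials(g)
    expect_equal(nrow(tr), 246)
    expect_equal(sum(tr$is_control), 6)
    exp_tr <- tr[!tr$is_control, ]
    expect_equal(nrow(exp_tr), 240)
    expect_equal(sum(exp_tr$partner == "fairness_partner"), 120)
    counts <- table(exp_tr$partner, exp_tr$incentive_level, exp_tr$pairing)
    expect_true(all(counts == 10))
    # option categories follow the pairing
    uve <- exp_tr[exp_tr$pairing == "unfair_vs_equal", ]
    hve <- exp_tr[exp_tr$pairing == "hyperfair_vs_equal", ]
    s1 <- uve$points_self_opt1 / (uve$points_self_opt1 + uve$points_other_opt1)
    s2 <- uve$points_self_opt2 / (uve$points_self_opt2 + uve$points_other_opt2)
    expect_true(all(s1 >= 0.65 & s1 <= 0.75))
    expect_true(all(s2 >= 0.45 & s2 <= 0.55))
    h1 <- hve$points_self_opt1 / (hve$points_self_opt1 + hve$points_other_opt1)
    h2 <- hve$points_self_opt2 / (hve$points_self_opt2 + hve$points_other_opt2)
    expect_true(all(h1 >= 0.45 & h1 <= 0.55))
    expect_true(all(h2 >= 0.25 & h2 <= 0.35))
    # control trials: option 1 weakly dominates for both players
    ctl <- tr[tr$is_control, ]
    expect_true(all(ctl$points_self_opt1 >= ctl$points_self_opt2 &
                      ctl$points_other_opt1 >= ctl$points_other_opt2))
    expect_true(all(ctl$points_self_opt2 >= 0 & ctl$points_other_opt2 >= 0))
  }
})

test_that("the observation phase has 20 trials with the 80/20 split", {
  set.seed(3)
  obs <- generate_observation_phase()
  expect_equal(nrow(obs), 20)
  expect_equal(sum(obs$allocator_decision == "favour_self"), 16)
  per <- table(obs$pairing, obs$allocator_decision)
  expect_true(all(per[, "favour_other"] == 2))
  expect_true(all(per[, "favour_self"] == 8))
})

test_that("congruence coding marks the domain-congruent option and inverts", {
  gp <- group_condition("punishment", "aligned")
  gc <- group_condition("compensation", "conflict")
  expect_equal(code_congruence("favour_self", gp), 1L)
  expect_equal(code_congruence("favour_other", gp), 0L)
  expect_equal(code_congruence("favour_self", gc), 0L)
  expect_equal(code_congruence("favour_other", gc), 1L)
  for (g in all_groups()) {
    d <- c("favour_self", "favour_other")
    expect_equal(decode_congruence(code_congruence(d, g), g), d)
    expect_equal(code_congruence(decode_congruence(c(0L, 1L), g), g), c(0L, 1L))
  }
})

test_that("payouts follow the incentive-matching rule of the reward scheme", {
  expect_equal(compute_payout(449, 500, "favour_self", "favour_self"), 4.745)
  expect_equal(compute_payout(449, 500, "favour_self", "favour_other"), 2.245)
  expect_equal(compute_payout(0, 0, "favour_self", "favour_self"), 0)
  # non-decreasing in incentive when matched, constant when not
  inc <- seq(0, 500, by = 100)
  matched <- compute_payout(rep(300, 6), inc, "favour_self", "favour_self")
  unmatched <- compute_payout(rep(300, 6), inc, "favour_self", "favour_other")
  expect_true(all(diff(matched) >= 0))
  expect_true(all(diff(unmatched) == 0))
  expect_equal(payout_total(c(1, 2)), 6) # 3 EUR show-up fee
  expect_error(compute_payout(-1, 0, "favour_self", "favour_self"),
               "non-negative")
})

test_that("sessions contain 278 trials and are seed-reproducible", {
  g <- group_condition("compensation", "aligned")
  s1 <- generate_session(g, seed = 11)
  s2 <- generate_session(g, seed = 11)
  s3 <- generate_session(g, seed = 12)
  expect_equal(s1$n_trials, 278)
  expect_equal(nrow(s1$decision), 246)
  expect_equal(nrow(s1$observation), 20)
  expect_identical(s1$decision, s2$decision)
  expect_identical(s1$observation, s2$observation)
  expect_false(identical(s1$decision, s3$decision))
})

test_that("the trial CSV round-trips including missing response times", {
  study <- simulate_study(n_per_group = 1, model = "logistic", seed = 5)
  path <- tempfile(fileext = ".csv")
  write_trials(study$trials, path)
  back <- read_trials(path)
  expect_equal(nrow(back), nrow(study$trials))
  expect_true(all(is.na(back$rt_s)))
  expect_equal(back$response, study$trials$response)
  expect_equal(back$points_self_opt1, study$trials$points_self_opt1)
  # empty-field encoding for missing RT
  raw <- readLines(path, n = 2)
  expect_false(grepl("NA", raw[2]))
})
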