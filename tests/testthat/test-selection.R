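test_that("DIC components satisfy the defining identity", {
  d <- compute_dic(deviance = c(10, 14), dev_at_mean = 11)
  expect_equal(d$dbar, 12)
  expect_equal(d$pd, 1)
  expect_equal(d$dic, 13)
  one <- compute_dic(deviance = 42, dev_at_mean = 42)
  expect_equal(one$pd, 0)
  expect_equal(one$dic, 42)
  expect_error(compute_dic(deviance = numeric(0), dev_at_mean = 1), "empty")
})

test_that("model selection applies the 10-point rule order-invariantly", {
  f <- function(name, dic) make_fake_fit(name, dic)
  s1 <- select_model(list(f("M0", 100), f("V2", 85)))
  expect_equal(s1$winners, "V2")
  expect_false(s1$averaged)
  s2 <- select_model(list(f("M0", 100), f("V1", 95)))
  expect_setequal(s2$winners, c("M0", "V1"))
  expect_true(s2$averaged)
  s3 <- select_model(list(f("M0", 90), f("V1", 90), f("V2", 90)))
  expect_setequal(s3$winners, c("M0", "V1", "V2"))
  # boundary: exactly 10 apart keeps only the lower-DIC model
  s4 <- select_model(list(f("M0", 100), f("V2", 90)))
  expect_equal(s4$winners, "V2")
  # order invariance
  a <- select_model(list(f("M0", 100), f("V1", 95), f("V2", 85)))
  b <- select_model(list(f("V2", 85), f("M0", 100), f("V1", 95)))
  expect_identical(a$table, b$table)
  expect_identical(a$winners, b$winners)
  expect_error(select_model(list(f("M0", 1))), "length")
})

test_that("averaging weights follow exp(-delta DIC / 2)", {
  set.seed(1)
  tr <- rnorm(5000, 1)
  fits <- list(make_fake_fit("V1", 100,
                             v_cell_traces = list(aligned = tr + 0.5,
                                                  conflict = tr - 0.5)),
               make_fake_fit("V2", 102,
                             v_cell_traces = list(
                               aligned_punishment = tr + 0.5,
                               conflict_punishment = tr - 0.5,
                               aligned_compensation = tr + 0.5,
                               conflict_compensation = tr - 0.5),
                             n_draws = 5000))
  av <- average_models(fits, function(f) conflict_effect_trace(f, "v"))
  expect_equal(unname(av$weights),
               c(exp(0), exp(-1)) / (exp(0) + exp(-1)), tolerance = 1e-12)
  expect_length(av$trace, 5000)
})

test_that("averaging identical members reproduces the member distribution", {
  set.seed(2)
  half <- rnorm(10000, 0.35, 0.1)
  mk <- function(name, dic) {
    make_fake_fit(name, dic, v_cell_traces = list(aligned = half,
                                                  conflict = -half),
                  n_draws = 10000)
  }
  member_effect <- 2 * half # what conflict_effect_trace returns per member
  av <- average_models(list(mk("V1", 50), mk("V1", 50)),
                       function(f) conflict_effect_trace(f, "v"))
  ks <- suppressWarnings(stats::ks.test(av$trace, member_effect)$statistic)
  expect_lt(unname(ks), 0.02)
  # single member passes through untouched
  single <- average_models(list(mk("V1", 50)),
                           function(f) conflict_effect_trace(f, "v"))
  expect_equal(single$trace, member_effect)
})

test_that("members without the parameter contribute a null effect", {
  set.seed(3)
  tr <- rnorm(4000, 1)
  fits <- list(make_fake_fit("M0", 100, n_draws = 4000),
               make_fake_fit("V1", 100,
                             v_cell_traces = list(aligned = tr,
                                                  conflict = tr - 2),
                             n_draws = 4000))
  av <- average_models(fits, function(f) conflict_effect_trace(f, "v"))
  # equal weights: half the pooled draws are exact zeros from M0, the other
  # half the V1 member's constant effect of 2
  expect_equal(mean(av$trace == 0), 0.5, tolerance = 0.05)
  expect_equal(mean(av$trace), 1, tolerance = 0.1)
})

test_that("exceedance probabilities behave as paired-sample fractions", {
  set.seed(4)
  b <- rnorm(10000)
  expect_equal(exceedance(b + 1, b), 1)
  a <- rnorm(10000)
  p <- exceedance(a, b)
  expect_lt(abs(p - 0.5), 0.015)
  expect_equal(exceedance(a, b) + exceedance(b, a), 1)
  # closed-form normal comparison: P(A > B) = Phi(0.3 / sqrt(0.02))
  a2 <- rnorm(1e5, 0.3, 0.1)
  b2 <- rnorm(1e5, 0, 0.1)
  expect_equal(exceedance(a2, b2), pnorm(0.3 / sqrt(0.02)), tolerance = 0.005)
  expect_error(exceedance(rnorm(10), rnorm(9)), "equal length")
})

test_that("hypothesis tests read the winning set and its traces", {
  set.seed(7)
  cell <- function(m) rnorm(4000, m, 0.1) # independent noise per cell
  # V2 winner with a huge uniform conflict effect: H4 certain, H6 null
  v2 <- make_fake_fit("V2", 80, v_cell_traces = list(
    aligned_punishment = cell(10), conflict_punishment = cell(0),
    aligned_compensation = cell(10), conflict_compensation = cell(0)))
  m0 <- make_fake_fit("M0", 120, n_draws = 4000)
  sel <- select_model(list(m0, v2))
  hyp <- evaluate_hypotheses(sel)
  expect_equal(hyp$label, c("H4", "H5", "H6"))
  h4 <- hyp[hyp$label == "H4", ]
  expect_equal(h4$probability, 1)
  expect_true(h4$confirmed)
  h6 <- hyp[hyp$label == "H6", ]
  expect_lt(abs(h6$probability - 0.5), 0.05)
  expect_false(h6$confirmed)
  # H5 not evaluable: no model in the winning set varies z
  h5 <- hyp[hyp$label == "H5", ]
  expect_false(h5$evaluable)
  expect_true(is.na(h5$confirmed))
  # only the null model: nothing evaluable, never silently false
  sel0 <- select_model(list(make_fake_fit("M0", 100, n_draws = 4000),
                            make_fake_fit("M0b", 101, n_draws = 4000)))
  hyp0 <- evaluate_hypotheses(sel0)
  expect_true(all(!hyp0$evaluable))
  expect_true(all(is.na(hyp0$confirmed)))
})
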