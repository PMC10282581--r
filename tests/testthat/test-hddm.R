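test_that("the model space holds the five confirmatory models", {
  sp <- build_model_space()
  expect_named(sp, c("M0", "V1", "V2", "Z1", "Z2"))
  expect_length(sp$M0$v_covariates, 0)
  expect_length(sp$M0$z_covariates, 0)
  expect_setequal(sp$V2$v_covariates, c("conflict_degree", "fairness_domain"))
  expect_length(sp$V2$z_covariates, 0)
  expect_equal(sp$Z1$z_covariates, "conflict_degree")
  spe <- build_model_space(exploratory = TRUE)
  expect_length(spe, 9)
  zi <- spe[grepl("^ZI_", names(spe))]
  expect_length(zi, 4)
  expect_true(all(vapply(zi, function(s) "incentive_level" %in% s$z_covariates,
                         logical(1))))
  expect_false(is.null(zi[[1]]$group))
})

test_that("split R-hat passes stationary chains and flags separated ones", {
  set.seed(5)
  good <- list(rnorm(10000), rnorm(10000))
  gr <- gelman_rubin(good)
  expect_lt(gr$rhat, 1.01)
  sep <- list(rnorm(1000, 0), rnorm(1000, 10))
  expect_gt(gelman_rubin(sep)$rhat, 1.1)
  # two identical stationary chains are indistinguishable
  x <- rnorm(5000)
  expect_lt(gelman_rubin(list(x, x))$rhat, 1.01)
  expect_error(gelman_rubin(list(rnorm(100))), "two chains")
})

test_that("the Geweke score separates white noise from drifting chains", {
  set.seed(6)
  expect_lt(abs(geweke_z(rnorm(5000))), 3)
  expect_gt(abs(geweke_z(seq(0, 5, length.out = 2000) + rnorm(2000, 0, 0.1))),
            4)
})

test_that("single-subject posteriors concentrate near generating values", {
  set.seed(77)
  p_true <- ddm_params(1, 1.5, 0.5, 0.3)
  sim <- rwiener_fp(2500, p_true)
  d <- data.frame(participant_id = "s1", conflict_degree = "aligned",
                  fairness_domain = "punishment", incentive_level = 0,
                  response = sim$boundary, rt_s = sim$rt)
  fit <- suppressWarnings(fit_hddm(d, hddm_spec("M0"), chains = 2,
                                   draws = 500, burnin = 500, seed = 3))
  sm <- fit$subject_means
  expect_lt(abs(sm$v - 1), 0.1)
  expect_lt(abs(sm$a - 1.5), 0.1)
  expect_lt(abs(sm$z - 0.5), 0.05)
  expect_lt(abs(sm$t0 - 0.3), 0.05)
  # DIC identity holds exactly
  expect_equal(fit$dic, fit$dbar + fit$pd)
  expect_equal(fit$pd, fit$dbar - fit$dev_at_mean)
})

test_that("fits are reproducible under a seed and respect trace shapes", {
  set.seed(12)
  d <- sim_hddm_data(2, 40)
  f1 <- suppressWarnings(fit_hddm(d, hddm_spec("M0"), chains = 2, draws = 50,
                                  burnin = 50, seed = 10))
  f2 <- suppressWarnings(fit_hddm(d, hddm_spec("M0"), chains = 2, draws = 50,
                                  burnin = 50, seed = 10))
  expect_identical(f1$traces, f2$traces)
  expect_identical(f1$dic, f2$dic)
  expect_equal(nrow(f1$traces[[1]]), 50)
  expect_true(all(is.finite(parameter_traces(f1))))
  expect_equal(length(f1$deviance[[1]]), 50)
  expect_s3_class(f1$rhat, "data.frame")
})

test_that("a V1 fit recovers the conflict effect on the drift rate", {
  set.seed(202)
  d <- sim_hddm_data(4, 80, v_cells = c(aligned_punishment = 1.2,
                                        conflict_punishment = 0.4,
                                        aligned_compensation = 1.2,
                                        conflict_compensation = 0.4))
  fit <- suppressWarnings(fit_hddm(d, hddm_spec("V1",
                                                v_covariates = "conflict_degree"),
                                   chains = 2, draws = 400, burnin = 400,
                                   seed = 4))
  eff <- conflict_effect_trace(fit, "v")
  expect_false(is.null(eff))
  expect_lt(abs(mean(eff) - 0.8), 0.35)
  expect_gt(exceedance(eff, 0), 0.9)
  # models without the covariate expose no conflict trace
  expect_null(conflict_effect_trace(fit, "z"))
  # posterior predictive: simulating at the subject-level posterior means
  # reproduces each subject's congruent-choice fraction
  set.seed(303)
  pp_err <- vapply(seq_len(nrow(fit$subject_means)), function(i) {
    sm <- fit$subject_means[i, ]
    sim <- rwiener_fp(4000, ddm_params(sm$v, sm$a, sm$z, sm$t0))
    obs <- mean(d$response[d$participant_id == sm$participant_id])
    abs(mean(sim$boundary) - obs)
  }, numeric(1))
  expect_lt(mean(pp_err), 0.05)
})

test_that("start-point covariates stay inside the unit interval", {
  set.seed(55)
  d <- sim_hddm_data(2, 40, z_cells = c(aligned_punishment = 0.62,
                                        conflict_punishment = 0.45,
                                        aligned_compensation = 0.62,
                                        conflict_compensation = 0.45))
  fit <- suppressWarnings(fit_hddm(
    d, hddm_spec("Z1", z_covariates = "conflict_degree"),
    chains = 2, draws = 120, burnin = 120, seed = 9))
  zc <- fairddm:::.cell_traces(fit, "z")
  expect_true(all(zc > 0 & zc < 1))
  expect_equal(colnames(zc), c("aligned", "conflict"))
})
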