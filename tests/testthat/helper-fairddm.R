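# Shared fixture builders: all synthetic, generated at test time.

# Minimal trial table for hierarchical fits: n_per_group subjects in each of
# the four groups, n_trials Wiener-simulated responses each. v_cells is a
# named vector over group labels (aligned_punishment, ...).
sim_hddm_data <- function(n_per_group, n_trials,
                          v_cells = c(aligned_punishment = 1.1,
                                      conflict_punishment = 0.3,
                                      aligned_compensation = 1.1,
                                      conflict_compensation = 0.3),
                          a = 1.8, z = 0.5, t0 = 0.3,
                          sd_v = 0.3, z_cells = NULL) {
  rows <- list()
  pid <- 0L
  for (g in all_groups()) {
    for (j in seq_len(n_per_group)) {
      pid <- pid + 1L
      zi <- if (is.null(z_cells)) z else z_cells[[g$label]]
      p <- ddm_params(v = v_cells[[g$label]] + sd_v * rnorm(1), a = a,
                      z = zi, t0 = t0)
      sim <- rwiener_fp(n_trials, p)
      rows[[pid]] <- data.frame(
        participant_id = sprintf("s%03d", pid),
        conflict_degree = g$conflict_degree,
        fairness_domain = g$fairness_domain,
        incentive_level = rep_len(seq(0, 500, by = 100), n_trials),
        response = sim$boundary, rt_s = sim$rt,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

# Hand-built hddm_fit stand-in with prescribed DIC and drift-cell traces,
# for exercising the selection logic without running MCMC.
make_fake_fit <- function(name, dic, v_cell_traces = NULL,
                          z_cell_traces = NULL, n_draws = 2000) {
  if (!is.null(v_cell_traces)) n_draws <- length(v_cell_traces[[1]])
  if (!is.null(z_cell_traces)) n_draws <- length(z_cell_traces[[1]])
  spec <- switch(name,
                 M0 = hddm_spec("M0"),
                 V1 = hddm_spec("V1", v_covariates = "conflict_degree"),
                 V2 = hddm_spec("V2", v_covariates = c("conflict_degree",
                                                       "fairness_domain")),
                 Z1 = hddm_spec("Z1", z_covariates = "conflict_degree"),
                 Z2 = hddm_spec("Z2", z_covariates = c("conflict_degree",
                                                       "fairness_domain")),
                 hddm_spec(name))
  vc <- if (is.null(v_cell_traces)) {
    matrix(rnorm(n_draws), ncol = 1, dimnames = list(NULL, "mu_v"))
  } else {
    m <- do.call(cbind, v_cell_traces)
    colnames(m) <- sprintf("mu_v[%s]", names(v_cell_traces))
    m
  }
  zc <- if (is.null(z_cell_traces)) {
    matrix(rnorm(n_draws), ncol = 1, dimnames = list(NULL, "mu_zlogit"))
  } else {
    m <- do.call(cbind, z_cell_traces)
    colnames(m) <- sprintf("mu_zlogit[%s]", names(z_cell_traces))
    m
  }
  tr <- cbind(vc, zc)
  structure(list(
    spec = spec, traces = list(tr),
    deviance = list(rep(dic, 4)), dbar = dic, dev_at_mean = dic, pd = 0,
    dic = dic, rhat = data.frame(parameter = colnames(tr),
                                 rhat = rep(1, ncol(tr))),
    converged = TRUE,
    cells = list(v = if (is.null(v_cell_traces)) "all" else
                   names(v_cell_traces),
                 z = if (is.null(z_cell_traces)) "all" else
                   names(z_cell_traces)),
    n_subjects = 0L, n_trials = 0L,
    settings = list(chains = 1, draws = n_draws, burnin = 0, thin = 1,
                    seed = 0)
  ), class = "hddm_fit")
}

# Conditional-on-boundary CDF of the analytic first-passage density,
# evaluated by trapezoidal quadrature on a fine grid; used as the reference
# distribution in Kolmogorov-Smirnov checks of the simulator.
wfpt_cdf_fun <- function(params, boundary = "upper", t_max = 20,
                         n_grid = 8000) {
  tg <- seq(params$t0, t_max, length.out = n_grid)
  dg <- wfpt_density(tg, boundary, params)
  cg <- cumsum(c(0, diff(tg) * (head(dg, -1) + tail(dg, -1)) / 2))
  cg <- cg / cg[length(cg)]
  approxfun(tg, cg, yleft = 0, yright = 1)
}
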