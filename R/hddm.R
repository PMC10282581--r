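#' Hierarchical DDM model specification
#'
#' Names the parameters that vary by condition. `v_covariates` and
#' `z_covariates` are subsets of the between-subject factors
#' `conflict_degree` and `fairness_domain` (the start point may additionally
#' carry the within-subject `incentive_level` regressor in the exploratory
#' space); boundary separation and non-decision time never carry covariates.
#' When covariates are named, the group-level mean of the parameter is
#' estimated per cell of the crossed factor levels.
#'
#' @param name model label.
#' @param v_covariates character vector of factors the drift rate varies by.
#' @param z_covariates character vector of factors/regressors the start
#'   point varies by.
#' @param group optional group label: fit restricted to one experimental
#'   group (used by the exploratory incentive-level models).
#' @return An object of class `hddm_spec`.
#' @export
hddm_spec <- function(name, v_covariates = character(0),
                      z_covariates = character(0), group = NULL) {
  stopifnot(all(v_covariates %in% c("conflict_degree", "fairness_domain")),
            all(z_covariates %in% c("conflict_degree", "fairness_domain",
                                    "incentive_level")))
  structure(list(name = name, v_covariates = v_covariates,
                 z_covariates = z_covariates, group = group),
            class = "hddm_spec")
}

#' @exportS3Method base::print
print.hddm_spec <- function(x, ...) {
  fmt <- function(cv) if (length(cv) == 0) "-" else paste(cv, collapse = " + ")
  cat(sprintf("hddm model %s: v ~ %s, z ~ %s%s\n", x$name,
              fmt(x$v_covariates), fmt(x$z_covariates),
              if (is.null(x$group)) "" else paste0(" [group ", x$group, "]")))
  invisible(x)
}

#' The model space
#'
#' The confirmatory space holds five models: a null model M0 with all
#' parameters fixed across conditions, drift-rate models V1
#' (`v ~ conflict_degree`) and V2 (`v ~ conflict_degree + fairness_domain`),
#' and start-point models Z1 and Z2 with the same covariate structure on the
#' start point. With `exploratory = TRUE`, four per-group models regressing
#' the start point on the trial-wise incentive level (coded 0--5) are
#' appended, one per experimental group.
#'
#' @param exploratory append the per-group incentive-level models?
#' @return Named list of [hddm_spec] objects.
#' @export
build_model_space <- function(exploratory = FALSE) {
  space <- list(
    M0 = hddm_spec("M0"),
    V1 = hddm_spec("V1", v_covariates = "conflict_degree"),
    V2 = hddm_spec("V2", v_covariates = c("conflict_degree", "fairness_domain")),
    Z1 = hddm_spec("Z1", z_covariates = "conflict_degree"),
    Z2 = hddm_spec("Z2", z_covariates = c("conflict_degree", "fairness_domain"))
  )
  if (exploratory) {
    for (g in names(all_groups())) {
      nm <- paste0("ZI_", g)
      space[[nm]] <- hddm_spec(nm, z_covariates = "incentive_level", group = g)
    }
  }
  space
}

# --- internal: data preparation ---------------------------------------------

.hddm_prepare <- function(data, spec) {
  need <- c("participant_id", "conflict_degree", "fairness_domain",
            "incentive_level", "response", "rt_s")
  if (!all(need %in% names(data))) {
    stop("data must contain columns: ", paste(need, collapse = ", "))
  }
  if (!is.null(spec$group)) {
    lab <- paste(data$conflict_degree, data$fairness_domain, sep = "_")
    data <- data[lab == spec$group, , drop = FALSE]
    if (nrow(data) == 0) stop("no rows for group ", spec$group)
  }
  data <- data[is.finite(data$rt_s) & data$rt_s > 0 &
                 data$response %in% c(0, 1), , drop = FALSE]
  ids <- unique(data$participant_id)
  first <- data[!duplicated(data$participant_id), , drop = FALSE]
  first <- first[match(ids, first$participant_id), ]
  cell_of <- function(covs) {
    covs <- setdiff(covs, "incentive_level")
    if (length(covs) == 0) return(rep("all", length(ids)))
    do.call(paste, c(lapply(covs, function(cv) first[[cv]]), sep = "_"))
  }
  cv <- cell_of(spec$v_covariates)
  cz <- cell_of(spec$z_covariates)
  zi <- "incentive_level" %in% spec$z_covariates
  subs <- lapply(ids, function(id) {
    d <- data[data$participant_id == id, ]
    list(rt = d$rt_s, up = as.integer(d$response),
         inc = d$incentive_level / 100, n = nrow(d))
  })
  list(ids = ids, subs = subs,
       cellv = factor(cv, levels = sort(unique(cv))),
       cellz = factor(cz, levels = sort(unique(cz))),
       cellv_info = first[, intersect(c("conflict_degree", "fairness_domain"),
                                      spec$v_covariates), drop = FALSE],
       cellz_info = first[, intersect(c("conflict_degree", "fairness_domain"),
                                      setdiff(spec$z_covariates, "incentive_level")),
                          drop = FALSE],
       zi = zi, n_trials = nrow(data))
}

# conjugate normal draw for a group-level mean
.draw_mu <- function(theta, sigma, prior_mean, prior_sd, lower = -Inf) {
  n <- length(theta)
  prec <- n / sigma^2 + 1 / prior_sd^2
  m <- (sum(theta) / sigma^2 + prior_mean / prior_sd^2) / prec
  s <- sqrt(1 / prec)
  if (is.finite(lower)) {
    u <- runif(1, pnorm(lower, m, s), 1)
    # guard the extreme tail
    qnorm(min(max(u, 1e-12), 1 - 1e-12), m, s)
  } else {
    rnorm(1, m, s)
  }
}

# log target for a group-level scale (half-normal prior, log-scale RW)
.sigma_logpost <- function(sigma, theta, mu_of_theta, prior_sd = 0.5) {
  if (sigma <= 0) return(-Inf)
  sum(dnorm(theta, mu_of_theta, sigma, log = TRUE)) +
    dnorm(sigma, 0, prior_sd, log = TRUE) + log(sigma)
}

#' Fit a hierarchical drift-diffusion model by MCMC
#'
#' Subject-level parameters (drift `v`, boundary `a`, logit start point
#' `zeta`, non-decision time `t0`) are drawn from group-level normal
#' distributions whose means are estimated per condition cell for the
#' parameters named in the model specification. The start point uses a
#' logistic link, so condition or incentive effects can never push it
#' outside (0, 1). Sampling is Metropolis-within-Gibbs: random-walk updates
#' with proposal scales adapted during burn-in for subject-level parameters,
#' group scales and the incentive regression weight, and conjugate draws for
#' group means. Priors are weakly informative: group means
#' Normal(0, 2) for `v`, Normal(1.5, 0.75) for `a`, Normal(0, 1) for the
#' logit start point, Normal(0.4, 0.2) truncated positive for `t0`; all
#' group scales Half-Normal(0.5); incentive weight Normal(0, 1).
#'
#' The deviance trace conditions on the subject-level parameters
#' (lowest-level focus), and `DIC = Dbar + pD` with
#' `pD = Dbar - D(theta_bar)` evaluated at the posterior mean of the
#' subject-level parameters on the sampling scale.
#'
#' @param data trial-level data.frame with columns `participant_id`,
#'   `conflict_degree`, `fairness_domain`, `incentive_level`, `response`
#'   (0/1) and `rt_s` (s). Rows without a usable response time are dropped.
#' @param spec an [hddm_spec].
#' @param chains number of chains (>= 2 for convergence diagnostics).
#' @param draws posterior draws kept per chain.
#' @param burnin burn-in iterations per chain (discarded, used to adapt).
#' @param thin thinning interval.
#' @param seed integer seed; chain c uses `seed + c - 1`.
#' @param progress print progress?
#' @return An object of class `hddm_fit`: posterior traces of the
#'   group-level parameters per chain, deviance traces, DIC components
#'   (`dbar`, `dev_at_mean`, `pd`, `dic`), split-R-hat per parameter,
#'   subject-level posterior means, and the settings used. If any R-hat is
#'   at or above 1.01 the fit is flagged (`converged = FALSE`) with a
#'   warning, never silently.
#' @export
fit_hddm <- function(data, spec, chains = 4, draws = 5000, burnin = 2000,
                     thin = 1, seed = NULL, progress = FALSE) {
  stopifnot(inherits(spec, "hddm_spec"), chains >= 2, draws >= 1)
  prep <- .hddm_prepare(data, spec)
  ns <- length(prep$ids)
  kv <- nlevels(prep$cellv)
  kz <- nlevels(prep$cellz)
  iv <- as.integer(prep$cellv)
  iz <- as.integer(prep$cellz)
  zi <- prep$zi
  if (is.null(seed)) seed <- sample.int(1e6, 1)

  par_names <- c(
    if (kv == 1) "mu_v" else sprintf("mu_v[%s]", levels(prep$cellv)),
    "sigma_v",
    "mu_a", "sigma_a",
    if (kz == 1) "mu_zlogit" else sprintf("mu_zlogit[%s]", levels(prep$cellz)),
    "sigma_zlogit",
    "mu_t0", "sigma_t0",
    if (zi) "gamma_z_incentive"
  )

  ll_sub <- function(s, v, a, zeta, t0, gamma) {
    z <- if (zi) plogis(zeta + gamma * s$inc) else plogis(zeta)
    wfpt_loglik_cpp(s$rt, s$up, v, a, z, t0, 1e-7)
  }

  run_chain <- function(chain_id) {
    set.seed(seed + chain_id - 1)
    # initial values from crude per-subject moments, jittered per chain
    a_i <- pmax(0.8, 1.5 + 0.1 * rnorm(ns))
    zeta_i <- 0.2 * rnorm(ns)
    t0_i <- vapply(prep$subs, function(s) {
      max(0.05, min(0.3, 0.8 * min(s$rt)))
    }, numeric(1)) * runif(ns, 0.85, 1)
    v_i <- vapply(seq_len(ns), function(i) {
      p <- min(max(mean(prep$subs[[i]]$up), 0.05), 0.95)
      qlogis(p) / a_i[i]
    }, numeric(1)) + 0.1 * rnorm(ns)
    mu_v <- as.numeric(tapply(v_i, iv, mean))
    mu_a <- mean(a_i)
    mu_zl <- as.numeric(tapply(zeta_i, iz, mean))
    mu_t0 <- max(0.05, mean(t0_i))
    sig_v <- 0.4; sig_a <- 0.25; sig_zl <- 0.3; sig_t0 <- 0.08
    gamma <- 0

    cur_ll <- vapply(seq_len(ns), function(i) {
      ll_sub(prep$subs[[i]], v_i[i], a_i[i], zeta_i[i], t0_i[i], gamma)
    }, numeric(1))
    if (any(!is.finite(cur_ll))) {
      # push t0 below the fastest response where needed
      bad <- which(!is.finite(cur_ll))
      for (i in bad) {
        t0_i[i] <- 0.5 * min(prep$subs[[i]]$rt)
        cur_ll[i] <- ll_sub(prep$subs[[i]], v_i[i], a_i[i], zeta_i[i],
                            t0_i[i], gamma)
      }
    }

    step <- c(v = 0.4, a = 0.2, zeta = 0.35, t0 = 0.05,
              lsig = 0.4, gamma = 0.15)
    acc <- rej <- setNames(numeric(length(step)), names(step))

    n_iter <- burnin + draws * thin
    keep <- matrix(NA_real_, nrow = draws, ncol = length(par_names),
                   dimnames = list(NULL, par_names))
    dev <- numeric(draws)
    sub_sum <- matrix(0, nrow = ns, ncol = 4,
                      dimnames = list(NULL, c("v", "a", "zeta", "t0")))
    kept <- 0L

    upd_subject <- function(i, what) {
      th <- switch(what, v = v_i[i], a = a_i[i], zeta = zeta_i[i], t0 = t0_i[i])
      prop <- th + step[[what]] * rnorm(1)
      if (what == "a" && prop <= 0) return(FALSE)
      if (what == "t0" && prop < 0) return(FALSE)
      ll_new <- switch(what,
        v = ll_sub(prep$subs[[i]], prop, a_i[i], zeta_i[i], t0_i[i], gamma),
        a = ll_sub(prep$subs[[i]], v_i[i], prop, zeta_i[i], t0_i[i], gamma),
        zeta = ll_sub(prep$subs[[i]], v_i[i], a_i[i], prop, t0_i[i], gamma),
        t0 = ll_sub(prep$subs[[i]], v_i[i], a_i[i], zeta_i[i], prop, gamma))
      pr_old <- switch(what,
        v = dnorm(th, mu_v[iv[i]], sig_v, log = TRUE),
        a = dnorm(th, mu_a, sig_a, log = TRUE),
        zeta = dnorm(th, mu_zl[iz[i]], sig_zl, log = TRUE),
        t0 = dnorm(th, mu_t0, sig_t0, log = TRUE))
      pr_new <- switch(what,
        v = dnorm(prop, mu_v[iv[i]], sig_v, log = TRUE),
        a = dnorm(prop, mu_a, sig_a, log = TRUE),
        zeta = dnorm(prop, mu_zl[iz[i]], sig_zl, log = TRUE),
        t0 = dnorm(prop, mu_t0, sig_t0, log = TRUE))
      if (log(runif(1)) < (ll_new + pr_new) - (cur_ll[i] + pr_old)) {
        switch(what,
               v = (v_i[i] <<- prop), a = (a_i[i] <<- prop),
               zeta = (zeta_i[i] <<- prop), t0 = (t0_i[i] <<- prop))
        cur_ll[i] <<- ll_new
        TRUE
      } else FALSE
    }

    upd_sigma <- function(sig, theta, mu_theta) {
      lsig <- log(sig) + step[["lsig"]] * rnorm(1)
      prop <- exp(lsig)
      lp_new <- .sigma_logpost(prop, theta, mu_theta)
      lp_old <- .sigma_logpost(sig, theta, mu_theta)
      if (log(runif(1)) < lp_new - lp_old) list(sig = prop, acc = TRUE)
      else list(sig = sig, acc = FALSE)
    }

    for (it in seq_len(n_iter)) {
      for (i in seq_len(ns)) {
        for (what in c("v", "a", "zeta", "t0")) {
          ok <- upd_subject(i, what)
          if (ok) acc[what] <- acc[what] + 1 else rej[what] <- rej[what] + 1
        }
      }
      for (k in seq_len(kv)) {
        mu_v[k] <- .draw_mu(v_i[iv == k], sig_v, 0, 2)
      }
      mu_a <- .draw_mu(a_i, sig_a, 1.5, 0.75)
      for (k in seq_len(kz)) {
        mu_zl[k] <- .draw_mu(zeta_i[iz == k], sig_zl, 0, 1)
      }
      mu_t0 <- .draw_mu(t0_i, sig_t0, 0.4, 0.2, lower = 0)

      r <- upd_sigma(sig_v, v_i, mu_v[iv]); sig_v <- r$sig
      acc["lsig"] <- acc["lsig"] + r$acc; rej["lsig"] <- rej["lsig"] + !r$acc
      r <- upd_sigma(sig_a, a_i, mu_a); sig_a <- r$sig
      r <- upd_sigma(sig_zl, zeta_i, mu_zl[iz]); sig_zl <- r$sig
      r <- upd_sigma(sig_t0, t0_i, mu_t0); sig_t0 <- r$sig

      if (zi) {
        prop <- gamma + step[["gamma"]] * rnorm(1)
        ll_new <- vapply(seq_len(ns), function(i) {
          ll_sub(prep$subs[[i]], v_i[i], a_i[i], zeta_i[i], t0_i[i], prop)
        }, numeric(1))
        lp <- sum(ll_new) + dnorm(prop, 0, 1, log = TRUE) -
          sum(cur_ll) - dnorm(gamma, 0, 1, log = TRUE)
        if (is.finite(lp) && log(runif(1)) < lp) {
          gamma <- prop
          cur_ll <- ll_new
          acc["gamma"] <- acc["gamma"] + 1
        } else rej["gamma"] <- rej["gamma"] + 1
      }

      if (it <= burnin && it %% 25 == 0) { # proposal adaptation
        for (w in names(step)) {
          tot <- acc[w] + rej[w]
          if (tot > 0) {
            rate <- acc[w] / tot
            step[w] <- step[w] * exp(min(0.25, 2 / sqrt(it / 25)) *
                                       (rate - 0.44))
          }
          acc[w] <- rej[w] <- 0
        }
      }

      if (it > burnin && (it - burnin) %% thin == 0) {
        kept <- kept + 1L
        keep[kept, ] <- c(mu_v, sig_v, mu_a, sig_a, mu_zl, sig_zl,
                          mu_t0, sig_t0, if (zi) gamma)
        dev[kept] <- -2 * sum(cur_ll)
        sub_sum <- sub_sum + cbind(v_i, a_i, zeta_i, t0_i)
      }
      if (progress && it %% 500 == 0) {
        message(sprintf("chain %d: iteration %d / %d", chain_id, it, n_iter))
      }
    }
    list(trace = keep, deviance = dev, sub_mean = sub_sum / draws)
  }

  res <- lapply(seq_len(chains), run_chain)
  traces <- lapply(res, `[[`, "trace")
  deviance <- lapply(res, `[[`, "deviance")
  sub_mean <- Reduce(`+`, lapply(res, `[[`, "sub_mean")) / chains
  gamma_mean <- if (zi) {
    mean(vapply(traces, function(m) mean(m[, "gamma_z_incentive"]), numeric(1)))
  } else 0
  dev_at_mean <- -2 * sum(vapply(seq_len(ns), function(i) {
    ll_sub(prep$subs[[i]], sub_mean[i, "v"], sub_mean[i, "a"],
           sub_mean[i, "zeta"], sub_mean[i, "t0"], gamma_mean)
  }, numeric(1)))
  dbar <- mean(unlist(deviance))
  pd <- dbar - dev_at_mean
  dic <- dbar + pd

  conv <- gelman_rubin(traces)
  converged <- all(conv$rhat < 1.01)
  if (!converged) {
    warning(sprintf("fit of %s flagged: max R-hat = %.3f (>= 1.01)",
                    spec$name, max(conv$rhat)))
  }

  structure(list(
    spec = spec, traces = traces, deviance = deviance,
    dbar = dbar, dev_at_mean = dev_at_mean, pd = pd, dic = dic,
    rhat = conv, converged = converged,
    subject_means = data.frame(participant_id = prep$ids,
                               v = sub_mean[, "v"], a = sub_mean[, "a"],
                               z = plogis(sub_mean[, "zeta"]),
                               t0 = sub_mean[, "t0"]),
    cells = list(v = levels(prep$cellv), z = levels(prep$cellz)),
    n_subjects = ns, n_trials = prep$n_trials,
    settings = list(chains = chains, draws = draws, burnin = burnin,
                    thin = thin, seed = seed)
  ), class = "hddm_fit")
}

#' @exportS3Method base::print
print.hddm_fit <- function(x, ...) {
  cat(sprintf(
    "Hierarchical DDM fit [%s]: %d subjects, %d trials\n  DIC = %.2f (Dbar = %.2f, pD = %.2f), max R-hat = %.4f%s\n",
    x$spec$name, x$n_subjects, x$n_trials, x$dic, x$dbar, x$pd,
    max(x$rhat$rhat), if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Pooled posterior traces
#'
#' @param fit an [fit_hddm()] result.
#' @return Matrix of posterior draws (chains concatenated) with one column
#'   per group-level parameter.
#' @export
parameter_traces <- function(fit) {
  stopifnot(inherits(fit, "hddm_fit"))
  do.call(rbind, fit$traces)
}

# condition-cell traces on the natural scale: drift (identity) or start
# point (logistic back-transform)
.cell_traces <- function(fit, param = c("v", "z")) {
  param <- match.arg(param)
  tr <- parameter_traces(fit)
  cells <- fit$cells[[param]]
  pre <- if (param == "v") "mu_v" else "mu_zlogit"
  cols <- if (length(cells) == 1 && cells == "all") pre
          else sprintf("%s[%s]", pre, cells)
  m <- tr[, cols, drop = FALSE]
  if (param == "z") m <- plogis(m)
  colnames(m) <- cells
  m
}

#' Posterior trace of the conflict effect on a parameter
#'
#' The per-iteration difference between the aligned and the conflict
#' condition mean of the parameter (averaged over fairness domains when the
#' model crosses both factors), on the natural scale. Positive values mean
#' the parameter is larger under aligned incentives. `NULL` when the model
#' does not let the parameter vary by conflict degree.
#'
#' @param fit an [fit_hddm()] result.
#' @param param `"v"` or `"z"`.
#' @return Numeric vector of posterior differences, or `NULL`.
#' @export
conflict_effect_trace <- function(fit, param = c("v", "z")) {
  param <- match.arg(param)
  covs <- fit$spec[[paste0(param, "_covariates")]]
  if (!"conflict_degree" %in% covs) return(NULL)
  m <- .cell_traces(fit, param)
  al <- grepl("^aligned", colnames(m))
  rowMeans(m[, al, drop = FALSE]) - rowMeans(m[, !al, drop = FALSE])
}

#' Posterior trace of the domain difference of the conflict effect
#'
#' The double difference (aligned - conflict in the punishment domain) minus
#' (aligned - conflict in the compensation domain). Requires a model in
#' which the parameter varies by both factors. `NULL` otherwise.
#'
#' @inheritParams conflict_effect_trace
#' @return Numeric vector of posterior double differences, or `NULL`.
#' @export
domain_difference_trace <- function(fit, param = c("v", "z")) {
  param <- match.arg(param)
  covs <- fit$spec[[paste0(param, "_covariates")]]
  if (!all(c("conflict_degree", "fairness_domain") %in% covs)) return(NULL)
  m <- .cell_traces(fit, param)
  (m[, "aligned_punishment"] - m[, "conflict_punishment"]) -
    (m[, "aligned_compensation"] - m[, "conflict_compensation"])
}

#' Write posterior traces to disk in long format
#'
#' One row per draw: `parameter`, `chain`, `iteration`, `value`. The
#' companion reader restores the per-chain trace matrices.
#'
#' @param fit an [fit_hddm()] result.
#' @param path CSV file path.
#' @return `write_traces` returns `path` invisibly; `read_traces` returns a
#'   list of chain matrices as in `fit$traces`.
#' @export
write_traces <- function(fit, path) {
  stopifnot(inherits(fit, "hddm_fit"))
  long <- do.call(rbind, lapply(seq_along(fit$traces), function(ch) {
    m <- fit$traces[[ch]]
    data.frame(parameter = rep(colnames(m), each = nrow(m)),
               chain = ch, iteration = rep(seq_len(nrow(m)), ncol(m)),
               value = as.vector(m), stringsAsFactors = FALSE)
  }))
  write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces
#' @export
read_traces <- function(path) {
  long <- read.csv(path, stringsAsFactors = FALSE)
  lapply(split(long, long$chain), function(d) {
    pars <- unique(d$parameter)
    m <- vapply(pars, function(p) d$value[d$parameter == p],
                numeric(sum(d$parameter == pars[1])))
    colnames(m) <- pars
    m
  })
}

#' Gelman-Rubin convergence diagnostic
#'
#' Split potential scale reduction factor: each chain is halved and the
#' standard R-hat is computed across the split chains for every parameter.
#'
#' @param traces list of chain matrices (iterations x parameters) with
#'   identical dimensions, or a list of numeric vectors for a single
#'   parameter.
#' @return Data.frame with columns `parameter` and `rhat`.
#' @export
gelman_rubin <- function(traces) {
  if (!is.list(traces) || length(traces) < 2) {
    stop("at least two chains are required")
  }
  if (is.null(dim(traces[[1]]))) {
    traces <- lapply(traces, function(x) matrix(x, ncol = 1,
                                                dimnames = list(NULL, "par")))
  }
  n <- nrow(traces[[1]])
  stopifnot(all(vapply(traces, nrow, integer(1)) == n))
  half <- floor(n / 2)
  splits <- unlist(lapply(traces, function(m) {
    list(m[seq_len(half), , drop = FALSE],
         m[(n - half + 1):n, , drop = FALSE])
  }), recursive = FALSE)
  pn <- colnames(traces[[1]])
  rhat <- vapply(seq_along(pn), function(j) {
    xs <- lapply(splits, function(m) m[, j])
    m <- length(xs)
    means <- vapply(xs, mean, numeric(1))
    vars <- vapply(xs, var, numeric(1))
    W <- mean(vars)
    B <- half * var(means)
    if (W < .Machine$double.eps) return(if (B < .Machine$double.eps) 1 else Inf)
    sqrt(((half - 1) / half * W + B / half) / W)
  }, numeric(1))
  data.frame(parameter = pn, rhat = rhat, stringsAsFactors = FALSE)
}

#' Geweke convergence z-score
#'
#' Compares the mean of the first `frac1` and the last `frac2` of a single
#' trace, with spectral-density-at-zero variance estimates from an AR fit.
#'
#' @param x numeric trace.
#' @param frac1,frac2 fractions of the trace compared (defaults 0.1 / 0.5).
#' @return z statistic (approximately standard normal under stationarity).
#' @export
geweke_z <- function(x, frac1 = 0.1, frac2 = 0.5) {
  n <- length(x)
  a <- x[seq_len(max(2, floor(frac1 * n)))]
  b <- x[(n - max(2, floor(frac2 * n)) + 1):n]
  s0 <- function(y) {
    if (var(y) < .Machine$double.eps) return(0)
    fit <- try(ar(y, aic = TRUE, order.max = min(20, length(y) - 2)),
               silent = TRUE)
    if (inherits(fit, "try-error") || length(fit$ar) == 0) return(var(y))
    fit$var.pred / (1 - sum(fit$ar))^2
  }
  se2 <- s0(a) / length(a) + s0(b) / length(b)
  if (se2 <= 0) return(0)
  (mean(a) - mean(b)) / sqrt(se2)
}
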