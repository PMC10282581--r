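#' Deviance information criterion
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`: the posterior mean
#' deviance plus the effective number of parameters, with the deviance
#' conditioned on the lowest-level (subject) parameters. Accepts either an
#' [fit_hddm()] result or raw components.
#'
#' @param fit an `hddm_fit`, or `NULL` when components are supplied.
#' @param deviance vector of per-draw deviances (when `fit` is `NULL`).
#' @param dev_at_mean deviance at the posterior mean of the parameters.
#' @return List with `dbar`, `dev_at_mean`, `pd`, `dic`.
#' @examples
#' compute_dic(deviance = c(10, 14), dev_at_mean = 11) # dic = 13
#' @export
compute_dic <- function(fit = NULL, deviance = NULL, dev_at_mean = NULL) {
  if (!is.null(fit)) {
    stopifnot(inherits(fit, "hddm_fit"))
    deviance <- unlist(fit$deviance)
    dev_at_mean <- fit$dev_at_mean
  }
  if (is.null(deviance) || length(deviance) == 0) {
    stop("an empty deviance trace cannot be summarised")
  }
  dbar <- mean(deviance)
  pd <- dbar - dev_at_mean
  list(dbar = dbar, dev_at_mean = dev_at_mean, pd = pd, dic = dbar + pd)
}

# model complexity = number of estimated condition cells beyond the null
.spec_complexity <- function(spec) {
  length(spec$v_covariates) + length(spec$z_covariates)
}

#' Select among fitted models by DIC
#'
#' Lower DIC wins. A more complex model is preferred outright only when its
#' DIC undercuts every competitor by at least 10; all models whose DIC lies
#' strictly within 10 of the minimum form a model-averaging set instead.
#' The result does not depend on the order the fits are supplied in.
#'
#' @param fits list of [fit_hddm()] results (>= 2).
#' @return A `model_selection` object: `table` (model, DIC, delta DIC,
#'   complexity), `winners` (labels of the selected / averaging set), and
#'   `averaged` (`TRUE` when more than one model was retained).
#' @export
select_model <- function(fits) {
  stopifnot(is.list(fits), length(fits) >= 2,
            all(vapply(fits, inherits, logical(1), "hddm_fit")))
  labs <- vapply(fits, function(f) f$spec$name, character(1))
  dic <- vapply(fits, `[[`, numeric(1), "dic")
  cx <- vapply(fits, function(f) .spec_complexity(f$spec), numeric(1))
  ord <- order(labs) # order-invariant output
  labs <- labs[ord]; dic <- dic[ord]; cx <- cx[ord]; fits <- fits[ord]
  delta <- dic - min(dic)
  winners <- labs[delta < 10]
  structure(list(
    table = data.frame(model = labs, dic = dic, delta_dic = delta,
                       complexity = cx, stringsAsFactors = FALSE),
    winners = winners,
    averaged = length(winners) > 1,
    fits = setNames(fits, labs)
  ), class = "model_selection")
}

#' @exportS3Method base::print
print.model_selection <- function(x, ...) {
  cat("DIC model comparison\n")
  print(x$table, row.names = FALSE)
  cat(if (x$averaged) "averaging set: " else "winning model: ",
      paste(x$winners, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Model-averaged posterior trace of a derived effect
#'
#' Pools posterior draws of a derived quantity across models with weights
#' proportional to `exp(-delta DIC / 2)`. A member model in which the
#' parameter does not vary contributes its implied null effect (a draw of
#' exactly zero). The pooled trace has the common member length.
#'
#' @param fits list of [fit_hddm()] results sharing equal trace lengths.
#' @param extract function mapping a fit to a numeric trace of the derived
#'   quantity, or `NULL` where the model has no such parameter (e.g.
#'   [conflict_effect_trace()]).
#' @return List with `trace` (pooled draws), `weights` (named, normalised)
#'   and `n_member` (draws available per member).
#' @export
average_models <- function(fits, extract) {
  stopifnot(is.list(fits), length(fits) >= 1)
  labs <- vapply(fits, function(f) f$spec$name, character(1))
  dic <- vapply(fits, `[[`, numeric(1), "dic")
  w <- exp(-(dic - min(dic)) / 2)
  w <- w / sum(w)
  member <- lapply(fits, extract)
  len <- unique(vapply(member[!vapply(member, is.null, logical(1))],
                       length, integer(1)))
  if (length(len) == 0) stop("no member carries the requested parameter")
  if (length(len) > 1) stop("member traces must have equal length")
  member <- lapply(member, function(tr) if (is.null(tr)) rep(0, len) else tr)
  if (length(fits) == 1) {
    return(list(trace = member[[1]], weights = setNames(1, labs),
                n_member = len))
  }
  pick <- sample.int(length(fits), len, replace = TRUE, prob = w)
  idx <- sample.int(len, len, replace = TRUE)
  pooled <- vapply(seq_len(len), function(i) member[[pick[i]]][idx[i]],
                   numeric(1))
  list(trace = pooled, weights = setNames(w, labs), n_member = len)
}

#' Posterior exceedance probability
#'
#' Fraction of paired posterior draws in which `trace_a` exceeds `trace_b`;
#' the directional "do the traces overlap" criterion, significant at the
#' 0.95 threshold.
#'
#' @param trace_a,trace_b equal-length numeric vectors of paired draws
#'   (pooled across chains). `trace_b` may be a scalar reference value.
#' @return Probability in `[0, 1]`.
#' @examples
#' exceedance(rnorm(1000, 1), rnorm(1000, 0))
#' @export
exceedance <- function(trace_a, trace_b = 0) {
  if (length(trace_b) == 1) trace_b <- rep(trace_b, length(trace_a))
  if (length(trace_a) != length(trace_b)) {
    stop("traces must have equal length")
  }
  mean(trace_a > trace_b)
}

#' Evaluate the directional hypotheses on the decision process
#'
#' Three posterior tests on the winning model(s) of a [select_model()]
#' result, each significant when the exceedance probability crosses 0.95:
#' * H4 — drift rate towards the congruent option is lower under conflicting
#'   incentives: requires a drift-rate (V) model in the winning set, tested
#'   as `P(v_aligned > v_conflict)`.
#' * H5 — the start point is shifted away from the congruent option under
#'   conflicting incentives: requires a start-point (Z) model in the winning
#'   set, tested as `P(z_aligned > z_conflict)`.
#' * H6 — the conflict effect differs between the fairness domains: requires
#'   V2 or Z2 in the winning set, tested as the double difference
#'   (aligned - conflict in punishment) - (aligned - conflict in
#'   compensation), significant in either direction.
#'
#' Traces are model-averaged over the winning set with DIC weights; members
#' without the parameter contribute a null effect. When no model in the
#' winning set carries the parameter at all, the hypothesis is reported as
#' not evaluable rather than false.
#'
#' @param selection a [select_model()] result.
#' @param threshold exceedance threshold (default 0.95).
#' @return Data.frame with columns `label`, `probability`, `gate` (was the
#'   required model type in the winning set), `evaluable`, `confirmed`.
#' @export
evaluate_hypotheses <- function(selection, threshold = 0.95) {
  stopifnot(inherits(selection, "model_selection"))
  win <- selection$fits[selection$winners]
  has <- function(fits, fun, param) {
    any(!vapply(fits, function(f) is.null(fun(f, param)), logical(1)))
  }
  one <- function(label, param, fun, gate, two_sided = FALSE) {
    evaluable <- has(win, fun, param)
    if (!evaluable) {
      return(data.frame(label = label, probability = NA_real_, gate = gate,
                        evaluable = FALSE, confirmed = NA,
                        stringsAsFactors = FALSE))
    }
    av <- average_models(win, function(f) fun(f, param))
    p <- exceedance(av$trace, 0)
    conf <- if (two_sided) {
      gate && (p > threshold || p < 1 - threshold)
    } else {
      gate && p > threshold
    }
    data.frame(label = label, probability = p, gate = gate,
               evaluable = TRUE, confirmed = conf, stringsAsFactors = FALSE)
  }
  v_gate <- any(grepl("^V", selection$winners))
  z_gate <- any(grepl("^Z", selection$winners))
  full_gate <- any(c("V2", "Z2") %in% selection$winners)
  h4 <- one("H4", "v", conflict_effect_trace, v_gate)
  h5 <- one("H5", "z", conflict_effect_trace, z_gate)
  h6 <- one("H6", if ("V2" %in% selection$winners) "v" else "z",
            domain_difference_trace, full_gate, two_sided = TRUE)
  rbind(h4, h5, h6)
}
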