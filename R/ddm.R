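#' Drift-diffusion parameter set
#'
#' Bundles the four parameters of the two-boundary Wiener diffusion model
#' with unit diffusion coefficient: drift rate `v` (evidence/s, positive
#' towards the upper boundary, which codes the fairness-congruent option),
#' boundary separation `a`, relative starting point `z` (fraction of `a`,
#' 0.5 = unbiased), and non-decision time `t0` (s).
#'
#' @param v drift rate (signed real).
#' @param a boundary separation, > 0.
#' @param z relative starting point, in (0, 1).
#' @param t0 non-decision time in seconds, >= 0.
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(v = 1, a = 2, z = 0.5, t0 = 0.3)
#' @export
ddm_params <- function(v, a, z = 0.5, t0 = 0.3) {
  stopifnot(is.numeric(v), is.numeric(a), is.numeric(z), is.numeric(t0),
            all(is.finite(c(v, a, z, t0))))
  if (any(a <= 0)) stop("boundary separation 'a' must be positive")
  if (any(z <= 0 | z >= 1)) stop("relative start 'z' must lie in (0, 1)")
  if (any(t0 < 0)) stop("non-decision time 't0' must be non-negative")
  structure(list(v = v, a = a, z = z, t0 = t0), class = "ddm_params")
}

#' @exportS3Method base::print
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: v = %.3f, a = %.3f, z = %.3f, t0 = %.3f\n",
              x$v, x$a, x$z, x$t0))
  invisible(x)
}

#' Probability of absorption at the upper boundary
#'
#' Closed-form probability that the diffusion is absorbed at the upper
#' (congruent) boundary before the lower one:
#' \deqn{P = \frac{1 - e^{-2 v z a}}{1 - e^{-2 v a}}}
#' with the driftless limit \eqn{P = z}. Serves as the analytic oracle for
#' the simulator and the density.
#'
#' @param params a [ddm_params] object.
#' @return Probability in (0, 1).
#' @examples
#' absorption_probability(ddm_params(v = 1, a = 2, z = 0.5))
#' @export
absorption_probability <- function(params) {
  stopifnot(inherits(params, "ddm_params"))
  v <- params$v; a <- params$a; z <- params$z
  if (abs(v) < 1e-12) return(z)
  # expm1 keeps the ratio stable for small |v * a|
  p <- expm1(-2 * v * z * a) / expm1(-2 * v * a)
  min(max(p, 0), 1)
}

#' Wiener first-passage-time density
#'
#' Density of the first passage at the named boundary at clock time `t`,
#' computed from the small-time and large-time series expansions with an
#' automatic switching rule (the expansion needing fewer terms at the
#' requested tolerance is used). For `t <= t0` the density is 0.
#'
#' @param t vector of clock times (s).
#' @param boundary `"upper"` or `"lower"` (recycled).
#' @param params a [ddm_params] object.
#' @param eps series truncation tolerance.
#' @param method `"auto"` (default), `"small"` or `"large"`: which series
#'   expansion to use; forcing one is intended for numerical checks only.
#' @return Vector of densities, same length as `t`.
#' @examples
#' p <- ddm_params(v = 1, a = 2, z = 0.5, t0 = 0.3)
#' wfpt_density(c(0.5, 1, 2), "upper", p)
#' @export
wfpt_density <- function(t, boundary, params, eps = 1e-7,
                         method = c("auto", "small", "large")) {
  stopifnot(inherits(params, "ddm_params"), is.numeric(t))
  method <- match.arg(method)
  boundary <- match.arg(boundary, c("upper", "lower"), several.ok = TRUE)
  n <- max(length(t), length(boundary))
  t <- rep_len(t, n)
  up <- as.integer(rep_len(boundary, n) == "upper")
  m <- c(auto = 0L, small = 1L, large = 2L)[[method]]
  wfpt_cpp(t, up, rep_len(params$v, n), rep_len(params$a, n),
           rep_len(params$z, n), rep_len(params$t0, n), eps, m)
}

#' Log-likelihood of a response dataset under condition-wise DDM parameters
#'
#' Sums the log first-passage density over trials, where `response = 1`
#' (congruent) maps to the upper boundary and `response = 0` to the lower.
#' Parameters may be supplied as one [ddm_params] for all trials, or as a
#' list of [ddm_params] indexed by a per-trial `condition` vector.
#'
#' Trials with `rt <= t0` have zero density; they contribute `-Inf` and
#' their indices are attached as attribute `"bad_trials"`.
#'
#' @param rt response times (s).
#' @param response binary congruence codes (1 = upper boundary).
#' @param params a [ddm_params] or a named list of them.
#' @param condition when `params` is a list: per-trial names into it.
#' @return Scalar log-likelihood (0 for an empty dataset), with attribute
#'   `"bad_trials"` listing any trials at or below `t0`.
#' @export
dataset_loglik <- function(rt, response, params, condition = NULL) {
  stopifnot(length(rt) == length(response), all(response %in% c(0, 1)))
  if (length(rt) == 0) return(0)
  if (inherits(params, "ddm_params")) {
    par_of <- function(i) params
    idx <- rep(1L, length(rt))
    plist <- list(params)
  } else {
    stopifnot(is.list(params), !is.null(condition),
              length(condition) == length(rt),
              all(condition %in% names(params)))
    plist <- params
    idx <- match(condition, names(params))
  }
  v <- vapply(plist, `[[`, numeric(1), "v")[idx]
  a <- vapply(plist, `[[`, numeric(1), "a")[idx]
  z <- vapply(plist, `[[`, numeric(1), "z")[idx]
  t0 <- vapply(plist, `[[`, numeric(1), "t0")[idx]
  d <- wfpt_cpp(rt, as.integer(response), v, a, z, t0, 1e-7, 0L)
  bad <- which(rt <= t0)
  ll <- sum(log(d))
  if (length(bad)) {
    ll <- -Inf
    warning(sprintf("%d trial(s) with rt <= t0 contribute -Inf", length(bad)))
  }
  attr(ll, "bad_trials") <- bad
  ll
}

#' Simulate first-passage times of the Wiener diffusion
#'
#' Euler–Maruyama simulation with a Brownian-bridge within-step crossing
#' correction, so that the discretisation bias is of order `dt` rather than
#' `sqrt(dt)`. Uses R's RNG stream, hence is reproducible under `set.seed()`.
#'
#' @param n number of paths.
#' @param params a [ddm_params] object.
#' @param dt Euler step (s).
#' @return A data.frame with columns `rt` (clock time incl. `t0`) and
#'   `boundary` (1 = upper, 0 = lower).
#' @examples
#' set.seed(1)
#' sim <- rwiener_fp(100, ddm_params(v = 1, a = 2))
#' mean(sim$boundary)
#' @export
rwiener_fp <- function(n, params, dt = 1e-3) {
  stopifnot(inherits(params, "ddm_params"), n >= 0, dt > 0)
  if (n == 0) return(data.frame(rt = numeric(0), boundary = integer(0)))
  out <- wiener_sim_cpp(as.integer(n), params$v, params$a, params$z,
                        params$t0, dt)
  data.frame(rt = out$rt, boundary = out$boundary)
}
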