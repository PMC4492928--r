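#' Retention functions for savings data
#'
#' Closed-form retention (forgetting) functions mapping a retention interval
#' to predicted savings \eqn{Q}. Savings is the relative amount of learning
#' effort saved at relearning, so \eqn{Q = 1} means perfect retention and
#' \eqn{Q = 0} no measurable retention.
#'
#' The family comprises:
#' \describe{
#'   \item{`eb1880`}{Ebbinghaus' 1880 double-power equation,
#'     \eqn{Q(t) = 1 - [1 - (2/t)^{a_1}]^{\mu_1}} with \eqn{t} in minutes.
#'     Defined only for \eqn{t > 2} min.}
#'   \item{`eb1885`}{Ebbinghaus' 1885 logarithmic equation,
#'     \eqn{Q(t) = \mu_1 / ((\log_{10} t)^{a_1} + \mu_1)} with \eqn{t} in
#'     minutes; \eqn{Q(1) = 1} exactly. Defined for \eqn{t \ge 1} min.}
#'   \item{`power`}{Two-parameter power function
#'     \eqn{Q(t) = \mu_1 (1 + t)^{-a_1}}, \eqn{t} in seconds. The `+ 1`
#'     keeps \eqn{Q(0) = \mu_1} finite; at the retention intervals of
#'     interest (\eqn{t \gg 1} s) it is indistinguishable from
#'     \eqn{\mu_1 t^{-a_1}}.}
#'   \item{`power_boost`}{The power function plus a constant upward jump
#'     ("boost") added to predicted savings for all intervals of one day and
#'     longer (\eqn{t \ge 86400} s, half-open convention), as used to
#'     quantify the 24-hour discontinuity often attributed to sleep.}
#'   \item{`summed_exp`}{Sum of two exponentials
#'     \eqn{Q(t) = \mu_1 e^{-a_1 t} + \mu_2 e^{-a_2 t}}, \eqn{t} in seconds.}
#'   \item{`mcm`}{The memory-chain (two-store consolidation) model:
#'     traces of initial strength \eqn{\mu_1} decay at rate \eqn{a_1} in a
#'     fast store while being copied at rate \eqn{\mu_2} into a slow store
#'     decaying at rate \eqn{a_2}:
#'     \eqn{Q(t) = \mu_1 e^{-a_1 t} + \mu_1\mu_2 (e^{-a_2 t} - e^{-a_1 t}) /
#'     (a_1 - a_2)}. Algebraically a reparameterized summed exponential (see
#'     [mcm_to_summed()]). When \eqn{|a_1 - a_2|} is numerically degenerate
#'     the analytic limit \eqn{\mu_1 e^{-a_1 t}(1 + \mu_2 t)} is used.}
#'   \item{`single_exp`}{\eqn{Q(t) = \mu_1 e^{-a_1 t}}, \eqn{t} in seconds.}
#'   \item{`power_printed`}{\eqn{Q(t) = (1 + \mu_1 t)^{-a_1}}: an alternative
#'     power parameterization that appears in parts of the literature. It is
#'     kept as a clearly labelled alternative; the published parameter
#'     estimates this package reproduces belong to the `power` form above,
#'     not to this one (evaluating this form at those estimates does not
#'     reproduce the published residual sums). It is excluded from
#'     [retention_models()]'s default comparison set.}
#' }
#'
#' All models are non-increasing in \eqn{t} for valid parameters
#' (\eqn{\mu_1 > 0}, \eqn{a_1 > 0}, and where present \eqn{\mu_2 > 0},
#' \eqn{a_2 \ge 0}, boost \eqn{\ge 0}).
#'
#' `retention_q()` is the unified evaluator: it takes time in seconds for
#' every model and converts to minutes internally for `eb1880`/`eb1885`.
#' The `q_*` functions evaluate each law in its native time unit.
#'
#' @param t_seconds retention interval(s) in seconds.
#' @param t_min retention interval(s) in minutes (for the 1880/1885 laws).
#' @param t_sec retention interval(s) in seconds.
#' @param model model name, one of `retention_models()$model` or
#'   `"power_printed"`.
#' @param pars named numeric vector of parameters (names as in
#'   `retention_models()`; order is also accepted).
#' @param mu1,a1,mu2,a2,boost model parameters.
#' @return Predicted savings, same length as the time vector.
#' @examples
#' q_eb1880(525, 0.523, 0.101)           # about 0.357
#' q_power(518400, 1.4, 0.13)            # about 0.253
#' retention_q("eb1885", 60 * 60, c(mu1 = 1.8, a1 = 1.21))
#' @name retention-models
NULL

# registry: one entry per model; fn takes time in the model's native unit
# and the parameter vector in registry order.
.retention_registry <- list(
  eb1880 = list(
    params = c("mu1", "a1"), unit = "min",
    lower = c(mu1 = 1e-3, a1 = 1e-3), upper = c(mu1 = 10, a1 = 5),
    fn = function(t, p) q_eb1880(t, p[[1]], p[[2]])
  ),
  eb1885 = list(
    params = c("mu1", "a1"), unit = "min",
    lower = c(mu1 = 1e-2, a1 = 1e-2), upper = c(mu1 = 20, a1 = 5),
    fn = function(t, p) q_eb1885(t, p[[1]], p[[2]])
  ),
  power = list(
    params = c("mu1", "a1"), unit = "sec",
    lower = c(mu1 = 1e-3, a1 = 1e-10), upper = c(mu1 = 10, a1 = 1),
    fn = function(t, p) q_power(t, p[[1]], p[[2]])
  ),
  power_boost = list(
    params = c("mu1", "a1", "boost"), unit = "sec",
    lower = c(mu1 = 1e-3, a1 = 1e-10, boost = 0),
    upper = c(mu1 = 10, a1 = 1, boost = 0.5),
    fn = function(t, p) q_power_boost(t, p[[1]], p[[2]], p[[3]])
  ),
  summed_exp = list(
    params = c("mu1", "a1", "mu2", "a2"), unit = "sec",
    lower = c(mu1 = 1e-3, a1 = 1e-10, mu2 = 0, a2 = 1e-10),
    upper = c(mu1 = 10, a1 = 1, mu2 = 10, a2 = 1),
    fn = function(t, p) q_summed_exp(t, p[[1]], p[[2]], p[[3]], p[[4]])
  ),
  mcm = list(
    params = c("mu1", "a1", "mu2", "a2"), unit = "sec",
    lower = c(mu1 = 1e-3, a1 = 1e-10, mu2 = 1e-10, a2 = 1e-10),
    upper = c(mu1 = 10, a1 = 1, mu2 = 1, a2 = 1),
    fn = function(t, p) q_mcm(t, p[[1]], p[[2]], p[[3]], p[[4]])
  ),
  single_exp = list(
    params = c("mu1", "a1"), unit = "sec",
    lower = c(mu1 = 1e-3, a1 = 1e-10), upper = c(mu1 = 10, a1 = 1),
    fn = function(t, p) q_single_exp(t, p[[1]], p[[2]])
  ),
  power_printed = list(
    params = c("mu1", "a1"), unit = "sec",
    lower = c(mu1 = 1e-10, a1 = 1e-10), upper = c(mu1 = 10, a1 = 1),
    fn = function(t, p) q_power_printed(t, p[[1]], p[[2]])
  )
)

.model_spec <- function(model) {
  spec <- .retention_registry[[match.arg(model, names(.retention_registry))]]
  spec$name <- model
  spec$k <- length(spec$params)
  spec
}

#' List the available retention models
#'
#' @param all if `TRUE`, include the alternative `power_printed`
#'   parameterization; by default only the seven canonical comparison models
#'   are listed.
#' @return A data frame with columns `model`, `k` (number of free
#'   parameters), `time_unit`, and `params` (comma-separated parameter
#'   names, in order).
#' @examples
#' retention_models()
#' @export
retention_models <- function(all = FALSE) {
  nm <- names(.retention_registry)
  if (!all) nm <- setdiff(nm, "power_printed")
  data.frame(
    model = nm,
    k = vapply(nm, function(m) length(.retention_registry[[m]]$params), 1L),
    time_unit = vapply(nm, function(m) .retention_registry[[m]]$unit, ""),
    params = vapply(nm, function(m)
      paste(.retention_registry[[m]]$params, collapse = ","), ""),
    row.names = NULL
  )
}

#' @rdname retention-models
#' @export
q_eb1880 <- function(t_min, mu1, a1) {
  if (any(t_min <= 2)) {
    stop("q_eb1880 is undefined for t <= 2 minutes ",
         "(the 2-minute singularity: (2/t)^a1 >= 1)", call. = FALSE)
  }
  1 - (1 - (2 / t_min)^a1)^mu1
}

#' @rdname retention-models
#' @export
q_eb1885 <- function(t_min, mu1, a1) {
  if (any(t_min < 1)) {
    stop("q_eb1885 is undefined for t < 1 minute ",
         "(log10 t < 0 raised to a non-integer power)", call. = FALSE)
  }
  mu1 / (log10(t_min)^a1 + mu1)
}

#' @rdname retention-models
#' @export
q_power <- function(t_sec, mu1, a1) {
  stopifnot(all(t_sec >= 0))
  mu1 * (1 + t_sec)^(-a1)
}

#' @rdname retention-models
#' @export
q_power_printed <- function(t_sec, mu1, a1) {
  stopifnot(all(t_sec >= 0))
  (1 + mu1 * t_sec)^(-a1)
}

#' @rdname retention-models
#' @export
q_power_boost <- function(t_sec, mu1, a1, boost) {
  q_power(t_sec, mu1, a1) + ifelse(t_sec >= 86400, boost, 0)
}

#' @rdname retention-models
#' @export
q_summed_exp <- function(t_sec, mu1, a1, mu2, a2) {
  stopifnot(all(t_sec >= 0))
  mu1 * exp(-a1 * t_sec) + mu2 * exp(-a2 * t_sec)
}

#' @rdname retention-models
#' @export
q_mcm <- function(t_sec, mu1, a1, mu2, a2) {
  stopifnot(all(t_sec >= 0))
  # a1 == a2 is a removable singularity; switch to the analytic limit when
  # the difference is below 1e-12 * max(a1, a2) to avoid catastrophic
  # cancellation (no visible discontinuity at this threshold).
  if (abs(a1 - a2) < 1e-12 * max(a1, a2)) {
    mu1 * exp(-a1 * t_sec) * (1 + mu2 * t_sec)
  } else {
    mu1 * exp(-a1 * t_sec) +
      mu1 * mu2 * (exp(-a2 * t_sec) - exp(-a1 * t_sec)) / (a1 - a2)
  }
}

#' @rdname retention-models
#' @export
q_single_exp <- function(t_sec, mu1, a1) {
  stopifnot(all(t_sec >= 0))
  mu1 * exp(-a1 * t_sec)
}

#' @rdname retention-models
#' @export
retention_q <- function(model, t_seconds, pars) {
  spec <- .model_spec(model)
  pars <- .check_pars(spec, pars)
  t <- if (spec$unit == "min") t_seconds / 60 else t_seconds
  spec$fn(t, pars)
}

# coerce a parameter vector to registry order, accepting names or position
.check_pars <- function(spec, pars) {
  pars <- unlist(pars)
  if (length(pars) != spec$k) {
    stop(sprintf("model '%s' takes %d parameters (%s), got %d",
                 spec$name, spec$k, paste(spec$params, collapse = ", "),
                 length(pars)), call. = FALSE)
  }
  if (!is.null(names(pars)) && all(nzchar(names(pars)))) {
    if (!setequal(names(pars), spec$params)) {
      stop(sprintf("parameter names must be {%s}",
                   paste(spec$params, collapse = ", ")), call. = FALSE)
    }
    pars <- pars[spec$params]
  } else {
    names(pars) <- spec$params
  }
  if (!all(is.finite(pars))) stop("parameters must be finite", call. = FALSE)
  pars
}

#' Map memory-chain-model parameters to summed-exponential coefficients
#'
#' The two-store memory-chain retention function is algebraically a summed
#' exponential with the same decay rates: collecting terms gives
#' coefficients \eqn{\beta_1 = \mu_1 (1 - \mu_2/(a_1 - a_2))} on
#' \eqn{e^{-a_1 t}} and \eqn{\beta_2 = \mu_1 \mu_2 / (a_1 - a_2)} on
#' \eqn{e^{-a_2 t}}. This is why least-squares fits of the two models attain
#' identical residual sums while reporting different parameters.
#'
#' @param mu1,a1,mu2,a2 memory-chain parameters: initial strength and decay
#'   rate of the fast store, consolidation rate, decay rate of the slow
#'   store (rates per second).
#' @return Named vector `c(beta1, beta2)`; the decay rates carry over
#'   unchanged, so `q_summed_exp(t, beta1, a1, beta2, a2)` equals
#'   `q_mcm(t, mu1, a1, mu2, a2)` for all `t`.
#' @examples
#' mcm_to_summed(0.704, 0.000319, 0.000145, 1.79e-7)
#' @export
mcm_to_summed <- function(mu1, a1, mu2, a2) {
  if (a1 == a2) {
    stop("a1 == a2: degenerate parameterization, no two-exponential form",
         call. = FALSE)
  }
  c(beta1 = mu1 * (1 - mu2 / (a1 - a2)), beta2 = mu1 * mu2 / (a1 - a2))
}
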