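#' Goodness-of-fit metrics for retention models
#'
#' The three statistics used to compare retention models on a savings
#' curve:
#' \describe{
#'   \item{SSD}{sum of squared differences between observed and predicted
#'     savings, \eqn{\sum_i (Q_i - Q(t_i))^2} — the quantity the fits
#'     minimize (unweighted).}
#'   \item{uncentered R²}{\eqn{1 - SSD / \sum_i Q_i^2}, variance explained
#'     relative to the raw (not mean-centered) observations.}
#'   \item{AIC}{Gaussian-likelihood Akaike information criterion with the
#'     error variance counted as a free parameter,
#'     \eqn{AIC = n \ln(2\pi\, SSD/n) + n + 2(k + 1)}. Differences greater
#'     than 2 are conventionally treated as meaningful.}
#' }
#'
#' @param curve a [savings_curve()] (or coercible data frame).
#' @param model model name (see [retention_models()]).
#' @param pars parameter vector for `model`.
#' @param ssd sum of squared deviations.
#' @param n number of data points.
#' @param k number of free model parameters (excluding the error variance,
#'   which the formula adds internally).
#' @return A single numeric value.
#' @examples
#' eb <- load_fixture("table3")$Ebbinghaus
#' s <- retention_ssd(eb, "summed_exp", c(0.383, 0.000319, 0.321, 1.79e-7))
#' r2_uncentered(eb, s)
#' aic_gaussian(s, n = 7, k = 4)
#' @export
retention_ssd <- function(curve, model, pars) {
  curve <- as_savings_curve(curve)
  sum((curve$savings - retention_q(model, curve$t_seconds, pars))^2)
}

#' @rdname retention_ssd
#' @export
r2_uncentered <- function(curve, ssd) {
  curve <- as_savings_curve(curve)
  ss_tot <- sum(curve$savings^2)
  if (ss_tot == 0) {
    stop("all savings are zero; uncentered R^2 undefined", call. = FALSE)
  }
  1 - ssd / ss_tot
}

#' @rdname retention_ssd
#' @export
aic_gaussian <- function(ssd, n, k) {
  stopifnot(ssd >= 0, n > 0, k >= 1)
  if (ssd == 0) {
    warning("SSD is zero; AIC is -Inf")
    return(-Inf)
  }
  n * log(2 * pi * ssd / n) + n + 2 * (k + 1)
}

# run thunk with a local, restored RNG state
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Fit a retention model to a savings curve
#'
#' Bounded nonlinear least squares with multiple random restarts.
#' Levenberg–Marquardt minimization (via [minpack.lm::nls.lm()]) is run
#' from `n_starts` log-uniform draws within the parameter bounds (uniform
#' draws for parameters whose lower bound is 0, such as the boost), and the
#' start reaching the smallest sum of squared deviations wins; exact ties
#' are broken toward the lexicographically smallest parameter vector so
#' results are reproducible. The restarts guard against the multi-modal
#' likelihoods of the summed-exponential family.
#'
#' Times are always supplied in seconds; models whose native unit is
#' minutes (`eb1880`, `eb1885`) are converted internally, and their fitted
#' parameters refer to time in minutes.
#'
#' For the `summed_exp` model the two exponential components are
#' interchangeable; the fitted parameters are reported with the faster
#' decay first (`a1 >= a2`).
#'
#' @param curve a [savings_curve()] or coercible data frame.
#' @param model model name, one of `retention_models(all = TRUE)$model`.
#' @param n_starts number of random restarts (default 50).
#' @param seed integer seed controlling the restart draws (default 0). With
#'   enough restarts the optimum is invariant to the seed.
#' @param lower,upper optional named vectors overriding the default
#'   per-parameter bounds.
#' @return An object of class `retention_fit`: a list with elements
#'   `model`, `par` (named), `ssd`, `r2`, `aic`, `n`, `k`, `n_starts`,
#'   `n_converged`, `seed`, `curve`, and `call`. Methods: `print`,
#'   `summary`, `coef`, `fitted`, `residuals`, `predict`, `deviance`,
#'   `logLik` (so [stats::AIC()] agrees with `$aic`), `plot`, `simulate`.
#' @examples
#' eb <- load_fixture("table3")$Ebbinghaus
#' fit <- fit_retention(eb, "power")
#' coef(fit)
#' predict(fit, t_seconds = 3600)
#' @export
fit_retention <- function(curve, model = "power", n_starts = 50, seed = 0,
                          lower = NULL, upper = NULL) {
  curve <- as_savings_curve(curve)
  spec <- .model_spec(model)
  n <- nrow(curve)
  if (n < spec$k) {
    stop(sprintf("under-determined: %d points but model '%s' has %d parameters",
                 n, model, spec$k), call. = FALSE)
  }
  lo <- spec$lower
  up <- spec$upper
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) up[names(upper)] <- upper

  t <- if (spec$unit == "min") curve$t_seconds / 60 else curve$t_seconds
  if (model == "eb1880" && any(t <= 2)) {
    stop("eb1880 requires all intervals > 2 minutes", call. = FALSE)
  }
  if (model == "eb1885" && any(t < 1)) {
    stop("eb1885 requires all intervals >= 1 minute", call. = FALSE)
  }
  q <- curve$savings
  resid_fn <- function(p) q - spec$fn(t, p)

  starts <- with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      p0 <- numeric(spec$k)
      for (j in seq_len(spec$k)) {
        p0[j] <- if (lo[[j]] > 0) {
          exp(stats::runif(1, log(lo[[j]]), log(up[[j]])))
        } else {
          stats::runif(1, lo[[j]], up[[j]])
        }
      }
      p0
    })
  })

  best <- NULL
  n_conv <- 0L
  for (p0 in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = p0, lower = unname(lo), upper = unname(up),
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL)
    if (is.null(res)) next
    n_conv <- n_conv + 1L
    ssd_i <- sum(res$fvec^2)
    if (is.null(best) || ssd_i < best$ssd - 1e-14 ||
        (abs(ssd_i - best$ssd) <= 1e-14 && .lex_less(res$par, best$par))) {
      best <- list(par = res$par, ssd = ssd_i)
    }
  }
  if (is.null(best)) {
    stop(sprintf("no start converged for model '%s' (%d attempted)",
                 model, n_starts), call. = FALSE)
  }

  par <- best$par
  names(par) <- spec$params
  if (model == "summed_exp" && par[["a2"]] > par[["a1"]]) {
    par <- par[c("mu2", "a2", "mu1", "a1")]
    names(par) <- spec$params
  }
  ssd <- retention_ssd(curve, model, par)
  structure(list(
    model = model, par = par,
    ssd = ssd,
    r2 = r2_uncentered(curve, ssd),
    aic = aic_gaussian(ssd, n, spec$k),
    n = n, k = spec$k,
    n_starts = n_starts, n_converged = n_conv, seed = seed,
    curve = curve, call = match.call()
  ), class = "retention_fit")
}

.lex_less <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(TRUE)
    if (a[i] > b[i]) return(FALSE)
  }
  FALSE
}

#' @export
print.retention_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Retention model '%s' fitted to '%s' (n = %d)\n",
              x$model, attr(x$curve, "subject"), x$n))
  cat("  parameters:",
      paste(sprintf("%s = %s", names(x$par), signif(x$par, digits)),
            collapse = ", "),
      sprintf("(time in %s)\n", .model_spec(x$model)$unit))
  cat(sprintf("  SSD = %s   R2 = %s   AIC = %s\n",
              signif(x$ssd, digits), signif(x$r2, digits),
              signif(x$aic, digits + 1)))
  invisible(x)
}

#' @export
summary.retention_fit <- function(object, ...) {
  res <- residuals(object)
  out <- list(fit = object, residuals = res,
              sigma = sqrt(object$ssd / (object$n - object$k)))
  class(out) <- "summary.retention_fit"
  out
}

#' @export
print.summary.retention_fit <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  residual sd (n - k): %s; converged starts: %d/%d; seed %s\n",
              signif(x$sigma, digits), x$fit$n_converged, x$fit$n_starts,
              x$fit$seed))
  cat("  residuals:\n")
  print(data.frame(interval = format_interval(x$fit$curve$t_seconds),
                   observed = x$fit$curve$savings,
                   fitted = fitted(x$fit),
                   residual = signif(x$residuals, digits)),
        row.names = FALSE)
  invisible(x)
}

#' @export
coef.retention_fit <- function(object, ...) object$par

#' @export
deviance.retention_fit <- function(object, ...) object$ssd

#' @export
logLik.retention_fit <- function(object, ...) {
  ll <- -object$n / 2 * (log(2 * pi * object$ssd / object$n) + 1)
  structure(ll, df = object$k + 1, nobs = object$n, class = "logLik")
}

#' @export
fitted.retention_fit <- function(object, ...) {
  retention_q(object$model, object$curve$t_seconds, object$par)
}

#' @export
residuals.retention_fit <- function(object, ...) {
  object$curve$savings - fitted(object)
}

#' @export
predict.retention_fit <- function(object, t_seconds = NULL, ...) {
  if (is.null(t_seconds)) return(fitted(object))
  retention_q(object$model, t_seconds, object$par)
}

#' @export
plot.retention_fit <- function(x, n_grid = 200, ...) {
  cu <- x$curve
  tr <- range(cu$t_seconds)
  grid <- exp(seq(log(tr[1]), log(tr[2]), length.out = n_grid))
  if (x$model == "power_boost") {
    grid <- sort(c(grid, 86400 - 1e-6, 86400))
  }
  graphics::plot(cu$t_seconds / 86400, cu$savings, log = "x",
                 xlab = "retention interval (days)", ylab = "savings",
                 main = sprintf("%s: %s fit", attr(cu, "subject"), x$model),
                 pch = 19, ylim = range(0, cu$savings, 1), ...)
  graphics::lines(grid / 86400, predict(x, grid), col = "steelblue")
  invisible(x)
}

#' @export
simulate.retention_fit <- function(object, nsim = 1, seed = NULL, ...) {
  sd <- sqrt(object$ssd / object$n)
  mu <- fitted(object)
  gen <- function() mu + stats::rnorm(object$n, 0, sd)
  sims <- if (is.null(seed)) {
    replicate(nsim, gen())
  } else {
    with_seed(seed, replicate(nsim, gen()))
  }
  out <- as.data.frame(matrix(sims, nrow = object$n))
  names(out) <- paste0("sim_", seq_len(nsim))
  cbind(data.frame(t_seconds = object$curve$t_seconds), out)
}
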