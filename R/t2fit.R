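#' Fit a mono-exponential T2 decay to a multi-echo magnitude series
#'
#' The central estimator of the package. Fits \eqn{S(TE) = S_0 e^{-TE/T_2}}
#' to a single pixel's (or ROI's) magnitude series by one of three methods:
#' \describe{
#'   \item{`"mle"`}{maximum likelihood under the Rician / noncentral-chi
#'     magnitude noise law ([t2_loglik()]). This is the estimator used for
#'     map generation: at low SNR magnitude data have a noise floor that
#'     ordinary least squares mistakes for slow decay, and the likelihood
#'     model removes that bias. Initialized from the log-linear fit and
#'     refined by bounded quasi-Newton optimization; the returned optimum is
#'     never worse than its initializer.}
#'   \item{`"lsq_log"`}{unweighted linear regression of `log(m)` on TE.}
#'   \item{`"lsq_nonlinear"`}{nonlinear least squares on the exponential.}
#' }
#'
#' @param series magnitude values, one per echo (>= 2).
#' @param echo_times echo times (ms) aligned with `series`.
#' @param noise a [noise_model()]; required for `"mle"`.
#' @param method fitting method.
#' @param t2_bounds search bounds for T2 (ms); default `c(1, 1000)`. The
#'   upper bound doubles as the display/physical ceiling recorded in maps.
#' @return An object of class `"t2fit"` with components `coefficients`
#'   (named `s0`, `t2`), `method`, `converged`, `series`, `echo_times`,
#'   `noise`, `logLik` (MLE only) and `init` (the initializing estimate).
#'   All-zero input yields a non-converged fit, not an error.
#' @seealso [fit_map()] to run the fitter over an image,
#'   [fit_cpmg()] for the dense reference fit.
#' @export
#' @examples
#' te <- echo_times(grase_preset("6Ec"))
#' m <- 100 * exp(-te / 52)
#' coef(t2_fit(m, te, noise_model(1e-6), method = "mle"))
t2_fit <- function(series, echo_times,
                   noise = NULL,
                   method = c("mle", "lsq_log", "lsq_nonlinear"),
                   t2_bounds = c(1, 1000)) {
  method <- match.arg(method)
  if (length(series) != length(echo_times))
    stop("series and echo_times must have the same length")
  if (length(series) < 2L) stop("need at least 2 echoes")
  if (any(series < 0)) stop("magnitudes must be non-negative")
  if (method == "mle" && is.null(noise))
    stop("method 'mle' requires a noise_model (sigma, n_channels)")

  fit <- switch(method,
    lsq_log = fit_lsq_log(series, echo_times, t2_bounds),
    lsq_nonlinear = fit_lsq_nonlinear(series, echo_times, t2_bounds),
    mle = fit_mle(series, echo_times, noise, t2_bounds))

  out <- list(coefficients = fit$coefficients, method = method,
              converged = fit$converged, series = series,
              echo_times = echo_times, noise = noise,
              logLik = fit$logLik, init = fit$init,
              t2_bounds = t2_bounds)
  class(out) <- "t2fit"
  out
}

# log-linear fit; magnitudes may be floored by the caller
fit_lsq_log <- function(series, echo_times, t2_bounds, floor = 0) {
  m <- pmax(series, floor)
  if (any(m <= 0)) {
    return(list(coefficients = c(s0 = NA_real_, t2 = NA_real_),
                converged = FALSE, logLik = NULL, init = NULL))
  }
  cf <- stats::lm.fit(cbind(1, echo_times), log(m))$coefficients
  t2 <- if (cf[2L] < 0) -1 / cf[2L] else t2_bounds[2L]
  t2 <- min(max(t2, t2_bounds[1L]), t2_bounds[2L])
  list(coefficients = c(s0 = unname(exp(cf[1L])), t2 = unname(t2)),
       converged = cf[2L] < 0, logLik = NULL, init = NULL)
}

fit_lsq_nonlinear <- function(series, echo_times, t2_bounds) {
  init <- fit_lsq_log(series, echo_times, t2_bounds,
                      floor = 1e-6 * max(series, 1e-12))
  start <- init$coefficients
  if (anyNA(start) || start[["s0"]] <= 0)
    start <- c(s0 = max(series), t2 = mean(t2_bounds) / 10)
  df <- data.frame(m = series, te = echo_times)
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ s0 * exp(-te / t2), data = df,
                      start = as.list(start),
                      lower = c(0, t2_bounds[1L]),
                      upper = c(Inf, t2_bounds[2L]),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    return(list(coefficients = start, converged = FALSE, logLik = NULL,
                init = start))
  }
  cf <- stats::coef(fit)
  list(coefficients = c(s0 = unname(cf[["s0"]]), t2 = unname(cf[["t2"]])),
       converged = TRUE, logLik = NULL, init = start)
}

fit_mle <- function(series, echo_times, noise, t2_bounds) {
  if (all(series == 0)) {
    return(list(coefficients = c(s0 = 0, t2 = NA_real_), converged = FALSE,
                logLik = NULL, init = NULL))
  }
  # robust cheap start: log-linear fit with magnitudes floored at sigma/2
  init <- fit_lsq_log(series, echo_times, t2_bounds, floor = noise$sigma / 2)
  start <- init$coefficients
  s0_hi <- 2 * max(series)
  start[["s0"]] <- min(max(start[["s0"]], 1e-9), s0_hi)
  nll <- function(par) -t2_loglik(series, echo_times, par[1L], par[2L], noise)
  opt <- tryCatch(
    stats::optim(c(start[["s0"]], start[["t2"]]), nll, method = "L-BFGS-B",
                 lower = c(1e-9, t2_bounds[1L]),
                 upper = c(s0_hi, t2_bounds[2L])),
    error = function(e) NULL)
  if (is.null(opt) || opt$value > nll(c(start[["s0"]], start[["t2"]])) + 1e-9) {
    # never degrade the initializer
    cf <- c(s0 = start[["s0"]], t2 = start[["t2"]])
    ll <- -nll(c(start[["s0"]], start[["t2"]]))
    return(list(coefficients = cf, converged = FALSE, logLik = ll,
                init = start))
  }
  list(coefficients = c(s0 = opt$par[1L], t2 = opt$par[2L]),
       converged = opt$convergence == 0L, logLik = -opt$value, init = start)
}

#' @export
print.t2fit <- function(x, ...) {
  cat(sprintf("T2 fit (%s): T2 = %.2f ms, S0 = %.2f%s\n", x$method,
              x$coefficients[["t2"]], x$coefficients[["s0"]],
              if (x$converged) "" else "  [not converged]"))
  invisible(x)
}

#' @export
summary.t2fit <- function(object, ...) {
  r <- stats::residuals(object)
  structure(list(fit = object, rmse = sqrt(mean(r^2)),
                 n_echoes = length(object$series)),
            class = "summary.t2fit")
}

#' @export
print.summary.t2fit <- function(x, ...) {
  print(x$fit)
  cat(sprintf("  %d echoes spanning %.1f-%.1f ms; residual RMSE %.4g\n",
              x$n_echoes, min(x$fit$echo_times), max(x$fit$echo_times),
              x$rmse))
  if (!is.null(x$fit$logLik))
    cat(sprintf("  log-likelihood %.4f\n", x$fit$logLik))
  if (!is.null(x$fit$noise)) print(x$fit$noise)
  invisible(x)
}

#' @export
coef.t2fit <- function(object, ...) object$coefficients

#' @export
logLik.t2fit <- function(object, ...) {
  ll <- object$logLik
  if (is.null(ll)) {
    if (is.null(object$noise))
      stop("log-likelihood needs a noise model; refit with method = 'mle' or supply noise")
    ll <- t2_loglik(object$series, object$echo_times,
                    object$coefficients[["s0"]], object$coefficients[["t2"]],
                    object$noise)
  }
  structure(ll, df = 2L, nobs = length(object$series), class = "logLik")
}

#' Predicted signal of a fitted T2 decay
#'
#' @param object a `t2fit`.
#' @param newdata optional echo times (ms); defaults to the fit's.
#' @param type `"decay"` for the noiseless decay curve
#'   `s0 * exp(-TE / t2)`; `"expected"` for the expected observed magnitude
#'   `E[m | a]` under the fit's noise model (includes the noise floor),
#'   computed by numerical quadrature.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.t2fit <- function(object, newdata = NULL,
                          type = c("decay", "expected"), ...) {
  type <- match.arg(type)
  te <- if (is.null(newdata)) object$echo_times else newdata
  a <- object$coefficients[["s0"]] * exp(-te / object$coefficients[["t2"]])
  if (type == "decay") return(a)
  if (is.null(object$noise))
    stop("type = 'expected' needs the fit's noise model")
  vapply(a, function(ai) ncchi_mean(ai, object$noise), numeric(1L))
}

# E[m | a] under the noncentral-chi law, by quadrature
ncchi_mean <- function(a, noise) {
  up <- a + 10 * noise$sigma * sqrt(noise$n_channels)
  stats::integrate(function(m) m * dncchi(m, a, noise), 0, up,
                   rel.tol = 1e-8)$value
}

#' @export
residuals.t2fit <- function(object, ...) {
  object$series - predict(object)
}

#' Simulate replicate magnitude series from a fitted decay
#'
#' Draws noisy multi-echo series from the fitted `(s0, t2)` decay under the
#' fit's noise model; useful for parametric-bootstrap uncertainty.
#'
#' @param object a `t2fit` carrying a noise model.
#' @param nsim number of replicate series.
#' @param seed optional RNG seed (restores the RNG state on exit).
#' @param ... unused.
#' @return A matrix with `nsim` rows, one column per echo.
#' @export
simulate.t2fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (is.null(object$noise)) stop("simulate needs the fit's noise model")
  if (!is.null(seed)) {
    old <- get_rng_state()
    on.exit(restore_rng_state(old))
    set.seed(seed)
  }
  a <- predict(object)
  t(vapply(seq_len(nsim),
           function(i) rncchi(length(a), a, object$noise),
           numeric(length(a))))
}

#' @export
plot.t2fit <- function(x, ...) {
  te <- x$echo_times
  graphics::plot(te, x$series, xlab = "echo time (ms)", ylab = "magnitude",
                 pch = 16, ...)
  tt <- seq(0, max(te) * 1.05, length.out = 200)
  graphics::lines(tt, x$coefficients[["s0"]] * exp(-tt / x$coefficients[["t2"]]))
  graphics::legend("topright", bty = "n",
                   legend = sprintf("T2 = %.1f ms (%s)",
                                    x$coefficients[["t2"]], x$method))
  invisible(x)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}
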