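#' Fit a T2 map over a multi-echo stack
#'
#' Applies the per-pixel fitter ([t2_fit()]) to every pixel of the stack (or
#' to the pixels of `mask` if given). Fitting is deterministic: no RNG is
#' involved and the result is independent of pixel visiting order. Pixels
#' where the maximum-likelihood optimizer fails fall back to nonlinear least
#' squares and are flagged in `converged`; non-fitted pixels carry T2 = 0
#' (0 is reserved for "not fitted"; fitted values live in
#' `[t2_bounds[1], t2_bounds[2]]`).
#'
#' @param stack a [multi_echo_stack()]; for `method = "mle"` it must carry a
#'   noise model (or supply `noise`).
#' @param mask optional logical matrix of pixels to fit (same shape as one
#'   echo image).
#' @param method fitting method, as in [t2_fit()].
#' @param noise optional [noise_model()] overriding the stack's.
#' @param t2_bounds T2 search bounds (ms).
#' @return An object of class `t2map`: matrices `t2`, `s0`, `converged`
#'   and `fitted`, plus `method`, `noise`, `protocol`, `t2_bounds`.
#' @export
fit_map <- function(stack, mask = NULL, method = c("mle", "lsq_log",
                                                   "lsq_nonlinear"),
                    noise = NULL, t2_bounds = c(1, 1000)) {
  method <- match.arg(method)
  stopifnot(inherits(stack, "multi_echo_stack"))
  d <- dim(stack$volumes)
  if (is.null(mask)) {
    mask <- matrix(TRUE, d[1L], d[2L])
  } else {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == d[1:2]))
      stop("mask shape does not match the image shape")
    mask <- mask & !is.na(mask)
  }
  if (is.null(noise)) noise <- stack$noise
  if (method == "mle" && is.null(noise))
    stop("method 'mle' needs a noise model (stack$noise or the noise argument)")

  t2 <- matrix(0, d[1L], d[2L])
  s0 <- matrix(0, d[1L], d[2L])
  conv <- matrix(FALSE, d[1L], d[2L])
  idx <- which(mask)
  te <- stack$echo_times
  nv <- matrix(stack$volumes, d[1L] * d[2L], d[3L])
  for (i in idx) {
    series <- nv[i, ]
    if (all(series == 0)) next     # stays non-fitted (t2 = 0)
    fit <- t2_fit(series, te, noise = noise, method = method,
                  t2_bounds = t2_bounds)
    if (method == "mle" && !fit$converged) {
      fb <- t2_fit(series, te, noise = noise, method = "lsq_nonlinear",
                   t2_bounds = t2_bounds)
      if (fb$converged) fit <- fb
    }
    cf <- fit$coefficients
    if (!is.na(cf[["t2"]])) {
      t2[i] <- cf[["t2"]]
      s0[i] <- cf[["s0"]]
      conv[i] <- fit$converged
    }
  }
  structure(list(t2 = t2, s0 = s0, converged = conv, fitted = mask,
                 method = method, noise = noise, protocol = stack$protocol,
                 t2_bounds = t2_bounds),
            class = "t2map")
}

#' @export
print.t2map <- function(x, ...) {
  n_fit <- sum(x$fitted)
  v <- x$t2[x$fitted & x$converged]
  cat(sprintf("T2 map (%s): %d x %d pixels, %d fitted, %d converged\n",
              x$method, nrow(x$t2), ncol(x$t2), n_fit,
              sum(x$converged)))
  if (length(v))
    cat(sprintf("  converged T2: median %.1f ms, IQR [%.1f, %.1f] ms\n",
                stats::median(v), stats::quantile(v, 0.25),
                stats::quantile(v, 0.75)))
  invisible(x)
}

#' @export
plot.t2map <- function(x, zlim = c(0, 120), ...) {
  img <- t(x$t2[nrow(x$t2):1, , drop = FALSE])
  graphics::image(img, zlim = zlim, col = grDevices::hcl.colors(64, "viridis"),
                  axes = FALSE, asp = ncol(x$t2) / nrow(x$t2),
                  main = sprintf("T2 map (%s), ms", x$method), ...)
  invisible(x)
}
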