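#' Fit a dense CPMG reference series
#'
#' Mono-exponential fit of a densely sampled multi-echo (CPMG-like) series,
#' used as the reference ("gold standard") T2 against which GraSE estimates
#' are benchmarked. By default a nonlinear least-squares fit; with a noise
#' model, maximum likelihood.
#'
#' @param series magnitudes of the dense echo train (>= 8 echoes).
#' @param echo_times echo times (ms).
#' @param noise optional [noise_model()] to fit by maximum likelihood.
#' @return A `t2fit` object.
#' @export
fit_cpmg <- function(series, echo_times, noise = NULL) {
  if (length(series) < 8L)
    stop("a CPMG reference fit needs a dense train (>= 8 echoes)")
  method <- if (is.null(noise)) "lsq_nonlinear" else "mle"
  t2_fit(series, echo_times, noise = noise, method = method)
}

#' Simulated CPMG reference echo train
#'
#' Ideal 180-degree refocusing, dense sampling: `n_echoes` echoes spaced
#' `delta_te` ms. Returns the noiseless normalized train
#' `exp(-TE_k / t2)` with its echo times.
#'
#' @param t2 transverse relaxation time (ms).
#' @param n_echoes number of echoes (default 32).
#' @param delta_te echo spacing (ms, default 10).
#' @return List with `echo_times` and `amplitudes`.
#' @export
cpmg_reference_train <- function(t2, n_echoes = 32L, delta_te = 10) {
  te <- delta_te * seq_len(n_echoes)
  list(echo_times = te, amplitudes = exp(-te / t2))
}

#' Agreement between GraSE and reference T2 values
#'
#' Pearson correlation and ordinary least-squares line (GraSE on reference)
#' for paired per-compartment T2 estimates. A slope above 1 with high R
#' indicates a systematic overestimation, the signature of stimulated-echo
#' contamination.
#'
#' @param grase_t2 GraSE-derived T2 per compartment (ms).
#' @param reference_t2 reference T2 per compartment (ms), same length >= 3.
#' @return List with `pearson_r`, `slope`, `intercept`, `n`.
#' @export
method_agreement <- function(grase_t2, reference_t2) {
  if (length(grase_t2) != length(reference_t2))
    stop("paired inputs must have equal length")
  if (length(grase_t2) < 3L) stop("need at least 3 paired compartments")
  if (stats::sd(grase_t2) == 0 || stats::sd(reference_t2) == 0)
    stop("zero-variance input: correlation undefined")
  cf <- stats::coef(stats::lm(grase_t2 ~ reference_t2))
  list(pearson_r = stats::cor(grase_t2, reference_t2),
       slope = unname(cf[2L]), intercept = unname(cf[1L]),
       n = length(grase_t2))
}
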