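#' Bland-Altman agreement of paired measurements
#'
#' Mean paired difference with 95\% limits of agreement
#' (mean difference +/- 1.96 x SD of the differences, sample SD with n - 1)
#' and the Pearson correlation of the paired values. The 1.96 multiplier and
#' the sample-SD convention are the standard Bland-Altman choices.
#'
#' @param x,y paired measurements (same length >= 3), e.g. global myocardial
#'   T2 per subject at two visits or from two readers.
#' @return An object of class `bland_altman` with `mean_diff`, `loa_low`,
#'   `loa_high`, `sd_diff`, `pearson_r` (NA with a flag if either input has
#'   zero variance), `n`.
#' @export
#' @examples
#' ba <- bland_altman(c(50, 52, 54, 56), c(51, 51, 55, 55))
#' ba$loa_high   # 1.96 * sd of differences
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have the same length")
  if (length(x) < 3L) stop("need at least 3 pairs")
  d <- x - y
  md <- mean(d)
  sdd <- stats::sd(d)
  r <- if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_ else
    stats::cor(x, y)
  structure(list(mean_diff = md, loa_low = md - 1.96 * sdd,
                 loa_high = md + 1.96 * sdd, sd_diff = sdd,
                 pearson_r = r, n = length(x)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): mean difference %.2f, 95%% LoA [%.2f; %.2f]\n",
              x$n, x$mean_diff, x$loa_low, x$loa_high))
  if (is.na(x$pearson_r)) cat("  Pearson R undefined (zero variance)\n")
  else cat(sprintf("  Pearson R = %.3f\n", x$pearson_r))
  invisible(x)
}

#' @export
plot.bland_altman <- function(x, pairs = NULL, ...) {
  if (is.null(pairs)) stop("supply pairs = list(x, y) to plot")
  a <- (pairs[[1L]] + pairs[[2L]]) / 2
  d <- pairs[[1L]] - pairs[[2L]]
  graphics::plot(a, d, xlab = "mean of pair", ylab = "difference", pch = 16,
                 ylim = range(c(d, x$loa_low, x$loa_high)), ...)
  graphics::abline(h = c(x$mean_diff, x$loa_low, x$loa_high),
                   lty = c(1, 2, 2))
  invisible(x)
}

#' Synthetic inter-study reproducibility experiment
#'
#' Emulates the repeated-examination design: for each synthetic subject a
#' cardiac phantom with subject-specific per-segment T2 is rendered twice
#' with independent noise realizations, each visit is fitted
#' ([fit_map()], maximum likelihood) and summarized by its global T2
#' ([segment_report()], segment-mean rule), and the per-subject pairs are
#' fed to [bland_altman()].
#'
#' @param n_subjects number of synthetic subjects.
#' @param protocol a [grase_protocol()] (default the clinical six-echo
#'   preset).
#' @param snr signal-to-noise ratio of each visit.
#' @param seed base RNG seed; per-subject/visit seeds are derived from it.
#' @param t2_mean,t2_sd population mean and between-subject SD of myocardial
#'   T2 (ms); per-segment values additionally jitter by `segment_sd`.
#' @param segment_sd within-subject between-segment SD (ms).
#' @param slice_level slice to simulate.
#' @param geometry optional geometry override passed to [phantom_spec()]
#'   (smaller grids speed the experiment up).
#' @param shared_visit_seed if `TRUE`, both visits of a subject reuse the
#'   same noise seed (identical scans): a determinism check that must give
#'   perfect agreement.
#' @return A list with `agreement` (a [bland_altman()] object), `visit1`,
#'   `visit2` (global T2 per subject), `truth` (per-subject mean true T2).
#' @export
interstudy_experiment <- function(n_subjects = 5, protocol = grase_preset("6Ec"),
                                  snr = 20, seed = 1, t2_mean = 52,
                                  t2_sd = 2, segment_sd = 1.5,
                                  slice_level = "mid", geometry = NULL,
                                  shared_visit_seed = FALSE) {
  ns <- n_segments_at_level(slice_level)
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  subject_t2 <- stats::rnorm(n_subjects, t2_mean, t2_sd)
  seg_t2 <- lapply(subject_t2, function(mu)
    pmax(stats::rnorm(ns, mu, segment_sd), 20))
  visit_seeds <- matrix(sample.int(2^30, 2 * n_subjects), n_subjects, 2)
  if (shared_visit_seed) visit_seeds[, 2L] <- visit_seeds[, 1L]
  one_visit <- function(st2, vseed) {
    spec <- phantom_spec("cardiac", t1_rule = 1000, snr = snr,
                         seed = vseed, geometry = geometry)
    ph <- generate_cardiac(spec, protocol, st2, slice_level)
    map <- fit_map(ph$stack, mask = ph$labels > 0, method = "mle")
    segment_report(map, ph$labels)$global_mean
  }
  v1 <- vapply(seq_len(n_subjects),
               function(i) one_visit(seg_t2[[i]], visit_seeds[i, 1L]),
               numeric(1L))
  v2 <- vapply(seq_len(n_subjects),
               function(i) one_visit(seg_t2[[i]], visit_seeds[i, 2L]),
               numeric(1L))
  list(agreement = bland_altman(v1, v2), visit1 = v1, visit2 = v2,
       truth = vapply(seg_t2, mean, numeric(1L)))
}
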