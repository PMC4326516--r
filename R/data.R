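#' Worked-example segmental T2 values
#'
#' Sixteen AHA-segment T2 values from a healthy volunteer's three-slice
#' six-echo examination, shipped as a worked example for the segmental
#' aggregation: the segment-mean rule gives a global T2 of 51.6 ms with a
#' population SD of 3.3 ms.
#'
#' @return Data frame with columns `segment` (AHA id 1-16), `name`,
#'   `t2_ms`.
#' @export
example_segment_t2 <- function() {
  utils::read.csv(system.file("extdata", "example_segments.csv",
                              package = "graset2", mustWork = TRUE))
}

#' Patient cohort global T2 values
#'
#' Global myocardial T2 (mean +/- SD, ms) for five patients with acute
#' myocardial injury examined with the clinical six-echo protocol: two with
#' acute myocarditis, two with acute myocardial infarction, one with
#' takotsubo cardiomyopathy.
#'
#' @return Data frame with columns `patient`, `diagnosis`, `global_t2_ms`,
#'   `global_t2_sd_ms`.
#' @export
patient_t2_table <- function() {
  utils::read.csv(system.file("extdata", "patient_t2.csv",
                              package = "graset2", mustWork = TRUE))
}

#' Aggregate per-segment means into a global value
#'
#' The segment-mean aggregation used for global myocardial T2: the
#' unweighted mean of the per-segment means with the population SD
#' (divide-by-n) of those means.
#'
#' @param segment_means numeric vector of per-segment mean T2 (ms).
#' @return List with `mean` and `sd`.
#' @export
#' @examples
#' aggregate_segments(example_segment_t2()$t2_ms)  # 51.6 +/- 3.3
aggregate_segments <- function(segment_means) {
  if (length(segment_means) < 1L) stop("need at least one segment mean")
  m <- mean(segment_means)
  list(mean = m, sd = sqrt(mean((segment_means - m)^2)))
}
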