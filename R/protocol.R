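#' GraSE protocol description
#'
#' Constructs a `grase_protocol` object: the complete timing and geometry
#' description of one multi-echo gradient-spin-echo (GraSE) T2-mapping
#' sequence variant. In this acquisition a train of refocusing pulses
#' generates one spin echo per pulse, each read out with a short EPI echo
#' train and reconstructed into a separate image at its effective echo time,
#' so the number of refocusing pulses (the TSE factor) fixes the number of
#' images in the multi-echo series.
#'
#' @param name label for the variant.
#' @param first_te effective echo time of the first reconstructed image (ms).
#' @param delta_te echo spacing of the refocusing train (ms).
#' @param n_echoes number of reconstructed echo images (>= 2 for fitting).
#' @param n_startup number of start-up echoes acquired but discarded (0 or 1).
#'   A start-up echo lets the train settle before imaging starts, which
#'   suppresses the bias that stimulated echoes under an imperfect slice
#'   profile induce in the first echo interval.
#' @param epi_factor gradient echoes (k-space lines) acquired per spin echo.
#' @param sense_factor parallel-imaging acceleration factor.
#' @param matrix_read,matrix_phase acquired matrix (frequency x phase encode).
#' @param voxel_size acquired in-plane voxel size (mm).
#' @param slice_thickness slice thickness (mm).
#' @param tr_mode repetition mode; the ECG-triggered sequence uses one RR
#'   interval per shot.
#' @param n_dummy dummy heartbeats before data acquisition (default 1).
#' @param refocusing_profile effective refocusing flip-angle profile label:
#'   `"ideal"`, `"slr_optimized"` or `"suboptimal"`. See
#'   [refocusing_profile()].
#'
#' @return An object of class `grase_protocol` (a named list).
#' @seealso [grase_preset()] for the four shipped presets, [echo_times()],
#'   [shot_duration()], [num_heartbeats()], [breath_hold_duration()].
#' @export
#' @examples
#' p <- grase_preset("6Ec")
#' echo_times(p)
#' num_heartbeats(p)
grase_protocol <- function(name, first_te, delta_te, n_echoes, n_startup = 1,
                           epi_factor = 7, sense_factor = 2,
                           matrix_read = 176, matrix_phase = 168,
                           voxel_size = 2.0, slice_thickness = 10.0,
                           tr_mode = "one RR interval", n_dummy = 1,
                           refocusing_profile = "slr_optimized") {
  p <- list(name = as.character(name), first_te = as.numeric(first_te),
            delta_te = as.numeric(delta_te), n_echoes = as.integer(n_echoes),
            n_startup = as.integer(n_startup),
            epi_factor = as.integer(epi_factor),
            sense_factor = as.numeric(sense_factor),
            matrix_read = as.integer(matrix_read),
            matrix_phase = as.integer(matrix_phase),
            voxel_size = as.numeric(voxel_size),
            slice_thickness = as.numeric(slice_thickness),
            tr_mode = tr_mode, n_dummy = as.integer(n_dummy),
            refocusing_profile = match.arg(refocusing_profile,
                                           c("ideal", "slr_optimized",
                                             "suboptimal")))
  class(p) <- "grase_protocol"
  validate_protocol(p)
  p
}

validate_protocol <- function(p) {
  stopifnot(inherits(p, "grase_protocol"))
  if (p$n_echoes < 2L) stop("a protocol needs at least 2 echoes for T2 fitting")
  if (p$delta_te <= 0) stop("echo spacing delta_te must be positive")
  if (p$n_startup < 0L || p$n_startup > 1L)
    stop("n_startup must be 0 or 1")
  if (p$epi_factor < 1L) stop("epi_factor must be >= 1")
  if (p$sense_factor < 1) stop("sense_factor must be >= 1")
  # equally spaced train from excitation: first imaged echo follows the
  # discarded start-up echoes
  expected <- (p$n_startup + 1L) * p$delta_te
  if (abs(p$first_te - expected) > 1e-6)
    stop(sprintf("first_te (%.1f) must equal (n_startup + 1) * delta_te (%.1f)",
                 p$first_te, expected))
  invisible(p)
}

#' Shipped GraSE protocol presets
#'
#' Returns one of the four sequence variants evaluated for breath-hold
#' myocardial T2 mapping: a nine-echo variant (`"9Ec"`), the six-echo variant
#' proposed for clinical use (`"6Ec"`), a lower-resolution six-echo variant
#' (`"6EcLR"`), and a seven-echo variant without start-up echo
#' (`"7Ec_no_se"`). Presets are read from the YAML file shipped in
#' `inst/extdata/grase_protocols.yaml`.
#'
#' @param name one of `"9Ec"`, `"6Ec"`, `"6EcLR"`, `"7Ec_no_se"`.
#' @return A [grase_protocol()] object.
#' @export
grase_preset <- function(name) {
  presets <- grase_presets()
  if (!name %in% names(presets))
    stop(sprintf("unknown preset '%s'; valid presets: %s", name,
                 paste(names(presets), collapse = ", ")))
  q <- presets[[name]]
  do.call(grase_protocol, q)
}

grase_presets <- function() {
  path <- system.file("extdata", "grase_protocols.yaml", package = "graset2",
                      mustWork = TRUE)
  yaml::read_yaml(path)
}

#' @export
print.grase_protocol <- function(x, ...) {
  cat(sprintf("GraSE protocol '%s'\n", x$name))
  cat(sprintf("  echoes: %d reconstructed (+%d start-up), delta TE %.1f ms\n",
              x$n_echoes, x$n_startup, x$delta_te))
  te <- echo_times(x)
  cat(sprintf("  echo times: %s ms\n", paste(format(te), collapse = ", ")))
  cat(sprintf("  shot duration: %.1f ms;  heartbeats/slice: %d (incl. %d dummy)\n",
              shot_duration(x), num_heartbeats(x), x$n_dummy))
  cat(sprintf("  matrix %d x %d, voxel %.1f mm, slice %.1f mm, EPI %d, SENSE %g\n",
              x$matrix_read, x$matrix_phase, x$voxel_size, x$slice_thickness,
              x$epi_factor, x$sense_factor))
  cat(sprintf("  refocusing profile: %s\n", x$refocusing_profile))
  invisible(x)
}

#' Effective echo times of a protocol
#'
#' Echo times of the reconstructed images: `first_te + k * delta_te` for
#' `k = 0 .. n_echoes - 1`. Start-up echoes are not part of the series.
#'
#' @param p a [grase_protocol()].
#' @return Numeric vector of echo times (ms), strictly increasing.
#' @export
echo_times <- function(p) {
  validate_protocol(p)
  p$first_te + p$delta_te * (seq_len(p$n_echoes) - 1)
}

#' Duration of the refocusing train per excitation
#'
#' The span of the TSE shot: `(n_echoes + n_startup) * delta_te` ms, i.e. the
#' time from excitation to the last acquired echo.
#'
#' @param p a [grase_protocol()].
#' @return Shot duration in ms.
#' @export
shot_duration <- function(p) {
  validate_protocol(p)
  (p$n_echoes + p$n_startup) * p$delta_te
}

#' Heartbeats needed to acquire one slice
#'
#' Each excitation (one per RR interval) acquires `epi_factor` phase-encode
#' profiles for every echo image, and SENSE reduces the number of required
#' profiles by `sense_factor`, so a slice takes
#' `ceiling(matrix_phase / (sense_factor * epi_factor))` imaging heartbeats
#' plus the dummy heartbeat(s).
#'
#' @param p a [grase_protocol()].
#' @return Integer number of RR intervals per slice, dummies included.
#' @export
num_heartbeats <- function(p) {
  validate_protocol(p)
  as.integer(ceiling(p$matrix_phase / (p$sense_factor * p$epi_factor))) +
    p$n_dummy
}

#' Breath-hold duration for one slice
#'
#' @param p a [grase_protocol()].
#' @param rr_interval RR interval (ms); must be positive.
#' @return Breath-hold length in seconds.
#' @export
breath_hold_duration <- function(p, rr_interval) {
  if (rr_interval <= 0) stop("rr_interval must be positive")
  num_heartbeats(p) * rr_interval / 1000
}

#' Dual-inversion black-blood nulling delay
#'
#' Inversion delay TI at which inverted blood magnetization crosses zero in
#' cyclic steady state with one inversion per heartbeat (repetition time equal
#' to the RR interval):
#' \deqn{TI = T_1 \ln\!\frac{2}{1 + e^{-RR/T_1}}.}
#' The delay is computed from the cardiac frequency assuming a blood T1 of
#' 1200 ms at 1.5 T. As the RR interval grows the delay approaches the
#' single-shot limit \eqn{T_1 \ln 2}.
#'
#' @param rr_interval RR interval (ms).
#' @param t1_blood blood T1 (ms), default 1200.
#' @return Inversion delay in ms.
#' @export
#' @examples
#' black_blood_inversion_delay(1000)   # ~398.7 ms
black_blood_inversion_delay <- function(rr_interval, t1_blood = 1200) {
  if (any(rr_interval <= 0)) stop("rr_interval must be positive")
  if (t1_blood <= 0) stop("t1_blood must be positive")
  t1_blood * log(2 / (1 + exp(-rr_interval / t1_blood)))
}
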