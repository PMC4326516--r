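#' Multi-echo magnitude image stack
#'
#' Container for a multi-echo series: one 2D magnitude image per echo with
#' its echo times, plus optional noise metadata and the acquiring protocol.
#'
#' @param volumes numeric 3D array `[rows, cols, echoes]` of non-negative
#'   magnitudes.
#' @param echo_times echo times (ms), one per echo volume.
#' @param noise optional [noise_model()].
#' @param protocol optional [grase_protocol()]; when given, its echo count
#'   must match.
#' @return An object of class `multi_echo_stack`.
#' @export
multi_echo_stack <- function(volumes, echo_times, noise = NULL,
                             protocol = NULL) {
  volumes <- as.array(volumes)
  if (length(dim(volumes)) != 3L)
    stop("volumes must be a 3D array [rows, cols, echoes]")
  if (dim(volumes)[3L] != length(echo_times))
    stop("number of echo volumes must match length of echo_times")
  if (any(volumes < 0)) stop("magnitudes must be non-negative")
  if (is.unsorted(echo_times, strictly = TRUE))
    stop("echo_times must be strictly increasing")
  if (!is.null(protocol)) {
    validate_protocol(protocol)
    if (protocol$n_echoes != length(echo_times))
      stop("protocol echo count does not match stack")
  }
  structure(list(volumes = volumes, echo_times = as.numeric(echo_times),
                 noise = noise, protocol = protocol),
            class = "multi_echo_stack")
}

#' @export
print.multi_echo_stack <- function(x, ...) {
  d <- dim(x$volumes)
  cat(sprintf("multi-echo stack: %d x %d pixels, %d echoes (%.1f-%.1f ms)\n",
              d[1L], d[2L], d[3L], min(x$echo_times), max(x$echo_times)))
  if (!is.null(x$protocol)) cat(sprintf("  protocol: %s\n", x$protocol$name))
  if (!is.null(x$noise)) print(x$noise)
  invisible(x)
}

#' Read a multi-echo stack from a 4D NIfTI file
#'
#' Reads a 4D NIfTI volume (echo along the 4th dimension; single-slice data
#' may have a singleton 3rd dimension) together with a JSON sidecar carrying
#' the echo times and optional noise metadata.
#'
#' @param nifti_path path to the NIfTI file.
#' @param sidecar_path path to the JSON sidecar; defaults to the NIfTI path
#'   with extension replaced by `.json`. Expected fields: `echo_times_ms`
#'   (required), `sigma`, `n_channels`, `protocol` (preset name).
#' @return A [multi_echo_stack()].
#' @export
read_multi_echo <- function(nifti_path, sidecar_path = NULL) {
  if (is.null(sidecar_path))
    sidecar_path <- paste0(sub("\\.nii(\\.gz)?$", "", nifti_path), ".json")
  img <- RNifti::readNifti(nifti_path)
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L) {
    arr <- array(arr[, , 1L, , drop = TRUE], dim = d[c(1L, 2L, 4L)])
  } else if (length(d) != 3L) {
    stop("expected a 3D or 4D NIfTI volume")
  }
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  if (is.null(meta$echo_times_ms)) stop("sidecar lacks echo_times_ms")
  noise <- if (!is.null(meta$sigma))
    noise_model(meta$sigma, meta$n_channels %||% 1L) else NULL
  protocol <- if (!is.null(meta$protocol)) grase_preset(meta$protocol) else NULL
  multi_echo_stack(arr, meta$echo_times_ms, noise = noise, protocol = protocol)
}

#' Write a multi-echo stack as 4D NIfTI plus JSON sidecar
#'
#' @param stack a [multi_echo_stack()].
#' @param nifti_path output NIfTI path (`.nii` or `.nii.gz`).
#' @param voxel_mm in-plane voxel size recorded in the header (mm).
#' @return Invisibly, the sidecar path.
#' @export
write_multi_echo <- function(stack, nifti_path, voxel_mm = NULL) {
  stopifnot(inherits(stack, "multi_echo_stack"))
  d <- dim(stack$volumes)
  arr <- array(stack$volumes, dim = c(d[1L], d[2L], 1L, d[3L]))
  if (is.null(voxel_mm))
    voxel_mm <- if (!is.null(stack$protocol)) stack$protocol$voxel_size else 1
  img <- RNifti::asNifti(arr, pixdim = c(voxel_mm, voxel_mm, 1, 1))
  RNifti::writeNifti(img, nifti_path)
  meta <- list(echo_times_ms = stack$echo_times)
  if (!is.null(stack$noise)) {
    meta$sigma <- stack$noise$sigma
    meta$n_channels <- stack$noise$n_channels
  }
  if (!is.null(stack$protocol)) meta$protocol <- stack$protocol$name
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", nifti_path), ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

#' Write a T2 map as NIfTI plus JSON provenance
#'
#' The map is written in ms as floating point; non-fitted pixels hold 0. The
#' provenance sidecar records the method, noise parameters and protocol.
#'
#' @param map a `t2map` from [fit_map()].
#' @param nifti_path output path.
#' @return Invisibly, the sidecar path.
#' @export
write_t2_map <- function(map, nifti_path) {
  stopifnot(inherits(map, "t2map"))
  RNifti::writeNifti(RNifti::asNifti(map$t2), nifti_path)
  meta <- list(units = "ms", method = map$method,
               t2_ceiling_ms = map$t2_bounds[2L],
               nonfitted_value = 0)
  if (!is.null(map$noise)) {
    meta$sigma <- map$noise$sigma
    meta$n_channels <- map$noise$n_channels
  }
  if (!is.null(map$protocol)) meta$protocol <- map$protocol$name
  sidecar <- paste0(sub("\\.nii(\\.gz)?$", "", nifti_path), ".json")
  jsonlite::write_json(meta, sidecar, auto_unbox = TRUE, digits = NA)
  invisible(sidecar)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
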