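#' Myocardial segment geometry for one short-axis slice
#'
#' Bundles the manually drawn endocardial and epicardial contours, the
#' anterior right-ventricular insertion point, and the slice level. Together
#' these define the AHA segmentation of the slice: 6 segments for basal and
#' mid-ventricular slices, 4 for apical (the apical cap, segment 17, is not
#' used).
#'
#' Coordinates are 0-based pixel coordinates `(x, y)` with `x` along image
#' columns and `y` along rows; pixel centres lie at integer coordinates.
#'
#' @param endo_contour closed polygon, matrix/data.frame with columns x, y.
#' @param epi_contour closed polygon enclosing `endo_contour`.
#' @param rv_insertion length-2 numeric, the anterior RV insertion point.
#' @param slice_level `"basal"`, `"mid"` or `"apical"`.
#' @return An object of class `segment_model`.
#' @export
segment_model <- function(endo_contour, epi_contour, rv_insertion,
                          slice_level = c("basal", "mid", "apical")) {
  slice_level <- match.arg(slice_level)
  endo <- as_contour(endo_contour, "endo_contour")
  epi <- as_contour(epi_contour, "epi_contour")
  rv_insertion <- as.numeric(rv_insertion)
  if (length(rv_insertion) != 2L) stop("rv_insertion must be a length-2 (x, y)")
  if (!all(point_in_poly(endo[, 1L], endo[, 2L], epi)))
    stop("endo_contour must lie strictly inside epi_contour")
  if (point_in_poly(rv_insertion[1L], rv_insertion[2L], endo))
    stop("rv_insertion must lie outside the endocardial contour")
  structure(list(endo_contour = endo, epi_contour = epi,
                 rv_insertion = rv_insertion, slice_level = slice_level),
            class = "segment_model")
}

as_contour <- function(p, what) {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L)
    stop(sprintf("%s must be a polygon with >= 3 (x, y) vertices", what))
  if (abs(polygon_area(p)) < 1e-9)
    stop(sprintf("%s is degenerate (zero area)", what))
  storage.mode(p) <- "double"
  colnames(p) <- c("x", "y")
  p
}

polygon_area <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  sum(x * y[j] - x[j] * y) / 2
}

polygon_centroid <- function(p) {
  x <- p[, 1L]; y <- p[, 2L]
  j <- c(seq_len(nrow(p))[-1L], 1L)
  cr <- x * y[j] - x[j] * y
  a <- sum(cr) / 2
  c(sum((x + x[j]) * cr) / (6 * a), sum((y + y[j]) * cr) / (6 * a))
}

point_in_poly <- function(px, py, poly) {
  bnd <- rbind(poly, poly[1L, , drop = FALSE])
  mgcv::in.out(bnd, cbind(px, py))
}

#' Number of segments at a slice level
#' @param slice_level `"basal"`, `"mid"` or `"apical"`.
#' @return 6 for basal/mid, 4 for apical.
#' @export
n_segments_at_level <- function(slice_level) {
  switch(slice_level, basal = 6L, mid = 6L, apical = 4L,
         stop("slice_level must be basal, mid or apical"))
}

aha_segment_ids <- function(slice_level) {
  switch(slice_level, basal = 1:6, mid = 7:12, apical = 13:16)
}

#' Names of the 16 AHA segments
#' @return Character vector indexed by AHA segment id 1-16.
#' @export
aha_segment_names <- function() {
  c("basal anterior", "basal anteroseptal", "basal inferoseptal",
    "basal inferior", "basal inferolateral", "basal anterolateral",
    "mid anterior", "mid anteroseptal", "mid inferoseptal",
    "mid inferior", "mid inferolateral", "mid anterolateral",
    "apical anterior", "apical septal", "apical inferior", "apical lateral")
}

# Sweep angle (radians, [0, 2pi)) from the RV-insertion ray, proceeding
# through the septum; counterclockwise in a standard short-axis display
# (anterior up, septum image-left), which with image y increasing downward
# is (theta0 - theta) in array coordinates.
sweep_angle <- function(px, py, center, rv_insertion) {
  th0 <- atan2(rv_insertion[2L] - center[2L], rv_insertion[1L] - center[1L])
  th <- atan2(py - center[2L], px - center[1L])
  (th0 - th) %% (2 * pi)
}

# ceiling rule: a pixel exactly on a sector boundary joins the
# lower-numbered segment
sector_of <- function(delta, slice_level) {
  if (slice_level == "apical") {
    # 90-degree sectors with the septal sector centred on the septum
    # (septum centre at 120 degrees from the RV ray): boundaries at -15 deg
    idx <- ceiling(((delta + pi / 12) %% (2 * pi)) / (pi / 2) - 1e-9)
  } else {
    idx <- ceiling(delta / (pi / 3) - 1e-9)
  }
  ns <- n_segments_at_level(slice_level)
  idx <- as.integer(idx)
  idx[idx < 1L] <- 1L        # delta exactly 0 sits on the 1/ns boundary
  pmin(idx, ns)
}

#' Assign AHA segment labels to the pixels of a slice
#'
#' Myocardial pixels are those whose centres lie inside the epicardial and
#' outside the endocardial contour (point-in-polygon on pixel centres).
#' Angular position is measured about the centroid of the endocardial
#' contour, starting at the ray through the RV insertion point and sweeping
#' through the septum; basal/mid slices get six 60-degree sectors in the
#' order anterior, anteroseptal, inferoseptal, inferior, inferolateral,
#' anterolateral, and apical slices four 90-degree sectors (anterior,
#' septal, inferior, lateral) with the septal sector centred on the septum.
#' A pixel exactly on a sector boundary joins the lower-numbered segment.
#'
#' @param model a [segment_model()].
#' @param image_shape `c(rows, cols)` of the slice.
#' @return Integer matrix of AHA segment ids (1-16); 0 outside the
#'   myocardium.
#' @export
assign_segments <- function(model, image_shape) {
  stopifnot(inherits(model, "segment_model"))
  nr <- image_shape[1L]; nc <- image_shape[2L]
  # pixel centres, 0-based: x = col - 1, y = row - 1
  px <- rep(0:(nc - 1L), each = nr)
  py <- rep(0:(nr - 1L), times = nc)
  in_epi <- point_in_poly(px, py, model$epi_contour)
  in_endo <- point_in_poly(px, py, model$endo_contour)
  myo <- in_epi & !in_endo
  labels <- matrix(0L, nr, nc)
  if (!any(myo)) return(labels)
  ctr <- polygon_centroid(model$endo_contour)
  delta <- sweep_angle(px[myo], py[myo], ctr, model$rv_insertion)
  sec <- sector_of(delta, model$slice_level)
  labels[myo] <- aha_segment_ids(model$slice_level)[sec]
  labels
}

#' Per-segment and global T2 statistics
#'
#' Computes segment-wise mean and SD of the fitted T2 values and two global
#' summaries: the segment-mean rule (global mean = unweighted mean of the
#' segment means; global SD = population SD, divide-by-n, of the segment
#' means), which is the headline aggregation, and a pixel-weighted
#' alternative (mean and SD over all included pixels) reported alongside.
#' Only converged, positive T2 pixels enter; empty segments are excluded and
#' flagged.
#'
#' @param t2_map a `t2map` from [fit_map()], or a plain numeric matrix of T2
#'   values (0 = not fitted).
#' @param labels integer label matrix from [assign_segments()] (or the
#'   generator's truth labels).
#' @return An object of class `segment_report`: data frame `per_segment`
#'   (segment id, name, mean, sd, n_pixels), `global_mean`, `global_sd`
#'   (segment-mean rule), `global_mean_pixelwise`, `global_sd_pixelwise`,
#'   `aggregation`, `empty_segments`.
#' @export
segment_report <- function(t2_map, labels) {
  if (inherits(t2_map, "t2map")) {
    vals <- t2_map$t2
    ok <- t2_map$converged & vals > 0
  } else {
    vals <- as.matrix(t2_map)
    ok <- vals > 0
  }
  labels <- as.matrix(labels)
  if (!all(dim(vals) == dim(labels)))
    stop("t2_map and labels shapes do not match")
  ids <- sort(unique(labels[labels > 0L]))
  rows <- lapply(ids, function(id) {
    v <- vals[labels == id & ok]
    data.frame(segment = id, name = aha_segment_names()[id],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n_pixels = length(v))
  })
  per <- do.call(rbind, rows)
  empty <- per$segment[per$n_pixels == 0L]
  used <- per[per$n_pixels > 0L, , drop = FALSE]
  if (nrow(used) == 0L) stop("no segment contains fitted pixels")
  sm <- used$mean
  allv <- vals[labels > 0L & ok]
  structure(list(
    per_segment = per,
    global_mean = mean(sm),
    global_sd = sqrt(mean((sm - mean(sm))^2)),   # population SD of segment means
    global_mean_pixelwise = mean(allv),
    global_sd_pixelwise = stats::sd(allv),
    aggregation = "global = unweighted mean of segment means; SD = population SD of segment means",
    empty_segments = empty), class = "segment_report")
}

#' @export
print.segment_report <- function(x, digits = 1, ...) {
  cat(sprintf("global T2: %.1f +/- %.1f ms (segment-mean rule; pixelwise %.1f +/- %.1f ms)\n",
              x$global_mean, x$global_sd, x$global_mean_pixelwise,
              x$global_sd_pixelwise))
  p <- x$per_segment
  p$mean <- round(p$mean, digits); p$sd <- round(p$sd, digits)
  print(p, row.names = FALSE)
  if (length(x$empty_segments))
    cat("empty segments excluded:", paste(x$empty_segments, collapse = ", "), "\n")
  invisible(x)
}

#' Regional T2 contrasts across slice levels and walls
#'
#' Slice-level mean differences (apical - mid, apical - basal, mid - basal,
#' each slice summarized by the mean of its segment means) and the
#' septal-versus-lateral wall contrast (segments 2, 3, 8, 9, 14 vs
#' 5, 6, 11, 12, 16). Missing slices produce `NA` contrasts with a flag
#' rather than an error.
#'
#' @param reports named list with elements `basal`, `mid`, `apical`, each a
#'   [segment_report()] (any may be missing).
#' @return A list with `slice_means`, `apical_minus_mid`,
#'   `apical_minus_basal`, `mid_minus_basal`, `septal_minus_lateral`,
#'   `missing_slices`.
#' @export
regional_contrasts <- function(reports) {
  levels <- c("basal", "mid", "apical")
  have <- intersect(levels, names(reports))
  missing <- setdiff(levels, have)
  slice_mean <- function(lvl) {
    if (!lvl %in% have) return(NA_real_)
    p <- reports[[lvl]]$per_segment
    mean(p$mean[p$n_pixels > 0L])
  }
  sm <- vapply(levels, slice_mean, numeric(1L))
  seg_means <- do.call(rbind, lapply(have, function(lvl)
    reports[[lvl]]$per_segment[, c("segment", "mean", "n_pixels")]))
  seg_means <- seg_means[seg_means$n_pixels > 0L, , drop = FALSE]
  septal <- seg_means$mean[seg_means$segment %in% c(2, 3, 8, 9, 14)]
  lateral <- seg_means$mean[seg_means$segment %in% c(5, 6, 11, 12, 16)]
  list(slice_means = sm,
       apical_minus_mid = sm[["apical"]] - sm[["mid"]],
       apical_minus_basal = sm[["apical"]] - sm[["basal"]],
       mid_minus_basal = sm[["mid"]] - sm[["basal"]],
       septal_minus_lateral = if (length(septal) && length(lateral))
         mean(septal) - mean(lateral) else NA_real_,
       missing_slices = missing)
}
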