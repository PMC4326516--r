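circle_poly <- function(center, r, n = 64) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(x = center[1] + r * cos(th), y = center[2] + r * sin(th))
}

test_that("segment models enforce their geometric invariants", {
  ctr <- c(20, 20)
  endo <- circle_poly(ctr, 6)
  epi <- circle_poly(ctr, 12)
  m <- segment_model(endo, epi, c(2, 20), "mid")
  expect_s3_class(m, "segment_model")
  expect_error(segment_model(epi, endo, c(14.5, 20), "mid"), "inside")
  expect_error(segment_model(endo, epi, ctr, "mid"), "outside")
  expect_error(segment_model(endo[1:2, ], epi, c(2, 20), "mid"), "vertices")
  expect_error(segment_model(endo, epi, c(2, 20), "mid-cavity"), "arg")
})

test_that("labels partition the myocardium into ordered angular sectors", {
  ctr <- c(20, 20)
  m <- segment_model(circle_poly(ctr, 6), circle_poly(ctr, 12), c(2, 20),
                     "mid")
  lab <- assign_segments(m, c(41, 41))
  myo <- lab > 0
  expect_setequal(unique(lab[myo]), 7:12)
  # every myocardial pixel gets exactly one label, no pixel outside epi does
  px <- rep(0:40, each = 41); py <- rep(0:40, times = 41)
  rr <- sqrt((px - 20)^2 + (py - 20)^2)
  expect_true(all(lab[rr > 12.5] == 0))
  expect_true(all(lab[rr < 5.5 & rr > 0] == 0))
  expect_true(all(lab[rr > 6.5 & rr < 11.5] > 0))
  # six roughly equal sectors
  counts <- table(lab[myo])
  expect_lt(diff(range(counts)) / mean(counts), 0.2)
  # apical model gives four sectors, ids 13-16
  ma <- segment_model(circle_poly(ctr, 6), circle_poly(ctr, 12), c(2, 20),
                      "apical")
  expect_setequal(unique(assign_segments(ma, c(41, 41))[myo]), 13:16)
})

test_that("sector boundaries resolve to the lower AHA index", {
  # with the RV insertion due image-left, the pixel diametrically opposite
  # the septum centre sits exactly on the inferolateral/anterolateral
  # boundary (300 degrees of sweep): the documented tie rule gives the
  # lower-numbered segment
  expect_equal(graset2:::sector_of(5 * pi / 3, "mid"), 5L)
  expect_equal(graset2:::sector_of(5 * pi / 3 + 1e-6, "mid"), 6L)
  expect_equal(graset2:::sector_of(5 * pi / 3 - 1e-6, "mid"), 5L)
  expect_equal(graset2:::sector_of(0, "mid"), 1L)         # on the RV ray
  expect_equal(graset2:::sector_of(pi / 3, "mid"), 1L)    # 60 deg boundary
  # apical: boundaries offset so the septal sector is centred on the septum
  expect_equal(graset2:::sector_of(2 * pi / 3, "apical"), 2L)  # septum centre
  expect_equal(graset2:::sector_of(5 * pi / 12, "apical"), 1L) # 75 deg edge
})

test_that("generator truth and contour-based assignment agree round-trip", {
  spec <- phantom_spec("cardiac", t1_rule = 1000, snr = 50, seed = 21,
                       geometry = small_cardiac_geometry())
  ph <- generate_cardiac(spec, grase_preset("6Ec"),
                         c(55.5, 57.1, 50.2, 50.2, 54.6, 49.2), "mid")
  lab <- assign_segments(ph$segment_model, dim(ph$labels))
  both <- lab > 0 & ph$labels > 0   # boundary-ring pixels excepted
  expect_gt(mean(lab[both] == ph$labels[both]), 0.99)
  expect_gt(sum(both) / sum(ph$labels > 0), 0.95)
})

test_that("segment reports aggregate by the segment-mean rule", {
  # sixteen constant-valued segments laid out as strips
  vals <- example_segment_t2()$t2_ms
  t2 <- matrix(rep(vals, each = 10), nrow = 10)
  labels <- matrix(rep(1:16, each = 10), nrow = 10)
  rep16 <- segment_report(t2, labels)
  expect_equal(rep16$global_mean, 51.6, tolerance = 0.001)
  expect_equal(rep16$global_sd, 3.3, tolerance = 0.02)
  expect_equal(rep16$per_segment$mean, vals)
  expect_equal(rep16$per_segment$name, example_segment_t2()$name)
  # invariant to pixel ordering within segments
  perm <- sample(160)
  rep_perm <- segment_report(matrix(t2[perm], nrow = 10),
                             matrix(labels[perm], nrow = 10))
  expect_equal(rep_perm$global_mean, rep16$global_mean)
  # all segments equal -> SD exactly 0
  repc <- segment_report(matrix(52, 10, 16), labels)
  expect_equal(repc$global_mean, 52)
  expect_equal(repc$global_sd, 0)
  # non-fitted pixels (0) are excluded; empty segments flagged
  t2z <- t2; t2z[, 1] <- 0
  repz <- segment_report(t2z, labels)
  expect_equal(repz$empty_segments, 1L)
  expect_equal(repz$global_mean, mean(vals[-1]), tolerance = 1e-9)
  expect_error(segment_report(t2, labels[, 1:8]), "match")
})

test_that("regional contrasts recover slice and wall differences", {
  strip_report <- function(vals, ids) {
    t2 <- matrix(rep(vals, each = 10), nrow = 10)
    labels <- matrix(rep(ids, each = 10), nrow = 10)
    segment_report(t2, labels)
  }
  seg <- example_segment_t2()
  reports <- list(
    basal = strip_report(seg$t2_ms[1:6], 1:6),
    mid = strip_report(seg$t2_ms[7:12], 7:12),
    apical = strip_report(seg$t2_ms[13:16], 13:16))
  rc <- regional_contrasts(reports)
  expect_equal(rc$slice_means[["mid"]], 52.80, tolerance = 1e-9)
  expect_equal(rc$slice_means[["apical"]], 53.45, tolerance = 1e-9)
  expect_equal(rc$apical_minus_mid, 0.65, tolerance = 1e-9)
  # identical slices -> all contrasts zero
  same <- list(basal = strip_report(rep(52, 6), 1:6),
               mid = strip_report(rep(52, 6), 7:12),
               apical = strip_report(rep(52, 4), 13:16))
  rcs <- regional_contrasts(same)
  expect_equal(rcs$apical_minus_mid, 0)
  expect_equal(rcs$septal_minus_lateral, 0)
  # a constructed apical elevation is recovered
  up <- list(mid = strip_report(rep(52, 6), 7:12),
             apical = strip_report(rep(53.2, 4), 13:16),
             basal = strip_report(rep(52, 6), 1:6))
  expect_equal(regional_contrasts(up)$apical_minus_mid, 1.2, tolerance = 1e-9)
  # missing slice flagged, partial output
  partial <- regional_contrasts(reports[c("basal", "mid")])
  expect_equal(partial$missing_slices, "apical")
  expect_true(is.na(partial$apical_minus_mid))
})
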