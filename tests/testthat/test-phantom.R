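p6 <- grase_preset("6Ec")

test_that("noiseless ideal-profile phantoms are exact forward renders", {
  spec <- phantom_spec("tubes", snr = Inf, geometry = small_tube_geometry())
  p_ideal <- p6; p_ideal$refocusing_profile <- "ideal"
  ph <- generate_stack(spec, p_ideal)
  te <- echo_times(p_ideal)
  i <- which(ph$labels == 3)[5]
  series <- sapply(1:6, function(e) ph$stack$volumes[, , e][i])
  expect_equal(series, 100 * exp(-te / 55), tolerance = 1e-12)
  # and fitting the noiseless stack returns the truth to optimizer tolerance
  map <- fit_map(ph$stack, mask = ph$labels > 0, method = "lsq_nonlinear")
  expect_equal(max(abs(map$t2[ph$labels > 0] - ph$t2_true[ph$labels > 0])), 0,
               tolerance = 1e-5)
})

test_that("a fixed seed makes generated stacks bit-identical", {
  spec <- phantom_spec("tubes", snr = 50, seed = 42,
                       geometry = small_tube_geometry())
  a <- generate_stack(spec, p6)
  b <- generate_stack(spec, p6)
  expect_identical(a$stack$volumes, b$stack$volumes)
  spec2 <- phantom_spec("tubes", snr = 50, seed = 43,
                        geometry = small_tube_geometry())
  expect_false(identical(generate_stack(spec2, p6)$stack$volumes,
                         a$stack$volumes))
})

test_that("tube medians are recovered within two percent at SNR 50", {
  spec <- phantom_spec("tubes", snr = 50, seed = 42,
                       geometry = small_tube_geometry())
  ph <- generate_stack(spec, p6)
  map <- fit_map(ph$stack, mask = ph$labels > 0, method = "mle")
  for (i in seq_along(spec$t2_values)) {
    med <- stats::median(map$t2[ph$labels == i])
    expect_lt(abs(med - spec$t2_values[i]) / spec$t2_values[i], 0.02)
  }
})

test_that("injected noise follows the declared magnitude law", {
  spec <- phantom_spec("tubes", snr = 50, seed = 11,
                       geometry = small_tube_geometry(), n_channels = 2L)
  ph <- generate_stack(spec, p6)
  bg <- as.vector(ph$stack$volumes[, , 1][ph$labels == 0])
  sigma <- ph$stack$noise$sigma
  # KS against the central-chi CDF; background count is ~ 4200 pixels
  cdf <- function(q) stats::pchisq(q^2 / sigma^2, df = 4)
  expect_gt(stats::ks.test(bg, cdf)$p.value, 0.01)
  # and the second-moment estimator recovers sigma
  expect_lt(abs(estimate_sigma(bg, 2) - sigma) / sigma, 0.03)
})

test_that("geometry violations are rejected", {
  bad <- small_tube_geometry()
  bad$centers[2, ] <- bad$centers[1, ] + c(3, 0)
  expect_error(generate_stack(phantom_spec("tubes", geometry = bad), p6),
               "overlap")
  expect_error(generate_stack(phantom_spec("cardiac"), p6), "cardiac")
  expect_error(phantom_spec("tubes", t2_values = c(-2, 50)), "positive")
})

test_that("the cardiac phantom carries consistent truth and black blood", {
  spec <- phantom_spec("cardiac", t1_rule = 1000, snr = 50, seed = 9,
                       geometry = small_cardiac_geometry())
  seg_t2 <- c(55.5, 57.1, 50.2, 50.2, 54.6, 49.2)
  ph <- generate_cardiac(spec, p6, seg_t2, "mid")
  expect_setequal(unique(ph$labels[ph$labels > 0]), 7:12)
  expect_equal(unname(ph$segment_t2), seg_t2)
  # blood pool: zero underlying signal, so fitted amplitude stays near noise
  ctr <- small_cardiac_geometry()$center
  blood_idx <- ph$labels == 0 &
    outer(0:(nrow(ph$labels) - 1), 0:(ncol(ph$labels) - 1),
          function(y, x) (x - ctr[1])^2 + (y - ctr[2])^2 < 6^2)
  expect_true(all(ph$s0_true[blood_idx] == 0))
  expect_error(generate_cardiac(spec, p6, seg_t2, "apical"), "4 segments")
  expect_error(generate_cardiac(spec, p6, seg_t2[1:4], "mid"), "6 segments")
})

test_that("uniform myocardium yields a uniform global estimate", {
  spec <- phantom_spec("cardiac", t1_rule = 1000, snr = 100, seed = 13,
                       geometry = small_cardiac_geometry())
  ph <- generate_cardiac(spec, p6, rep(52, 6), "mid")
  map <- fit_map(ph$stack, mask = ph$labels > 0, method = "mle")
  rep6 <- segment_report(map, ph$labels)
  expect_equal(rep6$global_mean, 52, tolerance = 0.01)  # relative
})
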