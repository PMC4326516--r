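te6 <- c(23.6, 35.4, 47.2, 59.0, 70.8, 82.6)

test_that("noiseless series are recovered exactly by every method", {
  m <- 100 * exp(-te6 / 52)
  f_mle <- t2_fit(m, te6, noise_model(1e-6), method = "mle")
  expect_equal(coef(f_mle)[["t2"]], 52, tolerance = 0.01 / 52)
  expect_equal(coef(f_mle)[["s0"]], 100, tolerance = 1e-3)
  expect_true(f_mle$converged)
  f_log <- t2_fit(m, te6, method = "lsq_log")
  f_nls <- t2_fit(m, te6, method = "lsq_nonlinear")
  expect_equal(coef(f_log)[["t2"]], coef(f_nls)[["t2"]], tolerance = 1e-4)
  expect_lt(abs(coef(f_log)[["t2"]] - 52), 0.01)
  # two-point closed form
  f2 <- t2_fit(c(100, 100 * exp(-59 / 52)), c(23.6, 82.6), method = "lsq_log")
  expect_equal(coef(f2)[["t2"]], 52, tolerance = 1e-9)
})

test_that("the bounded optimizer lands on the grid-search maximum", {
  nm <- noise_model(5, 1)
  set.seed(4)
  for (rep in 1:2) {
    m <- rncchi(length(te6), 100 * exp(-te6 / 52), nm)
    fit <- t2_fit(m, te6, nm, method = "mle")
    grid <- grid_search_mle(m, te6, nm, t2_max = 200)
    expect_lt(abs(coef(fit)[["t2"]] - grid[["t2"]]), 0.25 + 1e-9)
    expect_lt(abs(coef(fit)[["s0"]] - grid[["s0"]]), 0.25 + 1e-9)
    # and never below the grid's achievable likelihood
    expect_gte(fit$logLik, grid[["logLik"]] - 1e-9)
  }
})

test_that("maximum likelihood shrinks the noise-floor bias of log least squares", {
  nm <- noise_model(5, 1)   # S0/sigma = 20
  set.seed(5)
  reps <- 1500
  est <- replicate(reps, {
    m <- rncchi(length(te6), 100 * exp(-te6 / 52), nm)
    c(mle = coef(t2_fit(m, te6, nm, "mle"))[["t2"]],
      lsq = coef(t2_fit(m, te6, method = "lsq_log"))[["t2"]])
  })
  expect_lt(abs(mean(est["mle", ]) - 52), abs(mean(est["lsq", ]) - 52))
  # the floor biases the log fit upward relative to the likelihood fit
  expect_gt(mean(est["lsq", ]), mean(est["mle", ]))
})

test_that("the optimizer never degrades its least-squares initializer", {
  nm <- noise_model(8, 1)
  set.seed(6)
  for (i in 1:20) {
    m <- rncchi(length(te6), 60 * exp(-te6 / 45), nm)
    fit <- t2_fit(m, te6, nm, method = "mle")
    ll_init <- t2_loglik(m, te6, fit$init[["s0"]], fit$init[["t2"]], nm)
    expect_gte(fit$logLik, ll_init - 1e-9)
  }
})

test_that("degenerate series are flagged rather than raising", {
  f <- t2_fit(rep(0, 6), te6, noise_model(1), method = "mle")
  expect_false(f$converged)
  f_log <- t2_fit(c(10, 0, 5, 3, 2, 1), te6, method = "lsq_log")
  expect_false(f_log$converged)
  expect_error(t2_fit(c(1, 2), c(10, 20, 30)), "length")
})

test_that("fit methods expose the standard modelling interface", {
  nm <- noise_model(2, 1)
  set.seed(7)
  m <- rncchi(length(te6), 100 * exp(-te6 / 52), nm)
  fit <- t2_fit(m, te6, nm, method = "mle")
  expect_equal(predict(fit),
               coef(fit)[["s0"]] * exp(-te6 / coef(fit)[["t2"]]))
  expect_equal(residuals(fit), m - predict(fit))
  expect_gt(predict(fit, newdata = 300, type = "expected"),
            predict(fit, newdata = 300, type = "decay"))  # noise floor
  expect_s3_class(logLik(fit), "logLik")
  sims <- simulate(fit, nsim = 5, seed = 99)
  expect_equal(dim(sims), c(5L, 6L))
  expect_equal(simulate(fit, nsim = 5, seed = 99), sims)  # seeded determinism
  out <- capture.output(print(summary(fit)))
  expect_true(any(grepl("T2 fit", out)))
})

test_that("map fitting is masked, deterministic and flags non-fitted pixels", {
  p <- grase_preset("6Ec"); p$refocusing_profile <- "ideal"
  vol <- array(0, dim = c(8, 9, 6))
  for (e in 1:6) vol[, , e] <- 100 * exp(-te6[e] / 52)
  vol[1, 1, ] <- 0                          # a dead pixel
  stack <- multi_echo_stack(vol, te6, noise = noise_model(1e-6), protocol = p)
  map <- fit_map(stack, method = "mle")
  expect_equal(map$t2[3, 4], 52, tolerance = 1e-3)
  expect_equal(map$t2[1, 1], 0)             # non-fitted marker
  expect_false(map$converged[1, 1])
  # identical rerun (no RNG in fitting)
  expect_identical(map$t2, fit_map(stack, method = "mle")$t2)
  # masked fit leaves unmasked pixels untouched
  mask <- matrix(FALSE, 8, 9); mask[5, 5] <- TRUE
  mmap <- fit_map(stack, mask = mask, method = "mle")
  expect_equal(sum(mmap$t2 > 0), 1L)
  expect_equal(mmap$t2[5, 5], 52, tolerance = 1e-3)
  expect_error(fit_map(stack, mask = matrix(TRUE, 4, 4)), "mask")
})
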