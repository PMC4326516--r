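# Independent oracles used across the suite.

# Brute-force isochromat (Bloch rotation-matrix) simulation of a CPMG train:
# n_spins isochromats on a uniform grid of per-half-interval dephasing
# angles, explicit 3x3 rotations, relaxation with regrowth. The grid average
# of exp(i k theta) vanishes exactly for 0 < |k| < n_spins, so this matches
# the configuration-state recursion to numerical precision when the maximum
# dephasing order stays below n_spins.
isochromat_echoes <- function(t2, t1, delta_te, n_pulses, flip_deg,
                              n_spins = 600) {
  th <- 2 * pi * (seq_len(n_spins) - 0.5) / n_spins
  M <- matrix(0, 3, n_spins)
  M[2, ] <- -1                       # 90x excitation: M0 -> -y
  e2 <- exp(-delta_te / 2 / t2)
  e1 <- exp(-delta_te / 2 / t1)
  a <- flip_deg * pi / 180
  Ry <- matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
  ct <- cos(th); st <- sin(th)
  half <- function(M) {
    x <- M[1, ] * ct - M[2, ] * st
    y <- M[1, ] * st + M[2, ] * ct
    M[1, ] <- x * e2
    M[2, ] <- y * e2
    M[3, ] <- M[3, ] * e1 + (1 - e1)
    M
  }
  out <- numeric(n_pulses)
  for (p in seq_len(n_pulses)) {
    M <- half(M)
    M <- Ry %*% M
    M <- half(M)
    out[p] <- Mod(mean(complex(real = M[1, ], imaginary = M[2, ])))
  }
  out
}

# Exhaustive grid-search maximizer of the magnitude likelihood, the oracle
# for the bounded-optimizer fit. Vectorized over s0 for speed.
grid_search_mle <- function(series, te, noise, s0_step = 0.25,
                            t2_step = 0.25, t2_max = 1000) {
  s0_grid <- seq(s0_step, 2 * max(series), by = s0_step)
  t2_grid <- seq(1, t2_max, by = t2_step)
  best <- c(NA_real_, NA_real_)
  best_ll <- -Inf
  for (t2 in t2_grid) {
    decay <- exp(-te / t2)
    ll <- numeric(length(s0_grid))
    for (k in seq_along(te)) {
      ll <- ll + dncchi(rep(series[k], length(s0_grid)), s0_grid * decay[k],
                        noise, log = TRUE)
    }
    i <- which.max(ll)
    if (ll[i] > best_ll) {
      best_ll <- ll[i]
      best <- c(s0_grid[i], t2)
    }
  }
  c(s0 = best[1L], t2 = best[2L], logLik = best_ll)
}

# Small geometries that keep map fits fast in the suite.
small_tube_geometry <- function() {
  list(shape = c(60L, 90L), radius = 8,
       centers = cbind(x = rep(c(15, 45, 75), 2), y = rep(c(15, 45), each = 3)))
}

small_cardiac_geometry <- function() {
  list(shape = c(64L, 64L), center = c(31, 32), r_endo = 11, r_epi = 18,
       rv_angle_deg = 135)
}

fit_t2_lsq_train <- function(train, te) {
  coef(t2_fit(train, te, method = "lsq_nonlinear"))[["t2"]]
}
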