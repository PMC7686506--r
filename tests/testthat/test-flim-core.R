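test_that("phase lifetime conversion matches closed-form values", {
  # omega*tau = 1 at 10 MHz: the optimum lifetime 1/(2*pi*f)
  expect_equal(phase_lifetime(pi / 4, 1e7), 1e9 / (2 * pi * 1e7),
               tolerance = 1e-12)
  expect_equal(phase_lifetime(0, 1e7), 0)
  # frozen from arbitrary-precision evaluation of tan(pi/6)/(2*pi*1e7)
  expect_equal(phase_lifetime(pi / 6, 1e7), 9.1888147, tolerance = 1e-7)
  expect_true(is.na(phase_lifetime(pi / 2, 1e7)))
  expect_true(is.na(phase_lifetime(-0.1, 1e7)))
})

test_that("modulation lifetime conversion matches closed-form values", {
  expect_equal(modulation_lifetime(1, 1e7), 0)
  expect_equal(modulation_lifetime(1 / sqrt(2), 1e7), 1e9 / (2 * pi * 1e7),
               tolerance = 1e-12)
  # frozen from direct evaluation of sqrt(1/0.81 - 1)/omega
  expect_equal(modulation_lifetime(0.9, 1e7), 7.7082263, tolerance = 1e-7)
  expect_true(is.na(modulation_lifetime(1.05, 1e7)))  # super-modulation
  expect_true(is.na(modulation_lifetime(0, 1e7)))
})

test_that("mono-exponential phasors lie exactly on the universal semicircle", {
  taus <- c(0, 10^seq(-2, 2, length.out = 41))
  ph <- lifetime_to_phasor(taus, 1e7)
  expect_equal((ph$g - 0.5)^2 + ph$s^2, rep(0.25, length(taus)),
               tolerance = 1e-12)
  expect_equal(c(ph$g[1], ph$s[1]), c(1, 0))
  apex <- lifetime_to_phasor(1 / OMEGA_10MHZ, 1e7)
  expect_equal(c(apex$g, apex$s), c(0.5, 0.5), tolerance = 1e-12)
  p16 <- lifetime_to_phasor(16, 1e7)
  expect_equal(c(p16$g, p16$s), c(0.497, 0.500), tolerance = 1e-3)
})

test_that("mixture phasors are convex combinations on the chord", {
  p1 <- lifetime_to_phasor(16, 1e7)
  p2 <- lifetime_to_phasor(1.9, 1e7)
  for (a in c(0, 0.25, 0.5, 0.75, 1)) {
    ph <- mixture_phasor(decay_model(c(16, 1.9), c(a, 1 - a)), 1e7)
    expect_equal(ph$g, a * p1$g + (1 - a) * p2$g, tolerance = 1e-12)
    expect_equal(ph$s, a * p1$s + (1 - a) * p2$s, tolerance = 1e-12)
  }
  mid <- mixture_phasor(decay_model(c(16, 1.9), c(0.5, 0.5)), 1e7)
  expect_equal(c(mid$g, mid$s),
               c((p1$g + p2$g) / 2, (p1$s + p2$s) / 2), tolerance = 1e-12)
})

test_that("apparent phase lifetime is the identity on pure components and monotone in alpha", {
  expect_equal(apparent_phase_lifetime(decay_model(16, 1), 1e7), 16,
               tolerance = 1e-10)
  expect_equal(apparent_phase_lifetime(decay_model(1.9, 1), 1e7), 1.9,
               tolerance = 1e-10)
  alphas <- seq(0.01, 0.99, by = 0.01)
  taus <- vapply(alphas, function(a)
    apparent_phase_lifetime(decay_model(c(16, 1.9), c(a, 1 - a)), 1e7), 0)
  expect_true(all(diff(taus) > 0))
  # independent oracle: s/g assembled from the component phasors directly
  wt1 <- OMEGA_10MHZ * 16; wt2 <- OMEGA_10MHZ * 1.9
  g <- 0.783 / (1 + wt1^2) + 0.217 / (1 + wt2^2)
  s <- 0.783 * wt1 / (1 + wt1^2) + 0.217 * wt2 / (1 + wt2^2)
  expect_equal(
    apparent_phase_lifetime(decay_model(c(16, 1.9), c(0.783, 0.217)), 1e7),
    (s / g) / OMEGA_10MHZ, tolerance = 1e-12)
  expect_equal(
    apparent_phase_lifetime(decay_model(c(16, 1.9), c(0.783, 0.217)), 1e7),
    11.0, tolerance = 1e-3)
})

test_that("solve_long_fraction inverts the apparent lifetime and matches a grid search", {
  expect_equal(solve_long_fraction(16, 16, 1.9, 1e7), 1, tolerance = 1e-10)
  # limit case: alpha -> 0 as the target approaches the short component
  expect_equal(solve_long_fraction(1.9 + 1e-9, 16, 1.9, 1e7), 0,
               tolerance = 1e-6)
  # dense grid-search oracle for the 11.0 ns target
  grid <- seq(0, 1, by = 1e-5)
  tau_grid <- vapply(grid, function(a)
    apparent_phase_lifetime(decay_model(c(16, 1.9), c(a, 1 - a)), 1e7), 0)
  a_star <- grid[which.min(abs(tau_grid - 11.0))]
  expect_equal(solve_long_fraction(11.0, 16, 1.9, 1e7), a_star,
               tolerance = 2e-5)
  expect_equal(solve_long_fraction(11.0, 16, 1.9, 1e7), 0.783,
               tolerance = 1e-3)
  expect_error(solve_long_fraction(1.0, 16, 1.9, 1e7), "feasible")
  expect_error(solve_long_fraction(17, 16, 1.9, 1e7), "feasible")
})

test_that("solve_long_fraction o apparent_phase_lifetime is the identity", {
  set.seed(42)
  for (i in 1:40) {
    tl <- runif(1, 5, 20); ts <- runif(1, 0.1, 3)
    target <- runif(1, ts + 1e-3, tl)
    a <- solve_long_fraction(target, tl, ts, 1e7)
    expect_gte(a, -1e-12); expect_lte(a, 1 + 1e-12)
    back <- apparent_phase_lifetime(
      decay_model(c(tl, ts), c(a, 1 - a)), 1e7)
    expect_equal(back, target, tolerance = 1e-10)
  }
})

test_that("decay model validation rejects non-physical inputs", {
  expect_error(decay_model(c(16, -1), c(0.5, 0.5)), "positive")
  expect_error(decay_model(c(16, 2), c(0.7, 0.7)), "sum to 1")
  expect_error(decay_model(c(16, 2), c(1.2, -0.2)), "\\[0, 1\\]")
  expect_error(flim_config(n_phase_steps = 2), ">= 3")
  expect_error(flim_config(frequency_hz = -1))
})
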