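test_that("DFT demodulation is exact on noiseless sinusoids for any K >= 3", {
  set.seed(7)
  for (K in c(3L, 4L, 8L, 16L)) {
    cfg <- flim_config(1e7, K)
    phi <- runif(1, 0.05, 2 * pi - 0.05)
    m <- runif(1, 0.1, 1)
    dc <- runif(1, 10, 1e4)
    dem <- demodulate(sinusoid_stack(phi, m, dc, cfg))
    expect_equal(dem$phase_rad[1, 1], phi, tolerance = 1e-10)
    expect_equal(dem$modulation[1, 1], m, tolerance = 1e-10)
    expect_equal(dem$dc[1, 1], dc, tolerance = 1e-10)
  }
})

test_that("demodulation handles the stated worked examples", {
  dem <- demodulate(sinusoid_stack(pi / 3, 0.5, 100))
  expect_equal(dem$phase_rad[1, 1], pi / 3, tolerance = 1e-12)
  expect_equal(dem$modulation[1, 1], 0.5, tolerance = 1e-12)
  expect_equal(dem$dc[1, 1], 100, tolerance = 1e-12)
  # constant frames: zero AC component, phase indeterminate but flagged valid
  # only through dc > 0; modulation must be 0
  demc <- demodulate(sinusoid_stack(0, 0, 50))
  expect_equal(demc$modulation[1, 1], 0, tolerance = 1e-12)
  expect_equal(demc$dc[1, 1], 50)
  # dark pixels are flagged invalid, not errors
  dem0 <- demodulate(sinusoid_stack(1, 0.5, 0))
  expect_false(any(dem0$valid))
  expect_true(all(is.na(dem0$phase_rad)))
})

test_that("simulated frames follow the homodyne forward model", {
  cfg <- flim_config()
  tau_opt <- 1 / OMEGA_10MHZ
  st <- simulate_frames(decay_model(tau_opt, 1), 200, cfg)
  expected <- 200 * (1 + cos(cfg$phase_offsets_rad - pi / 4) / sqrt(2))
  expect_equal(as.vector(st$frames[1, 1, ]), expected, tolerance = 1e-9)
  # zero-lifetime (scattering) limit: phi = 0, m = 1
  st0 <- simulate_frames(decay_model(1e-9, 1), 200, cfg)
  expect_equal(as.vector(st0$frames[1, 1, ]),
               200 * (1 + cos(cfg$phase_offsets_rad)), tolerance = 1e-4)
  expect_error(simulate_frames(decay_model(5, 1), 100, cfg,
                               instrument_modulation = 0), "> 0")
  expect_error(simulate_frames(decay_model(5, 1), -5, cfg), "non-negative")
})

test_that("Poisson demodulation recovers the phase to Monte-Carlo accuracy", {
  cfg <- flim_config()
  frames <- array(0, c(25, 40, 16))
  for (k in 1:16)
    frames[, , k] <- 1e4 * (1 + 0.4 * cos(cfg$phase_offsets_rad[k] - 1.0))
  set.seed(99)
  frames <- array(rpois(length(frames), frames), dim = dim(frames))
  stack <- raw_frame_stack(frames, cfg)
  dem <- demodulate(stack)
  # 1000 pixel realizations at dc = 1e4, m = 0.4: the mean phase must sit
  # within +/- 0.01 rad of truth (per-pixel SD ~ sqrt(2/(K*dc*m^2)) ~ 0.009)
  expect_equal(mean(dem$phase_rad), 1.0, tolerance = 0.01)
  expect_equal(mean(dem$modulation), 0.4, tolerance = 0.01)
})

test_that("calibration recovers simulated instrument parameters", {
  cfg <- flim_config()
  # ideal instrument with a zero-lifetime reference
  ref0 <- simulate_frames(decay_model(1e-12, 1), 1000, cfg)
  cal0 <- calibrate(ref0, 0)
  expect_equal(cal0$instrument_phase_rad, 0, tolerance = 1e-9)
  expect_equal(cal0$instrument_modulation, 1, tolerance = 1e-9)
  # offset instrument observed through a 4 ns reference, noiseless
  ref <- simulate_frames(decay_model(4, 1), 1000, cfg,
                         instrument_phase_rad = 0.3,
                         instrument_modulation = 0.8)
  cal <- calibrate(ref, 4)
  expect_equal(cal$instrument_phase_rad, 0.3, tolerance = 1e-10)
  expect_equal(cal$instrument_modulation, 0.8, tolerance = 1e-10)
  # omega * tau_ref = 1 forces a subtracted true phase of exactly pi/4
  tau_opt <- 1 / OMEGA_10MHZ
  ref_opt <- simulate_frames(decay_model(tau_opt, 1), 1000, cfg)
  cal_opt <- calibrate(ref_opt, tau_opt)
  expect_equal(cal_opt$instrument_phase_rad, 0, tolerance = 1e-10)
  expect_equal(atan(OMEGA_10MHZ * tau_opt), pi / 4, tolerance = 1e-14)
  # reference without modulation cannot calibrate
  expect_error(calibrate(sinusoid_stack(0, 0, 0)), "calibration failure")
})

test_that("simulate -> calibrate -> reconstruct round trip is exact for any instrument", {
  set.seed(11)
  cfg <- flim_config()
  for (tau in c(0.1, 0.5, 1, 2, 5, 10, 15.9, 16)) {
    phi_i <- runif(1, -0.5, 0.5)
    # physical gains only: m_inst > 1 would push homodyne intensities
    # negative (clipped at zero) for short lifetimes
    m_i <- runif(1, 0.5, 1)
    st <- simulate_frames(decay_model(tau, 1), 5000, cfg,
                          instrument_phase_rad = phi_i,
                          instrument_modulation = m_i)
    ref <- simulate_frames(decay_model(1e-12, 1), 5000, cfg,
                           instrument_phase_rad = phi_i,
                           instrument_modulation = m_i)
    map <- reconstruct_map(st, calibrate(ref, 0))
    expect_true(all(map$valid))
    expect_equal(map$tau_ns[1, 1], tau, tolerance = 1e-9)
  }
})

test_that("reconstruction under shot noise is accurate at the map level", {
  cfg <- flim_config()
  tau <- 1 / OMEGA_10MHZ
  dc <- matrix(1e4, 128, 128)
  st <- simulate_frames(decay_model(tau, 1), dc, cfg, noise = "poisson",
                        seed = 5)
  ref <- simulate_frames(decay_model(1e-12, 1), dc, cfg, noise = "poisson",
                         seed = 6)
  map <- reconstruct_map(st, calibrate(ref, 0))
  expect_gt(mean(map$valid), 0.99)
  expect_equal(median(map$tau_ns[map$valid]), tau, tolerance = 0.01)
})

test_that("reconstruction rejects mismatched configurations and bad phases", {
  st <- simulate_frames(decay_model(5, 1), 1000, flim_config(1e7, 16))
  ref <- simulate_frames(decay_model(1e-12, 1), 1000, flim_config(1e7, 8))
  expect_error(reconstruct_map(st, calibrate(ref, 0)), "configuration")
  # negative calibrated phases (tau below the reference) are invalid pixels
  cal <- calibrate(simulate_frames(decay_model(1e-12, 1), 1000, flim_config(),
                                   instrument_phase_rad = 0.5), 0)
  m <- reconstruct_map(simulate_frames(decay_model(5, 1), 1000, flim_config()),
                       cal)
  expect_false(any(m$valid))
})
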