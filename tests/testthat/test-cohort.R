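test_that("default inventory reproduces the study composition", {
  inv <- default_inventory()
  expect_equal(nrow(inv), 42L)
  expect_equal(length(unique(inv$patient_id)), 21L)
  expect_equal(as.vector(table(inv$tissue)[c("NPL", "REA", "INF", "NEC", "TUM")]),
               c(2L, 5L, 12L, 7L, 16L))
  expect_equal(sum(inv$ala == "ALA_POS"), 21L)
  expect_equal(sum(inv$ala == "ALA_NEG"), 21L)
  expect_equal(as.vector(table(inv$grade)[c("LGG", "HGG", "MET")]),
               c(7L, 24L, 11L))
  # patient counts per grade
  pat <- unique(inv[, c("patient_id", "grade")])
  expect_equal(as.vector(table(pat$grade)[c("LGG", "HGG", "MET")]),
               c(3L, 14L, 4L))
  expect_false(anyDuplicated(inv$sample_id) > 0)
})

test_that("per-sample lifetime draws match the target distribution", {
  # degenerate quartiles collapse to the median
  set.seed(1)
  expect_equal(draw_sample_lifetime(2, 2, 2, n = 10), rep(2, 10))
  # lognormal draws: sample median within 1% of the 11.0 ns target
  set.seed(2)
  x <- draw_sample_lifetime(11.0, 8.2, 12.9, n = 1e5)
  expect_equal(median(x), 11.0, tolerance = 0.01)
  # the law fixes the median and the quartile ratio (a lognormal cannot
  # also match both quartiles when they are asymmetric about the median)
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  expect_equal(q[2] / q[1], 12.9 / 8.2, tolerance = 0.02)
  # clipping above the median leaves the median unchanged
  set.seed(3)
  xc <- draw_sample_lifetime(11.0, 8.2, 12.9, n = 1e5, range = c(1.95, 15.95))
  expect_true(all(xc <= 15.95))
  expect_equal(median(xc), 11.0, tolerance = 0.01)
})

test_that("noiseless jitter-free samples reconstruct to their drawn lifetime", {
  cfg <- exact_cohort_config()
  inv <- default_inventory()
  npl <- inv[inv$tissue == "NPL", ][1, ]
  smp <- generate_sample(npl, cfg, seed = 123)
  ref <- simulate_frames(decay_model(1e-12, 1),
                         matrix(cfg$photon_budget, 48, 48), cfg$flim,
                         cfg$instrument_phase_rad, cfg$instrument_modulation)
  cal <- calibrate(ref, 0)
  nadh <- reconstruct_map(smp$stacks$NADH, cal)
  vals <- nadh$tau_ns[smp$mask & nadh$valid]
  expect_gt(length(vals), 100)
  expect_equal(max(abs(vals / smp$true_tau_nadh_ns - 1)), 0, tolerance = 1e-9)
  # NPL NADH sits near 1.2 ns by construction
  expect_gt(smp$true_tau_nadh_ns, 0.9)
  expect_lt(smp$true_tau_nadh_ns, 1.6)
})

test_that("necrotic samples carry a sub-1 ns NADH core with reduced PPIX", {
  cfg <- exact_cohort_config()
  inv <- default_inventory()
  nec <- inv[inv$tissue == "NEC", ][1, ]
  smp <- generate_sample(nec, cfg, seed = 7)
  ref <- simulate_frames(decay_model(1e-12, 1),
                         matrix(cfg$photon_budget, 48, 48), cfg$flim,
                         cfg$instrument_phase_rad, cfg$instrument_modulation)
  cal <- calibrate(ref, 0)
  nadh <- reconstruct_map(smp$stacks$NADH, cal)
  expect_lt(min(nadh$tau_ns[smp$mask & nadh$valid]), 1)
})

test_that("vessel streaks exceed the NADH threshold and are removed by masking", {
  cfg <- exact_cohort_config(vessel_fraction = 1)
  inv <- default_inventory()
  tum <- inv[inv$tissue == "TUM", ][1, ]
  smp <- generate_sample(tum, cfg, seed = 21)
  ref <- simulate_frames(decay_model(1e-12, 1),
                         matrix(cfg$photon_budget, 48, 48), cfg$flim,
                         cfg$instrument_phase_rad, cfg$instrument_modulation)
  cal <- calibrate(ref, 0)
  nadh <- reconstruct_map(smp$stacks$NADH, cal)
  vessel_px <- smp$mask & nadh$valid & nadh$tau_ns > 5
  expect_gt(sum(vessel_px), 0)
  masked <- apply_mask(nadh, smp$mask, mask_config())
  expect_false(any(masked$tau_ns[masked$valid] >= 5))
})

test_that("cohort generation is reproducible and seed-sensitive where it should be", {
  cfg <- test_cohort_config()
  c1 <- generate_cohort(cfg, seed = 5)
  c2 <- generate_cohort(cfg, seed = 5)
  c3 <- generate_cohort(cfg, seed = 6)
  expect_equal(nrow(c1$manifest), 42L)
  expect_identical(c1$manifest, c2$manifest)
  expect_identical(c1$samples[["P01_S1"]]$stacks$PPIX$frames,
                   c2$samples[["P01_S1"]]$stacks$PPIX$frames)
  # different seed: same inventory, different lifetimes and pixels
  expect_identical(c1$manifest[, 1:6], c3$manifest[, 1:6])
  expect_false(isTRUE(all.equal(c1$manifest$true_tau_ppix_ns,
                                c3$manifest$true_tau_ppix_ns)))
  # duplicate ids rejected
  bad <- cfg
  bad$inventory <- rbind(bad$inventory, bad$inventory[1, ])
  expect_error(generate_cohort(bad, seed = 1), "duplicate")
})

test_that("ALA conditioning drives PPIX while NADH follows tissue", {
  set.seed(1)
  coh <- generate_cohort(test_cohort_config(mode = "ala"), seed = 17)
  man <- coh$manifest
  pos <- man$true_tau_ppix_ns[man$ala == "ALA_POS"]
  neg <- man$true_tau_ppix_ns[man$ala == "ALA_NEG" & man$tissue != "NPL"]
  expect_gt(median(pos), median(neg))
  # NPL samples always use NPL parameters for both channels
  npl <- man[man$tissue == "NPL", ]
  expect_true(all(npl$true_tau_ppix_ns < 3))
  expect_true(all(npl$true_tau_nadh_ns < 1.8))
})
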