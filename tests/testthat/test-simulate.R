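test_that("scenario configuration validates physiology", {
  expect_s3_class(scenario_config(), "eit_scenario")
  expect_error(scenario_config(rr = 0), "positive")
  expect_error(scenario_config(rr = 60, hr = 100), "band separability")
  expect_error(scenario_config(cardiac_frac = 0.5), "cardiac_frac")
  expect_error(scenario_config(brp = 7), "brp")
  expect_error(scenario_config(shift = 1.5), "shift")
})

test_that("breathing waveforms respect rate, range and breath boundaries", {
  wf <- breathing_waveform(2L, rr = 10, duration_s = 120, fps = 48, seed = 1)
  # about rr x duration cycles started; completed breaths one fewer at most
  expect_gte(nrow(wf$breaths), 18L)
  expect_lte(nrow(wf$breaths), 21L)
  expect_true(all(wf$v >= 0 & wf$v <= 1))
  # normalised expiration endpoints: filling 1 at end-inspiration, 0 at end
  v_insp <- wf$v[wf$breaths$i_end_insp]
  expect_true(all(v_insp > 0.99))
  v_exp <- wf$v[wf$breaths$i_start_insp]
  expect_true(all(v_exp < 0.05))
  expect_error(breathing_waveform(1L, rr = 10, duration_s = 2), "duration")
})

test_that("conductivity movies honour region physiology", {
  p <- test_chicken_phantom()
  wf <- breathing_waveform(1L, rr = 12, duration_s = 20, fps = 48, seed = 3)
  cfg <- scenario_config(rr = 12, duration_s = 20, seed = 3)
  sig <- conductivity_movie(p, wf, cfg)
  lab <- p$element_labels
  # lungs and background are isovolumetric: constant over time
  expect_equal(max(abs(sig[lab == "lung_r", ] - 0.3)), 0)
  expect_equal(max(abs(sig[lab == "lung_l", ] - 0.3)), 0)
  expect_equal(max(abs(sig[lab == "background", ] - 0.3)), 0)
  # air filling lowers conductivity
  expect_true(all(sig[lab == "airsac", ] <= 0.3 + 1e-12))
  # zero shift: left and right air-sac gains identical (mirror elements)
  i_end <- wf$breaths$i_end_insp[1L]
  air <- which(lab == "airsac")
  drop <- 1 - sig[air, i_end] / 0.3
  expect_lt(diff(range(drop)) / max(drop), 1e-9)
  # cardiac flutter off: cardiac constant
  cfg0 <- scenario_config(rr = 12, duration_s = 20, cardiac_frac = 0)
  sig0 <- conductivity_movie(p, wf, cfg0)
  expect_equal(max(abs(sig0[lab == "cardiac", ] - 0.3)), 0)
  # flat waveform: everything constant
  wf0 <- wf; wf0$v[] <- 0
  sigf <- conductivity_movie(p, wf0, cfg)
  expect_equal(max(abs(sigf[lab == "airsac", ] - 0.3)), 0)
  # non-physical amplitude rejected
  expect_error(conductivity_movie(p, wf, scenario_config(tiv_scale = 0.9,
                                                         shift = 0.5)),
               "tiv_scale")
})

test_that("imposed shift biases air-sac gains toward the non-dependent side", {
  p <- test_chicken_phantom()
  wf <- breathing_waveform(1L, rr = 12, duration_s = 20, fps = 48, seed = 3)
  i_end <- wf$breaths$i_end_insp[1L]
  air <- p$element_labels == "airsac"
  x <- p$element_centroids[air, 1L]
  # right lateral recumbency, positive shift: non-dependent = left (+x)
  cfg <- scenario_config(recumbency = "right_lateral", shift = 0.3,
                         rr = 12, duration_s = 20)
  drop <- 1 - conductivity_movie(p, wf, cfg)[air, i_end] / 0.3
  expect_gt(stats::cor(x, drop), 0.9)
  cfgL <- scenario_config(recumbency = "left_lateral", shift = 0.3,
                          rr = 12, duration_s = 20)
  dropL <- 1 - conductivity_movie(p, wf, cfgL)[air, i_end] / 0.3
  expect_lt(stats::cor(x, dropL), -0.9)
  # gains bounded by 1 +/- |shift|
  g <- drop / max(drop) * (1 + 0.3)
  expect_lt(max(g), 1.3 + 1e-9)
})

test_that("recordings are reproducible and noise leaves timing untouched", {
  p <- test_chicken_phantom(6)
  pat <- test_pattern()
  cfg <- scenario_config(duration_s = 15, rr = 16, hr = 320, seed = 77)
  r1 <- simulate_recording(p, cfg, pat)
  r2 <- simulate_recording(p, cfg, pat)
  expect_identical(r1$voltages, r2$voltages)
  cfg0 <- scenario_config(duration_s = 15, rr = 16, hr = 320, seed = 77,
                          noise_sd = 0)
  r0 <- simulate_recording(p, cfg0, pat)
  # same waveform and breath boundaries with and without channel noise
  expect_identical(r0$truth$breaths, r1$truth$breaths)
  expect_identical(r0$truth$volume, r1$truth$volume)
  expect_false(identical(r0$voltages, r1$voltages))
})
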