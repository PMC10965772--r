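synthetic_stream <- function(z, fps = 48) {
  # wrap a global signal into a 1-pixel image stream
  arr <- array(0, c(32L, 32L, length(z)))
  arr[16L, 16L, ] <- z
  mask <- matrix(FALSE, 32L, 32L); mask[16L, 16L] <- TRUE
  structure(list(frames = arr, fps = fps, mask = mask),
            class = "eit_image_stream")
}

curve_of <- function(z, fps = 48, filtered = TRUE) {
  structure(list(z = z, fps = fps, filtered = filtered),
            class = "eit_global_curve")
}

test_that("global_curve sums in-mask pixels linearly", {
  z <- sin(2 * pi * 0.2 * (0:199) / 48)
  st <- synthetic_stream(z)
  gc <- global_curve(st)
  expect_equal(gc$z, z)
  st2 <- st; st2$frames <- 2 * st$frames
  expect_equal(global_curve(st2)$z, 2 * z)
  # zero stream gives the zero curve
  st0 <- st; st0$frames[] <- 0
  expect_equal(global_curve(st0)$z, rep(0, 200L))
})

test_that("the global curve of simulator output peaks at the respiratory rate", {
  p <- test_chicken_phantom()
  cfg <- scenario_config(duration_s = 60, rr = 10, seed = 31,
                         noise_sd = 0, cardiac_frac = 0)
  rec <- simulate_recording(p, cfg, test_pattern())
  st <- reconstruct(test_model(), rec$voltages[, 1L], rec$voltages)
  z <- global_curve(st)$z
  sp <- Mod(stats::fft(z - mean(z)))[2:(length(z) %/% 2)]
  fpk <- which.max(sp) * 48 / length(z)
  expect_lt(abs(fpk - 10 / 60), 48 / length(z) + 1e-9)  # within one bin
})

test_that("remove_cardiac passes respiration and suppresses flutter", {
  t <- (0:(48 * 40 - 1)) / 48
  resp <- sin(2 * pi * 0.15 * t)
  flut <- 0.03 * sin(2 * pi * 4 * t)
  f <- remove_cardiac(curve_of(resp + flut, filtered = FALSE))
  mid <- 200:1700
  # respiratory band essentially unchanged
  expect_lt(max(abs(f$z[mid] - resp[mid])) / 1, 0.01)
  # 4 Hz component attenuated by more than 40 dB
  resid <- f$z[mid] - resp[mid]
  expect_lt(sqrt(mean(resid^2)) / (0.03 / sqrt(2)), 10^(-40 / 20))
  # constant curve unchanged
  cst <- remove_cardiac(curve_of(rep(3.2, 500L), filtered = FALSE))
  expect_equal(cst$z, rep(3.2, 500L), tolerance = 1e-9)
  expect_error(remove_cardiac(curve_of(resp), cutoff = 24), "Nyquist")
})

test_that("breath detection recovers sinusoidal cycles, TIV and rate", {
  t <- (0:(48 * 120 - 1)) / 48
  A <- 4.4
  z <- (A / 2) * sin(2 * pi * (10 / 60) * t)   # peak-to-trough amplitude A
  br <- detect_breaths(curve_of(z))
  expect_gte(nrow(br), 19L)
  expect_lte(nrow(br), 20L)
  span_s <- (br$i_end_exp[nrow(br)] - br$i_start_insp[1L]) / 48
  rr <- nrow(br) / span_s * 60
  expect_lt(abs(rr - 10), 0.5)
  expect_equal(br$tiv, rep(A, nrow(br)), tolerance = 0.02)
  # TIV is invariant to a constant offset
  br2 <- detect_breaths(curve_of(z + 100))
  expect_equal(br2$tiv, br$tiv, tolerance = 1e-12)
})

test_that("breath detection matches generator amplitude at the observed TIV", {
  # waveform scaled to the study's mean dorsal-recumbency TIV of 6.65 AU
  wf <- breathing_waveform(1L, rr = 10, duration_s = 120, fps = 48, seed = 2)
  br <- detect_breaths(curve_of(6.65 * wf$v))
  expect_true(all(abs(br$tiv - 6.65) <= 0.07))
})

test_that("detection warns when no cycles exist", {
  expect_warning(br <- detect_breaths(curve_of(rep(1, 100L))), "no complete breath")
  expect_equal(nrow(br), 0L)
})

test_that("artefact-free selection returns the earliest longest clean run", {
  wf <- breathing_waveform(1L, rr = 10, duration_s = 145, fps = 48, seed = 8)
  br <- detect_breaths(curve_of(wf$v))
  expect_gte(nrow(br), 20L)
  br <- br[1:20, ]
  # 20 clean breaths: first 10 returned
  sel <- select_artefact_free(br, fps = 48)
  expect_equal(nrow(sel), 10L)
  expect_equal(sel$i_start_insp, br$i_start_insp[1:10])
  # one TIV outlier at position 8 splits the runs; positions 9..18 win
  br2 <- br
  br2$tiv[8L] <- 3 * stats::median(br$tiv)
  sel2 <- select_artefact_free(br2, fps = 48)
  expect_equal(nrow(sel2), 10L)
  expect_equal(sel2$i_start_insp, br$i_start_insp[9:18])
  # fewer than min_n clean breaths is an error
  expect_error(select_artefact_free(br[1:5, ], fps = 48),
               "insufficient artefact-free breaths")
})
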