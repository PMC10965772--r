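expiration_of <- function(shape, n = 145L, fs = 48) {
  tau <- (0:(n - 1)) / (n - 1)
  z <- shape(tau)
  structure(list(z_norm = (z - z[n]) / (z[1L] - z[n]), tau = tau, fs = fs),
            class = "eit_expiration")
}

test_that("expiration extraction normalises endpoints and shape", {
  z <- c(rep(0, 10L), seq(0, 1, length.out = 20L), seq(1, 0.2, length.out = 41L)[-1L])
  cv <- structure(list(z = 5 + 3 * z, fps = 48, filtered = TRUE),
                  class = "eit_global_curve")
  b <- data.frame(i_start_insp = 11L, i_end_insp = 30L, i_end_exp = 70L)
  e <- extract_expiration(cv, b)
  expect_equal(e$z_norm[1L], 1)
  expect_equal(e$z_norm[length(e$z_norm)], 0)
  # linear decay maps to 1 - tau
  expect_equal(e$z_norm, 1 - e$tau, tolerance = 1e-9)
  b_short <- data.frame(i_start_insp = 1L, i_end_insp = 30L, i_end_exp = 33L)
  expect_error(extract_expiration(cv, b_short), "too short")
})

test_that("pause detection finds interior plateaus and ignores decays", {
  # pure exponential decay: no pause
  e <- expiration_of(function(tau) exp(-3 * tau))
  expect_null(detect_pause(e))
  # 0.5 s plateau at level 0.6 (3 s expiration)
  plateau <- function(level, pfrac, at) function(tau) {
    d1 <- at; d2 <- at + pfrac
    ifelse(tau < d1, 1 - (1 - level) * tau / d1,
           ifelse(tau < d2, level, level * (1 - (tau - d2) / (1 - d2))))
  }
  e2 <- expiration_of(plateau(0.6, 0.5 / 3, 0.3))
  pp <- detect_pause(e2)
  expect_false(is.null(pp))
  expect_equal(pp$onset_level, 0.60, tolerance = 0.02)
  expect_gte(pp$duration_s, 0.3)
  # a 0.2 s plateau is below the minimum duration
  e3 <- expiration_of(plateau(0.6, 0.2 / 3, 0.3))
  expect_null(detect_pause(e3))
})

test_that("breaths classify by curvature and pause onset", {
  concave <- expiration_of(function(tau) 1 - tau^2)
  expect_equal(classify_breath(concave)$label, "BrP1")
  convex <- expiration_of(function(tau) (1 - tau)^2)
  expect_equal(classify_breath(convex)$label, "BrP2")
  linear <- expiration_of(function(tau) 1 - tau)
  expect_equal(classify_breath(linear)$label, "BrP1")   # A >= 0 tie-break
  plateau <- function(level) function(tau) {
    d1 <- 0.3; d2 <- 0.5
    ifelse(tau < d1, 1 - (1 - level) * tau / d1,
           ifelse(tau < d2, level, level * (1 - (tau - d2) / (1 - d2))))
  }
  hi <- classify_breath(expiration_of(plateau(0.6)))
  expect_equal(hi$label, "BrP3")
  expect_equal(hi$pause_level, 0.6, tolerance = 0.02)
  lo <- classify_breath(expiration_of(plateau(0.4)))
  expect_equal(lo$label, "BrP4")
  expect_equal(lo$pause_level, 0.4, tolerance = 0.02)
})

test_that("classification is invariant to amplitude and time resampling", {
  shapes <- list(function(tau) 1 - tau^2, function(tau) (1 - tau)^2)
  labs <- c("BrP1", "BrP2")
  for (k in 1:2) {
    base <- classify_breath(expiration_of(shapes[[k]], n = 145L))$label
    expect_equal(base, labs[k])
    # different sampling density
    expect_equal(classify_breath(expiration_of(shapes[[k]], n = 73L))$label, labs[k])
    # amplitude scaling happens upstream in extract_expiration; the
    # normalised curve is identical by construction
    cv <- structure(list(z = 10 + 7 * shapes[[k]]((0:100) / 100), fps = 48,
                         filtered = TRUE), class = "eit_global_curve")
    b <- data.frame(i_start_insp = 1L, i_end_insp = 1L, i_end_exp = 101L)
    expect_equal(classify_breath(extract_expiration(cv, b))$label, labs[k])
  }
})

test_that("recording labels require 95% uniformity", {
  expect_equal(classify_recording(rep("BrP3", 10L)), "BrP3")
  expect_equal(classify_recording(c(rep("BrP3", 9L), "BrP2")), "mixed")
  expect_equal(classify_recording(rep("BrP1", 20L)), "BrP1")
  expect_equal(classify_recording(c(rep("BrP1", 19L), "BrP4")), "BrP1")
  expect_error(classify_recording(character()), "no breath labels")
})

test_that("generated waveforms classify back to their generating pattern", {
  for (brp in 1:4) {
    wf <- breathing_waveform(brp, rr = 10, duration_s = 60, fps = 48, seed = 40 + brp)
    cv <- structure(list(z = wf$v, fps = 48, filtered = TRUE),
                    class = "eit_global_curve")
    labs <- vapply(seq_len(nrow(wf$breaths)), function(k) {
      e <- extract_expiration(cv, wf$breaths[k, ])
      classify_breath(e)$label
    }, character(1L))
    expect_true(all(labs == paste0("BrP", brp)),
                info = paste("brp", brp, ":", paste(labs, collapse = " ")))
  }
})
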