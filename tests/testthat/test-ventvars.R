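test_that("CoV conventions place extreme distributions at 0 and 100 percent", {
  m <- matrix(0, 32L, 32L)
  mask <- matrix(TRUE, 32L, 32L)
  # all signal in the leftmost column (column 32 = subject's left)
  m[, 32L] <- 1
  expect_identical(centre_of_ventilation(functional_image(m, mask), "RL"), 100)
  # all signal in the ventral-most row (row 32)
  m2 <- matrix(0, 32L, 32L); m2[32L, ] <- 1
  expect_identical(centre_of_ventilation(functional_image(m2, mask), "VD"), 0)
  # mirror-symmetric image sits at exactly 50%
  set.seed(2)
  half <- matrix(stats::runif(32 * 16), 32L, 16L)
  sym <- cbind(half, half[, 16:1])
  expect_equal(centre_of_ventilation(functional_image(sym, mask), "RL"), 50,
               tolerance = 1e-9)
  expect_error(centre_of_ventilation(functional_image(matrix(0, 32, 32), mask)),
               "no ventilation signal")
})

test_that("RL ratio splits at the bounding-box midline", {
  mask <- matrix(TRUE, 32L, 32L)
  set.seed(3)
  half <- matrix(stats::runif(32 * 16), 32L, 16L)
  sym <- cbind(half, half[, 16:1])
  expect_equal(rl_ratio(functional_image(sym, mask)), 1, tolerance = 1e-9)
  # 60% of signal right (low columns), 40% left
  m <- matrix(0, 32L, 32L)
  m[16L, 4L] <- 60; m[16L, 28L] <- 40
  expect_equal(rl_ratio(functional_image(m, mask)), 1.5, tolerance = 1e-12)
  m2 <- matrix(0, 32L, 32L); m2[10L, 3L] <- 1
  expect_error(rl_ratio(functional_image(m2, mask)), "undefined RL ratio")
})

test_that("regional distribution sums to 100 and localises correctly", {
  mask <- matrix(TRUE, 32L, 32L)
  set.seed(4)
  img <- matrix(stats::rexp(1024), 32L, 32L)
  reg <- regional_distribution(functional_image(img, mask))
  expect_equal(sum(reg), 100, tolerance = 1e-9)
  expect_true(all(reg >= 0))
  # all signal inside one band-side: right ventral (rows 25..32, cols 1..16)
  m <- matrix(0, 32L, 32L); m[27L, 5L] <- 3
  reg2 <- regional_distribution(functional_image(m, mask))
  expect_equal(unname(reg2["R_V"]), 100)
  expect_equal(sum(reg2[names(reg2) != "R_V"]), 0)
  # uniform image: each region share equals its pixel-count share
  u <- regional_distribution(functional_image(matrix(1, 32, 32), mask))
  expect_equal(unname(u), rep(100 / 8, 8L), tolerance = 1e-9)
})

test_that("distribution metrics are scale invariant and mirror equivariant", {
  mask <- matrix(TRUE, 32L, 32L)
  set.seed(5)
  img <- matrix(stats::rnorm(1024, 1, 0.5), 32L, 32L)   # includes negatives
  f <- functional_image(img, mask)
  fa <- functional_image(7.3 * img, mask)
  expect_equal(centre_of_ventilation(fa, "RL"), centre_of_ventilation(f, "RL"),
               tolerance = 1e-12)
  expect_equal(centre_of_ventilation(fa, "VD"), centre_of_ventilation(f, "VD"),
               tolerance = 1e-12)
  expect_equal(rl_ratio(fa), rl_ratio(f), tolerance = 1e-12)
  expect_equal(regional_distribution(fa), regional_distribution(f),
               tolerance = 1e-12)
  # mirror: CoV_RL -> 100 - CoV_RL, ratio -> 1/ratio, R/L regions swap
  fm <- functional_image(img[, 32:1], mask)
  expect_equal(centre_of_ventilation(fm, "RL"),
               100 - centre_of_ventilation(f, "RL"), tolerance = 1e-9)
  expect_equal(rl_ratio(fm), 1 / rl_ratio(f), tolerance = 1e-9)
  rf <- regional_distribution(f); rm <- regional_distribution(fm)
  expect_equal(unname(rm[c("L_D", "L_CD", "L_CV", "L_V")]),
               unname(rf[c("R_D", "R_CD", "R_CV", "R_V")]), tolerance = 1e-9)
})

test_that("tidal images difference the breath's end frames", {
  arr <- array(0, c(32L, 32L, 5L))
  arr[, , 3L] <- 2; arr[, , 1L] <- 0.5
  mask <- matrix(TRUE, 32L, 32L)
  st <- structure(list(frames = arr, fps = 48, mask = mask),
                  class = "eit_image_stream")
  b <- data.frame(i_start_insp = 1L, i_end_insp = 3L, i_end_exp = 5L)
  f <- tidal_image(st, b)
  expect_equal(f$pixels, matrix(1.5, 32L, 32L))
  # identical frames give the zero image
  b0 <- data.frame(i_start_insp = 2L, i_end_insp = 4L, i_end_exp = 5L)
  expect_equal(max(abs(tidal_image(st, b0)$pixels)), 0)
  expect_error(tidal_image(st, data.frame(i_start_insp = 1L, i_end_insp = 9L,
                                          i_end_exp = 10L)), "out of range")
})

test_that("per-breath variables aggregate to their means", {
  arr <- array(0, c(32L, 32L, 4L))
  # two breaths with mirrored left/right weighting (both sides positive so
  # the RL ratio stays defined)
  arr[10L, 10L, 2L] <- 2; arr[10L, 23L, 2L] <- 1
  arr[10L, 10L, 4L] <- 1; arr[10L, 23L, 4L] <- 2
  mask <- matrix(TRUE, 32L, 32L)
  st <- structure(list(frames = arr, fps = 48, mask = mask),
                  class = "eit_image_stream")
  br <- data.frame(i_start_insp = c(1L, 3L), i_end_insp = c(2L, 4L),
                   i_end_exp = c(3L, 4L), tiv = c(1, 1), t_insp = c(0.5, 0.5))
  out <- variables_for_breaths(st, br)
  expect_equal(nrow(out$per_breath), 2L)
  # single breath: mean equals that breath
  one <- variables_for_breaths(st, br[1L, ])
  expect_equal(unname(one$means["cov_rl"]), one$per_breath$cov_rl[1L])
  # two breaths at mirrored columns average to 50%
  expect_equal(unname(out$means["cov_rl"]),
               mean(out$per_breath$cov_rl), tolerance = 1e-12)
  expect_equal(unname(out$means["cov_rl"]), 50, tolerance = 2)
})
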