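# the observed breathing-pattern frequencies by recumbency (10 chickens,
# one left-lateral recording excluded), used throughout as the reference
# contingency table
brp_counts <- matrix(c(5, 0, 1, 4,
                       2, 1, 3, 4,
                       0, 1, 7, 1,
                       0, 2, 8, 0), nrow = 4L, byrow = TRUE,
                     dimnames = list(c("dorsal", "ventral", "right_lateral",
                                       "left_lateral"),
                                     paste0("BrP", 1:4)))

test_that("2x2 exact test equals the hypergeometric enumeration", {
  t22 <- matrix(c(3, 1, 1, 3), 2L)
  p <- fisher_exact_rxc(t22, "exact")$p.value
  expect_equal(p, 34 / 70, tolerance = 1e-12)
  # direct hypergeometric sum over the free cell a = 0..4
  probs <- stats::dhyper(0:4, 4, 4, 4)
  p_direct <- sum(probs[probs <= stats::dhyper(3, 4, 4, 4) + 1e-12])
  expect_equal(p, p_direct, tolerance = 1e-12)
})

test_that("identical rows give p = 1", {
  t0 <- matrix(c(2, 3, 4, 2, 3, 4, 0, 0, 0), 3L, byrow = TRUE)
  expect_equal(fisher_exact_rxc(t0, "exact")$p.value, 1, tolerance = 1e-12)
})

test_that("the r x c exact test agrees with the reference implementation", {
  ours <- fisher_exact_rxc(brp_counts, "exact")$p.value
  oracle <- stats::fisher.test(brp_counts, workspace = 2e7)$p.value
  expect_equal(ours, oracle, tolerance = 1e-8)
  expect_equal(round(ours, 3), 0.001)
  # a second, asymmetric table
  t2 <- matrix(c(1, 5, 2, 0, 3, 4, 6, 1, 2), 3L, byrow = TRUE)
  expect_equal(fisher_exact_rxc(t2, "exact")$p.value,
               stats::fisher.test(t2)$p.value, tolerance = 1e-8)
})

test_that("the exact p-value is invariant to row and column permutations", {
  p0 <- fisher_exact_rxc(brp_counts, "exact")$p.value
  set.seed(6)
  for (k in 1:3) {
    t2 <- brp_counts[sample(4L), sample(4L)]
    expect_equal(fisher_exact_rxc(t2, "exact")$p.value, p0, tolerance = 1e-12)
  }
})

test_that("Monte-Carlo p converges to the exact p", {
  t22 <- matrix(c(3, 1, 1, 3), 2L)
  pe <- 34 / 70
  mc <- fisher_exact_rxc(t22, "montecarlo", mc_reps = 1e5, seed = 9)
  expect_lt(abs(mc$p.value - pe), 3 * sqrt(pe * (1 - pe) / 1e5))
  mcb <- fisher_exact_rxc(brp_counts, "montecarlo", mc_reps = 1e5, seed = 9)
  pb <- fisher_exact_rxc(brp_counts, "exact")$p.value
  expect_lt(abs(mcb$p.value - pb), 3 * sqrt(pb * (1 - pb) / 1e5) + 1e-4)
})

test_that("degenerate tables are rejected", {
  expect_error(fisher_exact_rxc(matrix(0, 2, 2)), "empty")
  expect_error(fisher_exact_rxc(matrix(c(-1, 2, 3, 4), 2)), "non-negative")
})

test_that("frequency tables count labels by recumbency, excluding mixed", {
  labs <- c(rep("BrP3", 10L), "mixed", "BrP1")
  rec <- c(rep("dorsal", 10L), "ventral", "ventral")
  tab <- brp_frequency_table(labs, rec)
  expect_equal(unname(tab["dorsal", ]), c(0L, 0L, 10L, 0L))
  expect_equal(unname(tab["ventral", ]), c(1L, 0L, 0L, 0L))
  # empty group yields a zero row
  tab2 <- brp_frequency_table(c("BrP2"), factor("dorsal",
                              levels = c("dorsal", "ventral")))
  expect_equal(sum(tab2), 1L)
})

test_that("summaries bracket group means with t intervals", {
  df <- data.frame(recumbency = rep(c("dorsal", "ventral"), each = 3L),
                   cov_rl = c(40, 50, 60, 48, 48, 48))
  s <- summarize_recordings(df)
  d <- s[s$recumbency == "dorsal" & s$variable == "cov_rl", ]
  expect_equal(d$mean, 50)
  expect_true(d$lo < 50 && d$hi > 50)
  v <- s[s$recumbency == "ventral" & s$variable == "cov_rl", ]
  expect_equal(v$hi - v$lo, 0)
  # singleton group: mean with absent CI
  s1 <- summarize_recordings(data.frame(recumbency = "dorsal", x = 5))
  expect_true(is.na(s1$lo))
  expect_equal(s1$mean, 5)
})
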