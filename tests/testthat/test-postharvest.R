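test_that("respiration rate matches the hand-checked closed-jar formula", {
  hs <- headspace_series(c(0, 6), c(0, 1.2), mass_kg = 0.1,
                         headspace_ml = 900)
  expect_equal(respiration_rate(hs), 18)          # (0.012*900)/(0.1*6)
  flat <- headspace_series(c(0, 6), c(0.5, 0.5), 0.1, 900)
  expect_equal(respiration_rate(flat), 0)
})

test_that("respiration rate scales linearly in V and inversely in m and dt", {
  mk <- function(m, V, dt, dco2) {
    respiration_rate(headspace_series(c(0, dt), c(0, dco2), m, V))
  }
  base <- mk(0.1, 900, 6, 1.2)
  expect_equal(mk(0.1, 1800, 6, 1.2), 2 * base)
  expect_equal(mk(0.2, 900, 6, 1.2), base / 2)
  expect_equal(mk(0.1, 900, 3, 1.2), 2 * base)
})

test_that("respiration recovery from generated headspace data", {
  hs <- gen_headspace_series(18, noise_sd_pct = 0.02, seed = 31)
  expect_equal(respiration_rate(hs, window = c(0, 6)), 18, tolerance = 0.05)
  # slope method is available for noisy analysers
  expect_equal(respiration_rate(hs, window = c(0, 6), method = "slope"), 18,
               tolerance = 0.05)
  expect_error(respiration_rate(hs, window = c(0, 0.1)), "2 samples")
})

test_that("weight-loss fraction interpolates and respects its bounds", {
  ws <- weight_series(c(0, 7, 14), c(20, 11, 6))
  expect_equal(weight_loss_fraction(ws, 0), 0)
  expect_equal(weight_loss_fraction(ws, 14), 0.70)
  expect_equal(weight_loss_fraction(ws, 10.5), 1 - 8.5 / 20)  # interpolated
  expect_error(weight_loss_fraction(ws, 15), "outside")
  const <- weight_series(c(0, 5, 10), rep(20, 3))
  expect_equal(weight_loss_fraction(const, c(0, 5, 10)), c(0, 0, 0))
  # monotone nondecreasing in day for nonincreasing weights
  days <- seq(0, 14, by = 0.5)
  expect_true(all(diff(weight_loss_fraction(ws, days)) >= 0))
  expect_true(all(weight_loss_fraction(ws, days) >= 0 &
                    weight_loss_fraction(ws, days) <= 1))
})

test_that("maximum penetration force reads the depth-windowed peak", {
  p <- gen_puncture_curve(4.2, peak_depth_mm = 6, noise_sd_n = 0, seed = 1)
  expect_equal(max_penetration_force(p), 4.2, tolerance = 1e-9)
  # monotone curve: the window endpoint value wins
  mono <- puncture_curve(seq(0, 8, 0.5), seq(0, 3, length.out = 17))
  expect_equal(max_penetration_force(mono), 3.0)
  trunc <- puncture_curve(seq(0, 5, 0.5), seq(0, 2, length.out = 11))
  expect_warning(max_penetration_force(trunc), "truncated")
  expect_error(puncture_curve(numeric(0), numeric(0)), "empty")
  # replicate aggregation
  fs <- firmness_summary(list(
    gen_puncture_curve(4.0, noise_sd_n = 0, seed = 1),
    gen_puncture_curve(4.4, noise_sd_n = 0, seed = 2)))
  expect_equal(fs$mean_n, 4.2, tolerance = 1e-9)
  expect_equal(fs$per_curve, c(4.0, 4.4), tolerance = 1e-9)
})

test_that("identical groups give F near zero and no flagged pairs", {
  v <- rep(c(1.0, 1.1, 0.9, 1.05), 3)
  g <- rep(c("a", "b", "c"), each = 4)
  gc <- group_compare(v, g)
  expect_lt(gc$anova$F, 1e-10)
  expect_false(any(gc$tukey$significant))
})

test_that("a large two-group difference is flagged at alpha 0.05", {
  withr::with_seed(5, {
    v <- c(rnorm(5, 0, 0.1), rnorm(5, 10, 0.1))
  })
  g <- rep(c("ctrl", "coated"), each = 5)
  gc <- group_compare(v, g)
  expect_lt(gc$anova$p, 1e-6)
  expect_true(all(gc$tukey$significant))
  # hand ANOVA arithmetic cross-check: F = MSB / MSW
  msb <- sum(5 * (tapply(v, g, mean) - mean(v))^2) / 1
  msw <- sum((v - ave(v, g))^2) / 8
  expect_equal(gc$anova$F, msb / msw, tolerance = 1e-10)
})

test_that("two-way design reports both factors", {
  withr::with_seed(8, {
    d <- expand.grid(beta = c("23", "36", "48"), dips = c("1", "2", "4"),
                     rep = 1:3)
    d$y <- as.numeric(d$beta) * 0.5 + rnorm(nrow(d), sd = 0.3)
  })
  gc <- group_compare(d$y, d$beta, d$dips, design = "two-way")
  expect_setequal(gc$anova$factor, c("g1", "g2"))
  expect_error(group_compare(d$y, d$beta, design = "two-way"), "group2")
})

test_that("ANOVA accept/reject agrees with a permutation oracle", {
  perm_p <- function(v, g, n_perm = 2000) {
    k <- nlevels(g)
    n <- length(v)
    fstat <- function(y) {
      m <- tapply(y, g, mean)
      cnt <- tabulate(g)
      ssb <- sum(cnt * (m - mean(y))^2)
      ssw <- sum((y - m[g])^2)
      (ssb / (k - 1)) / (ssw / (n - k))
    }
    f0 <- fstat(v)
    hits <- 0
    for (b in seq_len(n_perm)) {
      if (fstat(sample(v)) >= f0) hits <- hits + 1
    }
    (hits + 1) / (n_perm + 1)
  }
  agree <- withr::with_seed(77, {
    vapply(1:60, function(i) {
      k <- sample(2:3, 1)
      n_per <- sample(3:5, 1)
      effect <- runif(1, 0, 2)
      g <- factor(rep(seq_len(k), each = n_per))
      v <- rnorm(k * n_per) + effect * (as.integer(g) - 1)
      p_aov <- group_compare(v, g)$anova$p
      (p_aov < 0.05) == (perm_p(v, g) < 0.05)
    }, NA)
  })
  expect_gte(mean(agree), 0.95)
})

test_that("degenerate group designs are rejected", {
  expect_error(group_compare(1:4, rep("a", 4)), "2 groups")
  expect_error(group_compare(c(1, 2, 3), c("a", "a", "b")),
               "2 observations")
})
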