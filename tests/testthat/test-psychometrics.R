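# Psychometric fitting and the implied-uncertainty algebra.

test_that("cumulative Gaussian fit recovers known generating parameters", {
  set.seed(3)
  levels <- seq(-1.2, 1.2, length.out = 7)
  n <- rep(500, 7)
  p <- pnorm((levels - 0.3) / 0.5)
  k <- rbinom(7, n, p)
  fit <- fit_cumulative_gaussian(levels, k, n)
  expect_false(fit$flagged)
  # 95% CI scale for 3500 trials is a few hundredths on each parameter
  expect_equal(fit$mu, 0.3, tolerance = 0.25)
  expect_equal(fit$sigma, 0.5, tolerance = 0.25)
  # symmetric data give a PSE near zero
  k2 <- rbinom(7, n, pnorm(levels / 0.4))
  expect_lt(abs(fit_cumulative_gaussian(levels, k2, n)$mu), 0.1)
  # step data: fitted sigma below one level spacing
  k3 <- ifelse(levels > 0, 400, 0)
  fit3 <- fit_cumulative_gaussian(levels, k3, rep(400, 7))
  expect_lt(fit3$sigma, 0.4)
  # degenerate data are flagged
  expect_true(fit_cumulative_gaussian(levels, rep(0, 7), n)$flagged)
  expect_true(fit_cumulative_gaussian(levels, n, n)$flagged)
})

test_that("fits are invariant to affine rescaling of the level axis", {
  set.seed(4)
  levels <- seq(-1.2, 1.2, length.out = 7)
  n <- rep(200, 7)
  k <- rbinom(7, n, pnorm((levels - 0.2) / 0.45))
  f1 <- fit_cumulative_gaussian(levels, k, n)
  f2 <- fit_cumulative_gaussian(3 * levels + 1, k, n)
  expect_equal(f2$mu, 3 * f1$mu + 1, tolerance = 1e-3)
  expect_equal(f2$sigma, 3 * f1$sigma, tolerance = 1e-3)
})

test_that("scaled cumulative Gaussian returns the 75% threshold", {
  set.seed(5)
  levels <- seq(0, 2, length.out = 7)
  n <- rep(400, 7)
  k <- rbinom(7, n, 0.5 + 0.5 * pnorm((levels - 1) / 0.4))
  fit <- fit_scaled_cumulative_gaussian(levels, k, n)
  expect_false(fit$flagged)
  expect_equal(fit$threshold, 1, tolerance = 0.15)
  # chance-only data: unmeasurable
  kc <- rbinom(7, n, 0.5)
  expect_true(fit_scaled_cumulative_gaussian(levels, kc, n)$unmeasurable)
  # ceiling data: threshold extrapolated below the range, flagged
  kp <- n
  fitp <- fit_scaled_cumulative_gaussian(levels, kp, n)
  expect_true(fitp$flagged)
  expect_lt(fitp$mu, min(levels))
})

test_that("implied-uncertainty algebra round-trips exactly", {
  # equal weights: each implied variance is twice the combined variance
  iu <- implied_uncertainties(pse = 0, s = 0.32, d = -0.32, sigma2_combined = 1)
  expect_equal(iu$w_cd, 0.5)
  expect_equal(iu$sigma2_cd, 2)
  expect_equal(iu$sigma2_cs, 2)
  expect_false(iu$flagged)
  # grid round trip through the harmonic combination rule
  for (w in c(0.1, 0.25, 0.5, 0.8, 0.95)) {
    for (s2 in c(0.04, 1, 9)) {
      pse <- 0.32 - w * 0.64
      # pse maps back to w: w_cd = (pse - s)/(d - s)
      iu <- implied_uncertainties(pse, 0.32, -0.32, s2)
      expect_equal(iu$w_cd, w, tolerance = 1e-12)
      recomb <- iu$sigma2_cd * iu$sigma2_cs / (iu$sigma2_cd + iu$sigma2_cs)
      expect_equal(recomb, s2, tolerance = 1e-12)
      expect_equal(iu$sigma2_cs / iu$sigma2_cd, iu$w_cd / iu$w_cs,
                   tolerance = 1e-12)
    }
  }
  # PSE outside (s, d) flags the violation but still returns values
  expect_true(implied_uncertainties(0.5, 0.32, -0.32, 1)$flagged)
})

test_that("implied uncertainties invert a linear-MLE forward model exactly", {
  # forward: known sigma_cd = 2, sigma_cs = 1 (level units)
  s2cd <- 4; s2cs <- 1
  w_cd <- s2cs / (s2cd + s2cs)
  pse <- (1 - w_cd) * 0.32 + w_cd * (-0.32)
  s2comb <- s2cd * s2cs / (s2cd + s2cs)
  iu <- implied_uncertainties(pse, 0.32, -0.32, s2comb)
  expect_equal(iu$sigma2_cd, 4, tolerance = 1e-12)
  expect_equal(iu$sigma2_cs, 1, tolerance = 1e-12)
})

test_that("constant-CD prediction scales with the weight ratio", {
  pred <- constant_cd_prediction(pse = c(0, 0, 0), s = 0.32, d = -0.32,
                                 sigma2_cd_reference = 2)
  expect_equal(unique(round(pred$sigma2_cs, 12)), 2)
  # doubling w_cd/w_cs doubles the predicted CS variance
  p1 <- constant_cd_prediction(0.32 - 0.4 * 0.64, 0.32, -0.32, 2)
  p2 <- constant_cd_prediction(0.32 - (8 / 15) * 0.64, 0.32, -0.32, 2)
  expect_equal(p2$sigma2_cs / p1$sigma2_cs, (8 / 15 / (7 / 15)) / (0.4 / 0.6),
               tolerance = 1e-10)
  # self-consistency with implied_uncertainties under a constant-CD observer
  iu <- implied_uncertainties(0.1, 0.32, -0.32, 0.8)
  pred3 <- constant_cd_prediction(0.1, 0.32, -0.32, iu$sigma2_cd)
  expect_equal(pred3$sigma2_cs, iu$sigma2_cs, tolerance = 1e-12)
})

test_that("equivalent size ratios are zero without conflict and reproducible", {
  r0 <- equivalent_size_ratios(0, "amplitude", n_sims = 20, seed = 2)
  expect_equal(r0$mean_max_ratio, 0)
  ra <- equivalent_size_ratios(0.5, "phase", n_sims = 20, seed = 2)
  rb <- equivalent_size_ratios(0.5, "phase", n_sims = 20, seed = 2)
  expect_identical(ra$values, rb$values)
  # single-frame hand check: phase-only mismatch at one frame
  stim <- apply_conflict(triangular_trajectory(80, 1.5, 60),
                         conflict_spec("phase", 1), "cs", 40)
  k <- 23
  hand <- 2 * (764 - stim$cd$m[k]) *
    tan(atan((40 / 2) / (764 - stim$cs$m[k])))
  expect_equal(equivalent_surface_size(764, stim$cd$m[k], stim$cs$m[k], 40),
               hand, tolerance = 1e-12)
})

test_that("equivalent size ratios grow with conflict level", {
  for (ct in c("amplitude", "frequency", "phase")) {
    lv <- switch(ct, amplitude = c(0.2, 0.5, 1), frequency = c(0.3, 1, 2),
                 phase = c(0.3, 1.2, 3))
    vals <- vapply(lv, function(l)
      equivalent_size_ratios(l, ct, n_sims = 60, seed = 11)$mean_max_ratio,
      numeric(1))
    expect_true(all(diff(vals) > 0))
  }
})
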