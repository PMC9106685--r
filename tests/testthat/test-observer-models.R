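# Model observers and the 2IFC experiment simulator. These tests run on
# the small (5e4-motion) tables; quantitative claims at full scale live
# in test-acceptance.R.

test_that("2IFC choices are unbiased for identical intervals", {
  tabs <- small_tables()
  stim <- std_stimulus()
  obs <- speed_observer(noise_model(0.35, 3))
  set.seed(21)
  choices <- replicate(400, speed_2ifc_choice(stim, stim, obs, tabs))
  p1 <- mean(choices == 1)
  expect_gt(p1, 0.5 - 2.5 * sqrt(0.25 / 400))
  expect_lt(p1, 0.5 + 2.5 * sqrt(0.25 / 400))
})

test_that("an extreme consistent speed advantage is always detected", {
  tabs <- small_tables()
  obs <- speed_observer(noise_model(0.35, 3))
  fast <- consistent_stimulus(triangular_trajectory(80 * 2^1.2, 1.5, 60), 40)
  conf <- apply_conflict(triangular_trajectory(80, 1.5, 60),
                         conflict_spec("amplitude", 0.32), "both", 40)
  set.seed(22)
  choices <- replicate(50, speed_2ifc_choice(fast, conf, obs, tabs))
  expect_gte(mean(choices == 1), 0.95)
})

test_that("m-difference observer detects large phase conflicts and not null ones", {
  tabs <- small_tables()
  noise <- noise_model(0.35, 3)
  obs <- m_difference_observer(noise, "max")
  base <- triangular_trajectory(80, 1.5, 60)
  cons <- consistent_stimulus(base, 40)
  conf <- apply_conflict(base, conflict_spec("phase", pi), "cs", 40)
  set.seed(23)
  choices <- replicate(60, conflict_2ifc_choice(conf, cons, obs, tabs))
  expect_gt(mean(choices == 1), 0.95)
  # noiseless, zero conflict: the statistic is identically zero
  obs0 <- m_difference_observer(noise_model(0, 0), "max",
                                sample_measurements = FALSE)
  s <- stereomotion:::observer_statistic(obs0, list(cons, cons), tabs)
  expect_equal(s[1], s[2])
  # identical intervals -> fair coin
  set.seed(24)
  ch <- replicate(200, conflict_2ifc_choice(cons, cons, obs0, tabs))
  expect_gt(mean(ch == 1), 0.5 - 2.5 * sqrt(0.25 / 200))
  expect_lt(mean(ch == 1), 0.5 + 2.5 * sqrt(0.25 / 200))
})

test_that("size observer statistics match a hand computation", {
  tabs <- small_tables()
  noise <- noise_model(0.35, 3)
  obs <- size_conflict_observer(noise, "per_cue", "max",
                                sample_measurements = FALSE)
  stim <- std_stimulus()
  s_batch <- stereomotion:::observer_statistic(obs, list(stim), tabs)
  seg <- sample_segments(stim)
  est <- stereomotion:::segment_estimates(
    data.frame(disp_start = seg$disp_start, disp_end = seg$disp_end,
               size_start = seg$size_start, size_end = seg$size_end),
    noise, tabs)
  half <- (seg$size_end / (60 * 180 / pi)) / 2
  s_cd <- 2 * (est$v_cd - est$m_cd) * tan(half)
  s_cs <- 2 * (est$v_cs - est$m_cs) * tan(half)
  expect_equal(s_batch, max(abs(s_cs - s_cd), na.rm = TRUE), tolerance = 1e-10)
})

test_that("co-occurrence probability is the weighted table mass", {
  cot <- small_cotable()
  noise <- noise_model(0.36, 2.5)
  stim <- std_stimulus()
  seg <- sample_segments(stim)
  p <- cooccurrence_probability(seg, noise, cot)
  expect_length(p, nrow(seg))
  expect_true(all(p >= 0 & p <= 1))
  # noiseless consistent segment: table value at the true signal bin
  p0 <- cooccurrence_probability(seg[3, ], noise_model(0, 0), cot)
  a <- findInterval(seg$cs[3], cot$grids$cs_edges)
  b <- findInterval(seg$cd[3], cot$grids$cd_edges)
  expect_equal(p0, cot$table[a, b])
  # hand-computed 2x2 factorised sum
  Lcd <- stereomotion:::cd_weight_matrix(seg$cd[3], noise, cot$grids$cd_edges)
  Lcs <- stereomotion:::cs_weight_matrix(seg$size_end[3], seg$size_start[3],
                                         noise, cot$grids$cs_edges)
  hand <- as.numeric(Matrix::t(Lcs) %*% cot$table %*% Lcd)
  expect_equal(cooccurrence_probability(seg[3, ], noise, cot), hand,
               tolerance = 1e-10)
  # sign-inconsistent pair with small noise is (near-)impossible
  segx <- data.frame(disp_start = 292, disp_end = 292 + 8,   # cd = -8 (approach)
                     size_start = 180, size_end = 172)       # cs < 1 (recede)
  px <- cooccurrence_probability(segx, noise_model(0.1, 0.5), cot)
  expect_lt(px, 1e-6)
})

test_that("co-occurrence conflict decisions follow the threshold logic", {
  tabs <- small_tables()
  cot <- small_cotable()
  noise <- noise_model(0.36, 2.5)
  base <- triangular_trajectory(80, 1.5, 60)
  cons <- consistent_stimulus(base, 40)
  conf <- apply_conflict(base, conflict_spec("phase", pi), "cs", 40)
  params <- conflict_model_params(noise, 1.5e-5, 0.15)
  obs <- cooccurrence_observer(params)
  set.seed(31)
  ch <- replicate(40, conflict_2ifc_choice(conf, cons, obs, tabs, cot))
  expect_gt(mean(ch == 1), 0.9)
  # consistent vs consistent: both unflagged, fair coin
  set.seed(32)
  ch2 <- replicate(200, conflict_2ifc_choice(cons, cons, obs, tabs, cot))
  expect_gt(mean(ch2 == 1), 0.5 - 2.5 * sqrt(0.25 / 200))
  expect_lt(mean(ch2 == 1), 0.5 + 2.5 * sqrt(0.25 / 200))
  # degenerate threshold: nothing is ever flagged -> coin for conflicts too
  params1 <- conflict_model_params(noise, 1.5e-5, 0.999)
  obs1 <- cooccurrence_observer(params1)
  set.seed(33)
  ch3 <- replicate(200, conflict_2ifc_choice(conf, cons, obs1, tabs, cot))
  expect_gt(mean(ch3 == 1), 0.5 - 2.5 * sqrt(0.25 / 200))
  expect_lt(mean(ch3 == 1), 0.5 + 2.5 * sqrt(0.25 / 200))
})

test_that("simulate_experiment produces the stated factorial designs", {
  tabs <- small_tables()
  cot <- small_cotable()
  obs <- speed_observer(noise_model(0.35, 3))
  tr <- simulate_experiment("exp1", obs, tabs, trials_per_level = 30, seed = 41)
  expect_equal(nrow(tr), 30 * 7 * 3)       # 30 trials x 7 levels x 3 sizes
  expect_setequal(unique(tr$size), c(10, 40, 60))
  expect_equal(sort(unique(tr$level)), seq(-1.2, 1.2, length.out = 7))
  expect_true(all(abs(tr$amp_conflict - 80) <= 20))
  expect_true(all(abs(tr$dur_conflict - 1.5) <= 0.067))
  validate_trials(tr, "speed")
  # determinism
  tr2 <- simulate_experiment("exp1", obs, tabs, trials_per_level = 30, seed = 41)
  expect_identical(tr, tr2)
  # exp2 frequency levels span -2..0 in 7 equal steps
  cobs <- cooccurrence_observer(conflict_model_params(noise_model(0.36, 2.5)))
  tr3 <- simulate_experiment("exp2", cobs, tabs, cot, trials_per_level = 4,
                             seed = 42)
  validate_trials(tr3, "conflict")
  fl <- sort(unique(tr3$level[tr3$conflict_type == "frequency"]))
  expect_equal(fl, seq(-2, 0, length.out = 7))
  expect_true(all(abs(tr3$size - 40) <= 10))
  expect_equal(tr3$amp, tr3$amp2)  # shared jitters by default
  tr4 <- simulate_experiment("exp2", cobs, tabs, cot, trials_per_level = 4,
                             seed = 42, share_jitter = FALSE)
  expect_false(all(tr4$amp == tr4$amp2))
})
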