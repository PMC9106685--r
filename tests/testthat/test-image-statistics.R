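# Monte Carlo tables: histogram correctness against brute-force tallies,
# normalisation invariants, and the scene-recovery machinery.

test_that("simulate_motions draws the stated uniform world reproducibly", {
  a <- simulate_motions(2000, seed = 7)
  b <- simulate_motions(2000, seed = 7)
  expect_identical(a, b)
  expect_true(all(a$cd[a$m > 0] < 0))
  expect_true(all(a$cs[a$m > 0] > 1))
  # marginal uniformity on the stated ranges
  expect_gt(ks.test(a$v, "punif", 500, 10000)$p.value, 0.01)
  expect_gt(ks.test(a$s, "punif", 2, 1000)$p.value, 0.01)
  expect_gt(ks.test(a$m, "punif", -100, 100)$p.value, 0.01)
})

test_that("posterior tables equal a brute-force tally on a toy sample set", {
  toy <- simulate_motions(100, seed = 33)
  grids <- signal_grids()
  tab <- build_posterior_table(toy, grids, "cd")
  # independent tally: nested loops over samples
  n_m <- length(grids$m_edges) - 1L
  n_sig <- length(grids$cd_edges) - 1L
  counts <- matrix(0, nrow(tab$counts), n_sig)
  for (k in seq_len(nrow(toy))) {
    sb <- findInterval(toy$cd[k], grids$cd_edges, rightmost.closed = TRUE)
    vb <- findInterval(toy$v[k], grids$v_edges, rightmost.closed = TRUE)
    mb <- findInterval(toy$m[k], grids$m_edges, rightmost.closed = TRUE)
    cell <- (vb - 1L) * n_m + mb
    counts[cell, sb] <- counts[cell, sb] + 1
  }
  expect_equal(as.matrix(tab$counts), counts, ignore_attr = TRUE)
  # conditional normalisation on populated bins
  probs <- Matrix::colSums(tab$prob)
  expect_true(all(abs(probs[tab$supported] - 1) < 1e-12))
  expect_true(all(probs[!tab$supported] == 0))
  expect_true(all(tab$prob@x >= 0))
})

test_that("co-occurrence table equals a brute-force tally and is normalised", {
  toy <- simulate_motions(100, seed = 34)
  grids <- signal_grids()
  cot <- build_cooccurrence(toy, grids)
  expect_equal(sum(cot$table), 1)
  expect_true(all(cot$table >= 0))
  tally <- matrix(0, length(grids$cs_edges) - 1L, length(grids$cd_edges) - 1L)
  for (k in seq_len(nrow(toy))) {
    a <- findInterval(toy$cs[k], grids$cs_edges, rightmost.closed = TRUE)
    b <- findInterval(toy$cd[k], grids$cd_edges, rightmost.closed = TRUE)
    tally[a, b] <- tally[a, b] + 1
  }
  expect_equal(cot$table, tally / 100, ignore_attr = TRUE)
})

test_that("geometry forbids sign-inconsistent co-occurrence mass", {
  cot <- small_cotable()
  grids <- cot$grids
  cs_cent <- (grids$cs_edges[-1] + grids$cs_edges[-length(grids$cs_edges)]) / 2
  cd_cent <- (grids$cd_edges[-1] + grids$cd_edges[-length(grids$cd_edges)]) / 2
  # strictly inconsistent quadrants (one bin margin for the zero bins)
  bad <- outer(cs_cent > 1 + diff(grids$cs_edges)[1],
               cd_cent > diff(grids$cd_edges)[1]) |
         outer(cs_cent < 1 - diff(grids$cs_edges)[1],
               cd_cent < -diff(grids$cd_edges)[1])
  expect_equal(sum(cot$table[bad]), 0)
})

test_that("the CD bin at zero is broad in v but concentrated near m = 0", {
  tabs <- small_tables()
  zero_bin <- findInterval(0, tabs$grids$cd_edges)
  w <- weighted_posterior(
    structure(list(cue = "cd", w = replace(numeric(ncol(tabs$cd$prob)), zero_bin, 1),
                   edges = tabs$grids$cd_edges, value = 0),
              class = "measurement_weights"),
    tabs$cd)
  m_marg <- rowSums(w$p)
  v_marg <- colSums(w$p)
  # m mass concentrated near zero; v mass spread widely
  expect_gt(sum(m_marg[abs(w$m_centers) < 20]), 0.7)
  expect_gt(sum(v_marg > 1e-4), 50)
})

test_that("scene estimates follow the conditional tables and flag support", {
  tabs <- small_tables()
  # symmetric m-range: near-zero motions give near-zero m estimates.
  # (exactly m = 0 sits on the signed bin boundary, where the two cues'
  # zero-adjacent slices are disjoint and the product is flagged empty)
  est <- estimate_scene(cd_signal(2000, 0.5), cs_signal(2000, 0.5, 100), tabs)
  expect_true(est$supported)
  expect_lt(abs(est$m_cd), 25)
  expect_lt(abs(est$m_cs), 25)
  expect_lt(abs(est$m_comb), 10)
  # out-of-grid signals are flagged, not clamped
  est2 <- estimate_scene(c(0, 500), c(1, 1.001), tabs)
  expect_false(est2$supported[2])
  expect_true(is.na(est2$m_comb[2]))
})

test_that("hand-built tiny tables reproduce hand-computed combined estimates", {
  # two scenes in distinct cells, equal counts: combined posterior of the
  # matching signal pair must put all mass on the matching cell
  toy <- simulate_motions(60, seed = 55)
  tabs <- build_posterior_tables(toy)
  k <- 7
  est <- estimate_scene(toy$cd[k], toy$cs[k], tabs)
  # hand path: conditional slices, elementwise product, marginal means
  wcd <- cd_measurement_weights(toy$cd[k], 0, noise_model(0, 0), tabs$grids$cd_edges)
  wcs <- cs_measurement_weights(1, toy$cs[k], noise_model(0, 0), tabs$grids$cs_edges)
  pc <- combine_cues(weighted_posterior(wcd, tabs$cd),
                     weighted_posterior(wcs, tabs$cs))
  mm <- marginal_means(pc)
  expect_equal(est$m_comb, unname(mm["m"]), tolerance = 1e-10)
  expect_equal(est$v_comb, unname(mm["v"]), tolerance = 1e-10)
})

test_that("recovery improves with cue combination and reports exclusions", {
  tabs <- small_tables()
  rec <- evaluate_recovery(tabs, n_test = 2000, seed = 9)
  r2m <- rec$r2[rec$parameter == "m"]
  names(r2m) <- rec$cue[rec$parameter == "m"]
  expect_gte(r2m["combined"], max(r2m["cd"], r2m["cs"]) - 0.02)
  expect_true(all(rec$r2 >= 0 & rec$r2 <= 1))
  expect_gte(attr(rec, "v_saturation"), 3000)
  expect_equal(attr(rec, "n_used") + attr(rec, "n_excluded"), 2000)
})

test_that("tables round-trip through persistence with grids and metadata", {
  tabs <- small_tables()
  f <- tempfile(fileext = ".rds")
  on.exit(unlink(f))
  write_tables(tabs, f)
  back <- read_tables(f)
  expect_equal(back$grids, tabs$grids)
  expect_equal(back$cd$counts, tabs$cd$counts)
})
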