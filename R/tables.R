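# Monte Carlo construction of the binned joint posteriors p(v, m | CD),
# p(v, m | CS) and the co-occurrence distribution p(CS & CD), built from
# simulated rigid linear motions along the line of sight.

#' Scene parameter ranges for motion simulations
#'
#' Uniform sampling ranges for viewing distance `v`, surface size `s` and
#' distance moved `m`. Defaults cover near space: v in 0.5-10 m, s in
#' 2-1000 mm, m in +/- 100 mm.
#'
#' @param v,s,m Length-2 numeric ranges, mm.
#' @return A list of class `scene_ranges`.
#' @export
scene_ranges <- function(v = c(500, 10000), s = c(2, 1000), m = c(-100, 100)) {
  stopifnot(length(v) == 2L, length(s) == 2L, length(m) == 2L,
            v[1] > 0, v[1] < v[2], s[1] > 0, s[1] < s[2], m[1] < m[2],
            v[1] - max(abs(m)) > 0)
  structure(list(v = v, s = s, m = m), class = "scene_ranges")
}

#' Simulate rigid linear motions in depth
#'
#' Draws `n` independent scenes with uniform viewing distance, surface
#' size and distance moved, and computes the noiseless CD and CS signal
#' each motion generates. Each motion is defined by its start (fixation)
#' and end positions only.
#'
#' @param n Number of motions.
#' @param ranges A [scene_ranges()].
#' @param i Interocular separation, mm.
#' @param seed Optional integer seed for reproducibility.
#' @return A data.frame of class `scene_samples` with columns
#'   `v`, `s`, `m`, `cd` (arcmin), `cs` (ratio).
#' @examples
#' head(simulate_motions(100, seed = 1))
#' @export
simulate_motions <- function(n, ranges = scene_ranges(), i = 65, seed = NULL) {
  stopifnot(n >= 1)
  if (!is.null(seed)) set.seed(seed)
  v <- stats::runif(n, ranges$v[1], ranges$v[2])
  s <- stats::runif(n, ranges$s[1], ranges$s[2])
  m <- stats::runif(n, ranges$m[1], ranges$m[2])
  out <- data.frame(v = v, s = s, m = m,
                    cd = cd_signal(v, m, i),
                    cs = cs_signal(v, m, s))
  attr(out, "ranges") <- ranges
  attr(out, "i") <- i
  attr(out, "seed") <- seed
  class(out) <- c("scene_samples", "data.frame")
  out
}

#' Signal and scene bin grids
#'
#' Bin edges for the CD and CS signal axes and the (v, m) scene axes.
#' Signal edges are derived from the theoretical extremes of the scene
#' ranges (the small-angle limit bounds CS; the closest viewing distance
#' bounds CD), padded by one bin, so grids are deterministic functions of
#' the configuration rather than of a particular sample.
#'
#' Bin widths are a numerical choice, not part of the model: defaults
#' (0.1 arcmin for CD, 0.002 for CS, 100 mm for v, 2 mm for m) keep the
#' tables compact while leaving many samples per populated cell at
#' n = 1e6.
#'
#' @param ranges A [scene_ranges()].
#' @param i Interocular separation, mm.
#' @param cd_bin,cs_bin,v_bin,m_bin Bin widths.
#' @return A list of class `signal_grids` with elements `cd_edges`,
#'   `cs_edges`, `v_edges`, `m_edges`, `i`.
#' @export
signal_grids <- function(ranges = scene_ranges(), i = 65,
                         cd_bin = 0.1, cs_bin = 0.002,
                         v_bin = 100, m_bin = 2) {
  stopifnot(cd_bin > 0, cs_bin > 0, v_bin > 0, m_bin > 0)
  vmin <- ranges$v[1]
  cd_lo <- cd_signal(vmin, max(ranges$m), i)   # largest approach, nearest v
  cd_hi <- cd_signal(vmin, min(ranges$m), i)
  cs_lo <- vmin / (vmin - min(ranges$m))       # small-angle (s -> 0) bounds
  cs_hi <- vmin / (vmin - max(ranges$m))
  snap <- function(lo, hi, by)
    seq((floor(lo / by) - 1) * by, (ceiling(hi / by) + 1) * by, by = by)
  structure(list(cd_edges = snap(cd_lo, cd_hi, cd_bin),
                 cs_edges = snap(cs_lo, cs_hi, cs_bin),
                 v_edges = seq(ranges$v[1], ranges$v[2], by = v_bin),
                 m_edges = seq(ranges$m[1], ranges$m[2], by = m_bin),
                 i = i),
            class = "signal_grids")
}

bin_centers <- function(edges) (edges[-1] + edges[-length(edges)]) / 2

bin_of <- function(x, edges) {
  idx <- findInterval(x, edges, rightmost.closed = TRUE)
  idx[idx < 1L | idx > length(edges) - 1L] <- NA_integer_
  idx
}

# Flattened (v, m) cell index: v-major, m fastest.
vm_index <- function(v_bin, m_bin, n_m) (v_bin - 1L) * n_m + m_bin

#' Build a per-cue joint posterior table
#'
#' Histograms the simulated motions on (signal, v, m) and normalises each
#' signal bin's (v, m) slice to a conditional probability mass function,
#' yielding the binned posterior p(v, m | signal) under the flat scene
#' prior of the simulation. Signal bins containing no samples are flagged
#' as unsupported.
#'
#' @param samples A `scene_samples` data.frame from [simulate_motions()].
#' @param grids A [signal_grids()].
#' @param cue `"cd"` or `"cs"`.
#' @return An object of class `posterior_table`: sparse count and
#'   column-normalised probability matrices (rows: flattened (v, m)
#'   cells; columns: signal bins), support flags, per-bin marginal means
#'   of v and m, and the grids.
#' @export
build_posterior_table <- function(samples, grids, cue = c("cd", "cs")) {
  cue <- match.arg(cue)
  edges <- if (cue == "cd") grids$cd_edges else grids$cs_edges
  sig_bin <- bin_of(samples[[cue]], edges)
  v_bin <- bin_of(samples$v, grids$v_edges)
  m_bin <- bin_of(samples$m, grids$m_edges)
  keep <- !is.na(sig_bin) & !is.na(v_bin) & !is.na(m_bin)
  if (mean(keep) < 0.999)
    stop("grids do not cover the sample set (out-of-range mass >= 0.1%)")
  n_m <- length(grids$m_edges) - 1L
  n_v <- length(grids$v_edges) - 1L
  n_vm <- n_v * n_m
  n_sig <- length(edges) - 1L
  counts <- Matrix::sparseMatrix(
    i = vm_index(v_bin[keep], m_bin[keep], n_m),
    j = sig_bin[keep], x = 1,
    dims = c(n_vm, n_sig))
  col_counts <- Matrix::colSums(counts)
  prob <- counts
  # scale each column by its total; @p gives the column of each nonzero
  col_of <- rep(seq_len(n_sig), diff(prob@p))
  prob@x <- prob@x / col_counts[col_of]
  vm_v <- rep(bin_centers(grids$v_edges), each = n_m)
  vm_m <- rep(bin_centers(grids$m_edges), times = n_v)
  structure(list(cue = cue, grids = grids, signal_edges = edges,
                 counts = counts, prob = prob,
                 col_counts = col_counts, supported = col_counts > 0,
                 bin_mean_v = as.vector(Matrix::crossprod(prob, vm_v)),
                 bin_mean_m = as.vector(Matrix::crossprod(prob, vm_m)),
                 vm_v = vm_v, vm_m = vm_m,
                 n = sum(keep), n_dropped = sum(!keep)),
            class = "posterior_table")
}

#' @export
print.posterior_table <- function(x, ...) {
  cat(sprintf("posterior_table [%s]: %d signal bins (%d supported), %d (v,m) cells, n = %d\n",
              toupper(x$cue), length(x$supported), sum(x$supported),
              nrow(x$counts), x$n))
  invisible(x)
}

#' Build both posterior tables
#'
#' Builds the CD and CS tables and precomputes the cross-cue Gram
#' moments `G(x, y) = sum_c P_cd(c, x) P_cs(c, y)` (plus m- and
#' v-weighted versions) used to evaluate combined-cue marginal means
#' without touching the scene grid per measurement.
#'
#' @inheritParams build_posterior_table
#' @return A list of class `posterior_tables` with elements `cd`, `cs`,
#'   `grids`, and the Gram moment matrices `gram`.
#' @export
build_posterior_tables <- function(samples, grids = signal_grids(attr(samples, "ranges"), attr(samples, "i"))) {
  cd <- build_posterior_table(samples, grids, "cd")
  cs <- build_posterior_table(samples, grids, "cs")
  gram <- list(G = as.matrix(Matrix::crossprod(cd$prob, cs$prob)),
               Gm = as.matrix(Matrix::crossprod(cd$prob, cd$vm_m * cs$prob)),
               Gv = as.matrix(Matrix::crossprod(cd$prob, cd$vm_v * cs$prob)))
  structure(list(cd = cd, cs = cs, grids = grids, gram = gram),
            class = "posterior_tables")
}

#' @export
print.posterior_tables <- function(x, ...) {
  print(x$cd); print(x$cs)
  invisible(x)
}

#' Build the CS/CD co-occurrence distribution
#'
#' Normalised 2-D histogram of the (CS, CD) signal pairs generated by the
#' simulated motions: the probability p(CS & CD) that the two signal
#' values co-occur under rigid motion of a constant-size object. Signal
#' pairs off this distribution's support indicate cue conflict.
#'
#' @inheritParams build_posterior_table
#' @return An object of class `cooccurrence_table`: a dense probability
#'   matrix (rows: CS bins, columns: CD bins) plus the grids.
#' @export
build_cooccurrence <- function(samples, grids = signal_grids(attr(samples, "ranges"), attr(samples, "i"))) {
  cs_bin <- bin_of(samples$cs, grids$cs_edges)
  cd_bin <- bin_of(samples$cd, grids$cd_edges)
  keep <- !is.na(cs_bin) & !is.na(cd_bin)
  if (mean(keep) < 0.999)
    stop("grids do not cover the sample set (out-of-range mass >= 0.1%)")
  n_cs <- length(grids$cs_edges) - 1L
  n_cd <- length(grids$cd_edges) - 1L
  tab <- matrix(0, n_cs, n_cd)
  idx <- cbind(cs_bin[keep], cd_bin[keep])
  tally <- table(factor(cs_bin[keep], levels = seq_len(n_cs)),
                 factor(cd_bin[keep], levels = seq_len(n_cd)))
  tab[] <- as.numeric(tally)
  structure(list(table = tab / sum(tab), grids = grids, n = sum(keep)),
            class = "cooccurrence_table")
}

#' Estimate scene parameters from noiseless signals
#'
#' Looks up the (binned) posterior slice for each signal and reports the
#' marginal-mean estimates of distance moved and viewing distance: per
#' cue, the conditional's marginal means; combined, the marginal means of
#' the renormalised elementwise product of the two conditionals. Signals
#' falling in unsupported bins give `NA` estimates and are flagged.
#'
#' @param cd CD signals, arcmin (vectorised).
#' @param cs CS signals, ratio.
#' @param tables A `posterior_tables` object.
#' @return A data.frame with columns `m_cd`, `v_cd`, `m_cs`, `v_cs`,
#'   `m_comb`, `v_comb` and a logical `supported`.
#' @export
estimate_scene <- function(cd, cs, tables) {
  stopifnot(inherits(tables, "posterior_tables"), length(cd) == length(cs))
  grids <- tables$grids
  cd_bin <- bin_of(cd, grids$cd_edges)
  cs_bin <- bin_of(cs, grids$cs_edges)
  ok <- !is.na(cd_bin) & !is.na(cs_bin)
  ok[ok] <- tables$cd$supported[cd_bin[ok]] & tables$cs$supported[cs_bin[ok]]
  n <- length(cd)
  out <- data.frame(m_cd = rep(NA_real_, n), v_cd = NA_real_,
                    m_cs = NA_real_, v_cs = NA_real_,
                    m_comb = NA_real_, v_comb = NA_real_,
                    supported = ok)
  if (!any(ok)) return(out)
  # delta measurement weights: one unit column per motion
  nn <- sum(ok)
  Lcd <- Matrix::sparseMatrix(i = cd_bin[ok], j = seq_len(nn), x = 1,
                              dims = c(length(grids$cd_edges) - 1L, nn))
  Lcs <- Matrix::sparseMatrix(i = cs_bin[ok], j = seq_len(nn), x = 1,
                              dims = c(length(grids$cs_edges) - 1L, nn))
  est <- joint_estimates_core(tables, Lcd, Lcs)
  out$m_cd[ok] <- est$m_cd;   out$v_cd[ok] <- est$v_cd
  out$m_cs[ok] <- est$m_cs;   out$v_cs[ok] <- est$v_cs
  out$m_comb[ok] <- est$m_comb; out$v_comb[ok] <- est$v_comb
  out$supported <- ok & !is.na(out$m_comb)
  out
}

# Shared wrapper around the C++ kernels: measurement-weight columns in,
# per-measurement marginal-mean estimates out. Uses the Gram-factorised
# kernel when the tables carry precomputed cross moments; the direct
# scene-grid kernel otherwise (both are algebraically identical).
joint_estimates_core <- function(tables, Lcd, Lcs) {
  stopifnot(methods::is(Lcd, "CsparseMatrix"), methods::is(Lcs, "CsparseMatrix"))
  res <- if (!is.null(tables$gram)) {
    cpp_joint_estimates_gram(
      tables$gram$G, tables$gram$Gm, tables$gram$Gv,
      as.numeric(tables$cd$supported), tables$cd$bin_mean_m, tables$cd$bin_mean_v,
      as.numeric(tables$cs$supported), tables$cs$bin_mean_m, tables$cs$bin_mean_v,
      Lcd, Lcs)
  } else {
    cpp_joint_estimates(tables$cd$prob, tables$cs$prob, Lcd, Lcs,
                        tables$cd$vm_v, tables$cd$vm_m)
  }
  as.data.frame(res)
}

#' Scene-parameter recovery experiment
#'
#' Simulates `n_test` fresh motions, estimates distance moved and viewing
#' distance from their noiseless CD and CS signals via [estimate_scene()],
#' and reports the squared Pearson correlation between true and estimated
#' values for each cue and the combined estimator. Motions whose signals
#' fall in unsupported bins are excluded (and counted), not clamped.
#'
#' @param tables A `posterior_tables` object.
#' @param n_test Number of test motions (default 10000).
#' @param seed Integer seed for the test draw.
#' @param ranges Scene ranges for the test motions.
#' @return A data.frame with columns `cue` (cd/cs/combined), `parameter`
#'   (m/v) and `r2`; attributes `n_used`, `n_excluded`, and
#'   `v_saturation` (upper end, mm, of the range over which the combined
#'   viewing-distance estimate still tracks the true value with local
#'   slope > 0.5).
#' @export
evaluate_recovery <- function(tables, n_test = 10000, seed = NULL,
                              ranges = scene_ranges()) {
  test <- simulate_motions(n_test, ranges, i = tables$grids$i, seed = seed)
  est <- estimate_scene(test$cd, test$cs, tables)
  ok <- est$supported
  r2 <- function(truth, hat) stats::cor(truth, hat)^2
  out <- data.frame(
    cue = rep(c("cd", "cs", "combined"), each = 2),
    parameter = rep(c("m", "v"), 3),
    r2 = c(r2(test$m[ok], est$m_cd[ok]), r2(test$v[ok], est$v_cd[ok]),
           r2(test$m[ok], est$m_cs[ok]), r2(test$v[ok], est$v_cs[ok]),
           r2(test$m[ok], est$m_comb[ok]), r2(test$v[ok], est$v_comb[ok])))
  attr(out, "n_used") <- sum(ok)
  attr(out, "n_excluded") <- sum(!ok)
  # local slope of v_hat against v in 500 mm windows; saturation = end of
  # the contiguous low-v run with slope above 0.5
  br <- seq(ranges$v[1], ranges$v[2], by = 500)
  g <- cut(test$v[ok], br)
  slopes <- vapply(split(data.frame(v = test$v[ok], vh = est$v_comb[ok]), g),
                   function(d) if (nrow(d) > 10) stats::coef(stats::lm(vh ~ v, d))[2] else NA_real_,
                   numeric(1))
  good <- !is.na(slopes) & slopes > 0.5
  k <- 0L
  for (jj in seq_along(good)) if (good[jj]) k <- jj else break
  attr(out, "v_saturation") <- br[k + 1L]
  out
}

#' Persist / restore posterior tables
#'
#' Tables are written with their grids and build metadata so model runs
#' are reproducible without re-simulation. Serialisation uses R's native
#' RDS format.
#'
#' @param tables A `posterior_tables` (or any tables object).
#' @param file Path.
#' @export
write_tables <- function(tables, file) saveRDS(tables, file)

#' @rdname write_tables
#' @export
read_tables <- function(file) readRDS(file)
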