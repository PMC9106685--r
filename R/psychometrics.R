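# Psychometric fitting and derived analyses: cumulative-Gaussian PSE/JND
# fits, scaled (0.5-floor) fits with 75%-correct thresholds, implied
# single-cue uncertainties under maximum-likelihood linear integration,
# the constant-CD-uncertainty null model, and equivalent physical size
# ratios for threshold-level conflicts.

#' Aggregate a trial table into a psychometric dataset
#'
#' Collapses a trial table from [simulate_experiment()] (or the synthetic
#' generators) to per-level trial and success counts. For the speed task
#' responses are normalised for the direction of cue conflict before
#' pooling: the level axis is sign-flipped for the mirrored conflict
#' direction AND the response is complemented there (along the flipped
#' axis "consistent judged faster" runs the opposite way, so both flips
#' are needed for the two directions' curves to superimpose). For the
#' conflict task the success is a correct conflict identification.
#'
#' @param trials A trial data.frame.
#' @param task `"speed"` or `"conflict"`.
#' @return A data.frame with grouping columns (`size` or
#'   `conflict_type`), `level`, `n`, `k`.
#' @export
aggregate_trials <- function(trials, task = c("speed", "conflict")) {
  task <- match.arg(task)
  if (task == "speed") {
    dir <- if ("conflict_dir" %in% names(trials)) trials$conflict_dir else 1
    lev <- trials$level * dir
    succ <- ifelse(dir >= 0, trials$chose_consistent,
                   !trials$chose_consistent)
    g <- interaction(trials$size, lev, drop = TRUE)
    out <- data.frame(size = tapply(trials$size, g, `[`, 1),
                      level = tapply(lev, g, `[`, 1),
                      n = as.vector(tapply(lev, g, length)),
                      k = as.vector(tapply(succ, g, sum)))
  } else {
    g <- interaction(trials$conflict_type, trials$level, drop = TRUE)
    out <- data.frame(conflict_type = tapply(as.character(trials$conflict_type), g, `[`, 1),
                      level = tapply(trials$level, g, `[`, 1),
                      n = as.vector(tapply(trials$level, g, length)),
                      k = as.vector(tapply(trials$correct, g, sum)))
  }
  rownames(out) <- NULL
  out[order(out[[1]], out$level), ]
}

neg_loglik_binom <- function(p, k, n) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  -sum(k * log(p) + (n - k) * log(1 - p))
}

#' Fit a cumulative Gaussian psychometric function
#'
#' Binomial maximum-likelihood fit of `Phi((x - mu) / sigma)` to
#' success proportions. `mu` is the point of subjective equality (PSE)
#' and `sigma` the just-noticeable difference (JND, the 84% point
#' relative to the PSE). No lapse rate is modelled.
#'
#' @param levels Stimulus levels.
#' @param k Successes per level.
#' @param n Trials per level.
#' @return An object of class `psychometric_fit` with elements `mu`,
#'   `sigma`, `loglik`, `converged`, `flagged` (TRUE when the data are
#'   degenerate: all successes/failures or no transition), and the data.
#' @export
fit_cumulative_gaussian <- function(levels, k, n) {
  stopifnot(length(levels) == length(k), length(k) == length(n),
            all(k >= 0), all(k <= n), length(unique(levels)) >= 2)
  prop <- k / n
  flagged <- all(k == 0) || all(k == n)
  spacing <- mean(diff(sort(unique(levels))))
  ini <- tryCatch({
    g <- suppressWarnings(stats::glm(cbind(k, n - k) ~ levels,
                                     family = stats::binomial("probit")))
    b <- stats::coef(g)
    if (all(is.finite(b)) && b[2] > 0)
      unname(c(-b[1] / b[2], log(1 / b[2])))
    else NULL
  }, error = function(e) NULL)
  if (is.null(ini)) ini <- c(mean(levels), log(spacing))
  fit <- stats::optim(ini,
                      function(par) neg_loglik_binom(
                        stats::pnorm((levels - par[1]) / exp(par[2])), k, n),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  structure(list(mu = fit$par[1], sigma = exp(fit$par[2]),
                 loglik = -fit$value,
                 converged = fit$convergence == 0 && !flagged,
                 flagged = flagged || fit$convergence != 0,
                 data = data.frame(level = levels, k = k, n = n)),
            class = "psychometric_fit")
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("psychometric fit: mu (PSE) = %.4g, sigma (JND) = %.4g%s\n",
              x$mu, x$sigma, if (x$flagged) "  [FLAGGED]" else ""))
  invisible(x)
}

#' Fit a scaled cumulative Gaussian to proportion-correct data
#'
#' Binomial ML fit of `0.5 + 0.5 Phi((x - mu) / sigma)` (chance floor at
#' 0.5). The returned `threshold` is the level at which the fitted curve
#' crosses 75% correct, which equals `mu`. The threshold is flagged
#' unmeasurable when performance never rises credibly above chance, and
#' flagged as extrapolated when it falls outside the tested range
#' (e.g. perfect performance everywhere).
#'
#' @inheritParams fit_cumulative_gaussian
#' @return A `scaled_psychometric_fit` with `mu`, `sigma`,
#'   `threshold` (NA when unmeasurable), `flagged`, and the data.
#' @export
fit_scaled_cumulative_gaussian <- function(levels, k, n) {
  stopifnot(length(levels) == length(k), length(k) == length(n),
            length(unique(levels)) >= 2)
  prop <- k / n
  # credible above-chance evidence: pooled exact binomial test
  above <- stats::binom.test(sum(k), sum(n), 0.5,
                             alternative = "greater")$p.value < 0.01
  spacing <- mean(diff(sort(unique(levels))))
  init_mu <- if (any(prop >= 0.75)) min(levels[prop >= 0.75]) else max(levels)
  fit <- stats::optim(c(init_mu, log(spacing)),
                      function(par) neg_loglik_binom(
                        0.5 + 0.5 * stats::pnorm((levels - par[1]) / exp(par[2])),
                        k, n),
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  mu <- fit$par[1]
  unmeasurable <- !above || fit$convergence != 0
  outside <- mu < min(levels) || mu > max(levels)
  structure(list(mu = mu, sigma = exp(fit$par[2]),
                 threshold = if (unmeasurable) NA_real_ else mu,
                 loglik = -fit$value,
                 flagged = unmeasurable || outside,
                 unmeasurable = unmeasurable, outside_range = outside,
                 data = data.frame(level = levels, k = k, n = n)),
            class = "scaled_psychometric_fit")
}

#' Implied single-cue uncertainties from combined-cue performance
#'
#' Back-derives the single-cue variances consistent with an observed
#' combined-cue PSE and JND under standard maximum-likelihood linear
#' integration. Weights follow from the PSE,
#' `w_CD = (PSE - s) / (d - s)`, `w_CS = 1 - w_CD`, where `s` and `d` are
#' the conflict stimulus's CS and CD speeds on the level axis; the
#' implied variances are
#' `sigma2_CD = (w_CS / w_CD) sigma2_comb + sigma2_comb` and
#' `sigma2_CS = sigma2_CD (w_CD / w_CS)`. Recombining the two through
#' the harmonic relation `sigma2_comb = s2cd s2cs / (s2cd + s2cs)`
#' returns the input combined variance exactly.
#'
#' @param pse Observed PSE (level units).
#' @param s,d CS-cue and CD-cue speeds of the conflict stimulus on the
#'   level axis (`s != d`).
#' @param sigma2_combined Observed combined-cue variance (JND squared).
#' @return An object of class `implied_uncertainty` with weights
#'   `w_cd`, `w_cs`, variances `sigma2_cd`, `sigma2_cs`,
#'   `sigma2_combined`, and `flagged` (TRUE when the PSE lies outside
#'   (s, d) so a weight leaves [0, 1]; values are still returned).
#' @export
implied_uncertainties <- function(pse, s, d, sigma2_combined) {
  stopifnot(s != d, sigma2_combined > 0)
  w_cd <- (pse - s) / (d - s)
  w_cs <- 1 - w_cd
  flagged <- w_cd <= 0 || w_cs <= 0
  sigma2_cd <- (w_cs / w_cd) * sigma2_combined + sigma2_combined
  sigma2_cs <- sigma2_cd * (w_cd / w_cs)
  structure(list(w_cd = w_cd, w_cs = w_cs,
                 sigma2_cd = sigma2_cd, sigma2_cs = sigma2_cs,
                 sigma2_combined = sigma2_combined, flagged = flagged),
            class = "implied_uncertainty")
}

#' Constant-CD-uncertainty null prediction
#'
#' The change in implied CS uncertainty required to explain observed PSEs
#' if CD uncertainty were constant (fixed at a reference value, e.g. the
#' implied CD variance for the smallest surface size):
#' `sigma2_CS = sigma2_CD_ref * (w_CD / w_CS)` with weights from each
#' condition's PSE.
#'
#' @param pse Vector of PSEs (one per condition).
#' @param s,d As in [implied_uncertainties()].
#' @param sigma2_cd_reference Reference CD variance (level units squared).
#' @return Data.frame with `w_cd`, `w_cs` and the predicted `sigma2_cs`
#'   per condition.
#' @export
constant_cd_prediction <- function(pse, s, d, sigma2_cd_reference) {
  stopifnot(s != d, sigma2_cd_reference > 0)
  w_cd <- (pse - s) / (d - s)
  w_cs <- 1 - w_cd
  data.frame(pse = pse, w_cd = w_cd, w_cs = w_cs,
             sigma2_cs = sigma2_cd_reference * (w_cd / w_cs))
}

#' Equivalent physical size ratios at threshold
#'
#' Expresses a conflict-discrimination threshold as the physical size
#' change a surface would need to undergo to produce the threshold-level
#' cue conflict, assuming motion is accurately defined by the CD cue.
#' For each of `n_sims` simulated threshold-level conflict stimuli (with
#' the experiment's trial-wise jitters of surface size, amplitude and
#' duration), the equivalent size `s_CD` is computed at every display
#' frame via [equivalent_surface_size()], summarised as the maximum
#' absolute `log2(s_CD / s_CS)` across frames, and averaged over
#' simulations.
#'
#' @param threshold Threshold conflict level (log2 units for amplitude
#'   and frequency magnitudes, radians for phase).
#' @param conflict_type `"amplitude"`, `"frequency"`, or `"phase"`.
#' @param n_sims Number of simulated threshold conflicts (default 1000).
#' @param seed Optional seed.
#' @param base_amplitude,duration,frame_rate,surface_size,geometry
#'   Stimulus baseline as in [simulate_experiment()].
#' @param jitter Uniform jitter half-ranges (mm, mm, s).
#' @return An object of class `equivalent_size_result`: `mean_max_ratio`
#'   (mean over simulations of the per-simulation max |log2 ratio|) and
#'   the per-simulation values.
#' @export
equivalent_size_ratios <- function(threshold, conflict_type, n_sims = 1000,
                                   seed = NULL, base_amplitude = 80,
                                   duration = 1.5, frame_rate = 60,
                                   surface_size = 40,
                                   geometry = viewing_geometry(),
                                   jitter = list(amplitude = 20, size = 10,
                                                 duration = 0.067)) {
  stopifnot(is.finite(threshold), threshold >= 0)
  conflict_type <- match.arg(conflict_type, c("amplitude", "frequency", "phase"))
  if (!is.null(seed)) set.seed(seed)
  # frequency thresholds are magnitudes on the folded 0..2 axis; the
  # applied frequency level is their negative
  level <- if (conflict_type == "frequency") -threshold else threshold
  vals <- vapply(seq_len(n_sims), function(kk) {
    amp <- base_amplitude + stats::runif(1, -1, 1) * jitter$amplitude
    sz <- surface_size + stats::runif(1, -1, 1) * jitter$size
    dur <- duration + stats::runif(1, -1, 1) * jitter$duration
    stim <- apply_conflict(triangular_trajectory(amp, dur, frame_rate),
                           conflict_spec(conflict_type, level), "cs",
                           sz, geometry)
    s_cd <- equivalent_surface_size(geometry$distance, stim$cd$m, stim$cs$m,
                                    stim$surface_size)
    max(abs(log2(s_cd / stim$surface_size)))
  }, numeric(1))
  structure(list(conflict_type = conflict_type, threshold = threshold,
                 mean_max_ratio = mean(vals), values = vals),
            class = "equivalent_size_result")
}

#' @export
print.equivalent_size_result <- function(x, ...) {
  cat(sprintf("equivalent size ratios [%s, threshold %.3g]: mean max |log2 s_CD/s_CS| = %.3f\n",
              x$conflict_type, x$threshold, x$mean_max_ratio))
  invisible(x)
}
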