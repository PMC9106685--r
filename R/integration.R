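# Noisy-measurement cue integration: per-segment CD and CS measurement
# distributions, weighted posteriors (mixtures of binned conditionals),
# their product combination, and the speed-in-depth estimate sum(|M|)/t.

#' Measurement noise model
#'
#' Frame-level measurement noise: each sampled disparity value carries
#' independent zero-mean Gaussian noise with standard deviation
#' `n_disparity` (arcmin), each sampled angular size noise with standard
#' deviation `n_size` (arcmin). A CD measure, being a difference of two
#' noisy disparities, has variance `2 n_disparity^2`; a CS measure is a
#' ratio of two noisy sizes and follows the Gaussian-ratio distribution.
#'
#' @param n_disparity,n_size Standard deviations, arcmin (> 0; exactly 0
#'   is allowed and treated as the noiseless limit).
#' @return An object of class `noise_model`.
#' @export
noise_model <- function(n_disparity, n_size) {
  stopifnot(is.numeric(n_disparity), n_disparity >= 0,
            is.numeric(n_size), n_size >= 0)
  structure(list(n_disparity = n_disparity, n_size = n_size),
            class = "noise_model")
}

# Boundary samples: trajectory positions at every `stride` frames.
segment_boundaries <- function(stimulus, stride_frames = 5) {
  stopifnot(inherits(stimulus, "cue_stimulus"), stride_frames >= 1)
  n_samp <- length(stimulus$cd$m)
  idx <- seq(1L, n_samp, by = stride_frames)
  if (idx[length(idx)] != n_samp) idx <- c(idx, n_samp)
  if (length(idx) < 2L) stop("stimulus shorter than one segment")
  v <- stimulus$geometry$distance
  i <- stimulus$geometry$interocular
  data.frame(idx = idx,
             time = stimulus$cd$times[idx],
             m_cd = stimulus$cd$m[idx],
             m_cs = stimulus$cs$m[idx],
             disp = binocular_disparity(v - stimulus$cd$m[idx], i),
             size = angular_size(stimulus$surface_size, v - stimulus$cs$m[idx]))
}

# Start/end sample indices for the k measures of a stimulus with nb
# boundary samples. "cumulative" measures run from the motion onset to
# each later sample (matching the simulated motions, which all start at
# fixation); "consecutive" measures pair successive samples.
segment_pairs <- function(nb, measure) {
  k <- nb - 1L
  list(head = if (measure == "cumulative") rep(1L, k) else seq_len(k),
       tail = seq_len(k) + 1L)
}

#' Sample a stimulus into measurement segments
#'
#' Samples disparity (from the CD trajectory) and angular size (from the
#' CS trajectory) every `stride_frames` display frames. A 90-frame,
#' 60 Hz stimulus sampled every 5 frames yields 18 measurement segments
#' (sampled points 83.3 ms apart). With the default
#' `measure = "cumulative"` each segment spans from the motion onset to
#' one sampled point, so its CD/CS values are signals of a motion
#' starting at fixation, the kind the posterior tables are built from;
#' `measure = "consecutive"` pairs successive samples instead.
#'
#' @param stimulus A [cue_stimulus()].
#' @param stride_frames Frames between successive samples (default 5).
#' @param measure `"cumulative"` (onset to sampled point) or
#'   `"consecutive"` (successive samples).
#' @return A data.frame with one row per segment: times, start/end
#'   disparity (arcmin), start/end angular size (arcmin), the noiseless
#'   segment CD (`disp_start - disp_end`, arcmin) and CS
#'   (`size_end / size_start`), and the true displacements of each cue's
#'   trajectory over the segment.
#' @export
sample_segments <- function(stimulus, stride_frames = 5,
                            measure = c("cumulative", "consecutive")) {
  measure <- match.arg(measure)
  b <- segment_boundaries(stimulus, stride_frames)
  sp <- segment_pairs(nrow(b), measure)
  out <- data.frame(
    segment = seq_along(sp$head),
    t_start = b$time[sp$head], t_end = b$time[sp$tail],
    disp_start = b$disp[sp$head], disp_end = b$disp[sp$tail],
    size_start = b$size[sp$head], size_end = b$size[sp$tail],
    dm_cd = b$m_cd[sp$tail] - b$m_cd[sp$head],
    dm_cs = b$m_cs[sp$tail] - b$m_cs[sp$head])
  out$cd <- out$disp_start - out$disp_end
  out$cs <- out$size_end / out$size_start
  out
}

#' Gaussian-ratio density
#'
#' Density of `Z = X / Y` for independent `X ~ N(mu_num, sd_num^2)` and
#' `Y ~ N(mu_den, sd_den^2)` (Hinkley's closed form). Used for the CS
#' measurement distribution, where numerator and denominator are the
#' noisy end and start angular sizes of a segment.
#'
#' @param z Quantiles (vectorised).
#' @param mu_num,mu_den Means of numerator and denominator.
#' @param sd_num,sd_den Standard deviations (default equal).
#' @return Density values.
#' @export
dratio_gaussian <- function(z, mu_num, mu_den, sd_num, sd_den = sd_num) {
  stopifnot(sd_num > 0, sd_den > 0)
  a <- sqrt(z^2 / sd_num^2 + 1 / sd_den^2)
  b <- mu_num * z / sd_num^2 + mu_den / sd_den^2
  cc <- mu_num^2 / sd_num^2 + mu_den^2 / sd_den^2
  d <- exp((b^2 - cc * a^2) / (2 * a^2))
  b * d / (a^3 * sqrt(2 * pi) * sd_num * sd_den) *
    (2 * stats::pnorm(b / a) - 1) +
    exp(-cc / 2) / (a^2 * pi * sd_num * sd_den)
}

delta_weights <- function(value, edges) {
  idx <- bin_of(value, edges)
  if (is.na(idx)) stop("value falls outside the signal grid")
  w <- numeric(length(edges) - 1L)
  w[idx] <- 1
  w
}

#' CD measurement weight distribution
#'
#' Probability mass, over the CD signal bins, of the true CD value given
#' one noisy segment measurement: a Gaussian centred on
#' `disp_start - disp_end` with variance `2 n_disparity^2`, integrated
#' over each bin (CDF differences) and renormalised over the grid
#' support.
#'
#' @param disp_start,disp_end Sampled disparity values, arcmin.
#' @param noise A [noise_model()].
#' @param edges CD bin edges (arcmin), e.g. `grids$cd_edges`.
#' @return An object of class `measurement_weights`: the weight vector
#'   `w` (sums to 1), the grid edges, and the measured value.
#' @export
cd_measurement_weights <- function(disp_start, disp_end, noise, edges) {
  stopifnot(inherits(noise, "noise_model"))
  mu <- disp_start - disp_end
  sd <- sqrt(2) * noise$n_disparity
  w <- if (sd == 0) delta_weights(mu, edges) else {
    p <- stats::pnorm(edges, mu, sd)
    diff(p)
  }
  tot <- sum(w)
  if (tot <= 0) stop("measurement mass falls entirely outside the CD grid")
  structure(list(cue = "cd", w = w / tot, edges = edges, value = mu),
            class = "measurement_weights")
}

#' CS measurement weight distribution
#'
#' Probability mass, over the CS signal bins, of the true CS value given
#' one noisy segment measurement: the Gaussian-ratio density with
#' numerator mean `size_end` and denominator mean `size_start` (both with
#' standard deviation `n_size`), evaluated at bin centres times bin
#' widths and renormalised. Requires sizes well away from zero
#' (`> 3 n_size`), where the ratio distribution is well behaved.
#'
#' @param size_start,size_end Sampled angular sizes, arcmin.
#' @param noise A [noise_model()].
#' @param edges CS bin edges (ratio), e.g. `grids$cs_edges`.
#' @return A `measurement_weights` object.
#' @export
cs_measurement_weights <- function(size_start, size_end, noise, edges) {
  stopifnot(inherits(noise, "noise_model"))
  if (min(size_start, size_end) <= 3 * noise$n_size)
    stop("sizes within 3 n_size of zero: ratio distribution ill-behaved")
  ratio <- size_end / size_start
  sd0 <- abs(ratio) * noise$n_size *
    sqrt(1 / size_end^2 + 1 / size_start^2)
  w <- if (noise$n_size == 0) delta_weights(ratio, edges)
  else if (sd0 < min(diff(edges))) diff(stats::pnorm(edges, ratio, sd0))
  else {
    cent <- bin_centers(edges)
    dratio_gaussian(cent, size_end, size_start, noise$n_size) * diff(edges)
  }
  tot <- sum(w)
  if (tot <= 0) stop("measurement mass falls entirely outside the CS grid")
  structure(list(cue = "cs", w = w / tot, edges = edges, value = ratio),
            class = "measurement_weights")
}

#' Measurement-weighted posterior over (v, m)
#'
#' The scene posterior given one uncertain measurement: the mixture of
#' per-signal-bin conditionals weighted by the measurement distribution
#' `L`, renormalised over (v, m). With a point-mass weight vector this
#' reduces to the table's conditional slice.
#'
#' @param weights A `measurement_weights` object.
#' @param table A `posterior_table` for the matching cue.
#' @return A `joint_posterior`: probability matrix `p` (rows: m bins,
#'   columns: v bins, sums to 1) with bin-centre coordinates.
#' @export
weighted_posterior <- function(weights, table) {
  stopifnot(inherits(weights, "measurement_weights"),
            inherits(table, "posterior_table"))
  if (!identical(length(weights$w), ncol(table$prob)) ||
      max(abs(weights$edges - table$signal_edges)) > 1e-12)
    stop("weights and table do not share a signal grid")
  B <- as.vector(table$prob %*% weights$w)
  tot <- sum(B)
  if (tot <= 0) stop("all measurement weight lies on unsupported signal bins")
  n_m <- length(table$grids$m_edges) - 1L
  n_v <- length(table$grids$v_edges) - 1L
  structure(list(p = matrix(B / tot, nrow = n_m, ncol = n_v),
                 m_centers = bin_centers(table$grids$m_edges),
                 v_centers = bin_centers(table$grids$v_edges)),
            class = "joint_posterior")
}

#' Marginal-mean scene estimates of a joint posterior
#'
#' @param joint A `joint_posterior`.
#' @return Named vector with elements `m` and `v` (marginal means, mm).
#' @export
marginal_means <- function(joint) {
  stopifnot(inherits(joint, "joint_posterior"))
  c(m = sum(rowSums(joint$p) * joint$m_centers),
    v = sum(colSums(joint$p) * joint$v_centers))
}

#' Combine weighted posteriors across cues
#'
#' Elementwise product of the two cues' weighted posteriors over the
#' shared (v, m) grid. The default renormalises the product to sum to 1
#' (the stated combination rule); `method = "printed-sum"` instead
#' divides the product by the sum of the two posteriors, preserved as a
#' documented alternative (note it does not normalise the result; the
#' marginal means are unaffected by the overall scale).
#'
#' @param p_cd,p_cs `joint_posterior` objects on the same scene grid.
#' @param method `"product"` (renormalised product) or `"printed-sum"`.
#' @return A `joint_posterior`.
#' @export
combine_cues <- function(p_cd, p_cs, method = c("product", "printed-sum")) {
  method <- match.arg(method)
  stopifnot(inherits(p_cd, "joint_posterior"), inherits(p_cs, "joint_posterior"),
            identical(dim(p_cd$p), dim(p_cs$p)))
  prod <- p_cd$p * p_cs$p
  denom <- if (method == "product") sum(prod) else sum(p_cd$p + p_cs$p)
  if (sum(prod) <= 0)
    stop("cue posteriors are irreconcilable at this grid resolution (empty product)")
  structure(list(p = prod / denom,
                 m_centers = p_cd$m_centers, v_centers = p_cd$v_centers),
            class = "joint_posterior")
}

# Draw one set of noisy boundary measurements and return per-segment
# noisy disparity/size start-end values. Noise is drawn once per sampled
# boundary, so segments share their common boundary samples.
noisy_segments <- function(stimulus, noise, stride_frames = 5,
                           measure = "cumulative",
                           sample_measurements = FALSE) {
  b <- segment_boundaries(stimulus, stride_frames)
  nb <- nrow(b)
  disp <- b$disp
  size <- b$size
  if (sample_measurements) {
    disp <- disp + stats::rnorm(nb, 0, noise$n_disparity)
    size <- size + stats::rnorm(nb, 0, noise$n_size)
  }
  sp <- segment_pairs(nb, measure)
  data.frame(segment = seq_along(sp$head),
             disp_start = disp[sp$head], disp_end = disp[sp$tail],
             size_start = size[sp$head], size_end = size[sp$tail],
             t_start = b$time[sp$head], t_end = b$time[sp$tail])
}

# Perceived speed from per-segment marginal-mean displacement estimates.
# Cumulative measures estimate the displacement-from-onset M_k at each
# sampled point, so the absolute motions are the increments |M_k -
# M_{k-1}| (M_0 = 0, the motion starts at fixation); consecutive
# measures estimate per-segment motions directly.
speed_from_estimates <- function(m_hat, duration, measure) {
  if (measure == "cumulative") {
    # unsupported points (empty posterior product at a bin boundary)
    # carry the previous displacement estimate forward
    m <- c(0, m_hat)
    for (k in seq_along(m)[-1]) if (is.na(m[k])) m[k] <- m[k - 1]
    sum(abs(diff(m))) / duration
  } else {
    sum(abs(m_hat), na.rm = TRUE) / duration
  }
}

#' Model estimate of perceived speed-in-depth
#'
#' The observer's speed percept for a stimulus: disparity and size are
#' sampled every `stride_frames` frames; each measurement's uncertainty
#' distribution (Gaussian for CD, Gaussian-ratio for CS) weights the
#' posterior tables (mixture of conditionals); the two cues' weighted
#' posteriors are multiplied and renormalised; and the marginal mean M
#' of distance moved is taken per sampled point. The perceived speed is
#' the summed absolute estimated motion divided by the presentation
#' duration `t`: with cumulative measures `sum(|M_k - M_(k-1)|) / t`,
#' with consecutive measures `sum(|M|) / t`.
#'
#' By default the measurement distributions are centred on the true
#' sampled values and propagated deterministically — the percept is a
#' deterministic function of the stimulus, and trial-to-trial response
#' variability arises from the experiment's stimulus jitters. With
#' `sample_measurements = TRUE` the measurements are additionally drawn
#' from the noise model (one stochastic draw per call); the summed
#' absolute increments then acquire a large rectified-noise floor that
#' flattens speed discrimination, which is why sampling is not the
#' default.
#'
#' @param stimulus A [cue_stimulus()].
#' @param noise A [noise_model()].
#' @param tables A `posterior_tables` object.
#' @param stride_frames Frames per sample (default 5).
#' @param measure Measurement span, see [sample_segments()].
#' @param sample_measurements Draw noisy measurements instead of
#'   propagating distributions centred on the true values.
#' @return Speed estimate in mm/s (always >= 0).
#' @export
estimate_speed <- function(stimulus, noise, tables, stride_frames = 5,
                           measure = c("cumulative", "consecutive"),
                           sample_measurements = FALSE) {
  measure <- match.arg(measure)
  seg <- noisy_segments(stimulus, noise, stride_frames, measure,
                        sample_measurements)
  est <- segment_estimates(seg, noise, tables)
  if (all(is.na(est$m_comb)))
    stop("measurement weights fell entirely on unsupported signal bins")
  speed_from_estimates(est$m_comb, stimulus$cd$duration, measure)
}

# Batch per-segment estimates via the C++ kernel. `seg` holds noisy
# start/end disparities and sizes (any number of segments, possibly from
# many stimuli).
segment_estimates <- function(seg, noise, tables) {
  Lcd <- cd_weight_matrix(seg$disp_start - seg$disp_end, noise,
                          tables$grids$cd_edges)
  Lcs <- cs_weight_matrix(seg$size_end, seg$size_start, noise,
                          tables$grids$cs_edges)
  joint_estimates_core(tables, Lcd, Lcs)
}

# Sparse (n_bins x n_meas) measurement-weight matrices, one column per
# measurement, built in C++ and truncated at +/- span sd (renormalised
# per column). The single-measurement R constructors above are the
# reference implementations these are tested against.
cd_weight_matrix <- function(means, noise, edges, span = 6) {
  csc_to_dgc(cpp_gaussian_weights(means, sqrt(2) * noise$n_disparity,
                                  edges, span),
             length(means))
}

cs_weight_matrix <- function(mu_num, mu_den, noise, edges, span = 6) {
  csc_to_dgc(cpp_ratio_weights(mu_num, mu_den, noise$n_size, edges, span),
             length(mu_num))
}

csc_to_dgc <- function(lst, ncol) {
  methods::new("dgCMatrix", p = as.integer(lst$p), i = as.integer(lst$i),
               x = as.numeric(lst$x),
               Dim = c(as.integer(lst$nrow), as.integer(ncol)))
}
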