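# Model observers for the two 2IFC tasks: speed-in-depth discrimination
# (perturbation analysis) and cue-conflict detection. All observers share
# the segment-sampling front end and the posterior-table machinery; they
# differ only in the decision statistic.

#' Conflict-detection model parameters
#'
#' The co-occurrence conflict detector's parameters: measurement noise,
#' the per-segment co-occurrence probability threshold `t_inhibitory`
#' (segments below it emit inhibitory signals), and the proportion
#' threshold `t_conflict` above which a stimulus is judged to be in
#' conflict.
#'
#' @param noise A [noise_model()].
#' @param t_inhibitory Probability threshold in (0, 1).
#' @param t_conflict Proportion threshold in (0, 1).
#' @return An object of class `conflict_model_params`.
#' @export
conflict_model_params <- function(noise, t_inhibitory = 1.5e-5,
                                  t_conflict = 0.15) {
  stopifnot(inherits(noise, "noise_model"),
            t_inhibitory > 0, t_inhibitory < 1,
            t_conflict > 0, t_conflict < 1)
  structure(list(noise = noise, t_inhibitory = t_inhibitory,
                 t_conflict = t_conflict),
            class = "conflict_model_params")
}

#' Model observers
#'
#' Constructors for the model observers used by [simulate_experiment()]:
#' * `speed_observer()` — chooses the interval with the larger perceived
#'   speed-in-depth (combined-cue marginal-mean estimate).
#' * `m_difference_observer()` — chooses the interval with the larger
#'   per-segment discrepancy in distance moved between per-cue estimates,
#'   summarised by its `max` or `sd`.
#' * `size_conflict_observer()` — recovers per-segment physical surface
#'   sizes (per cue, or from the combined estimate) and chooses the
#'   interval with the larger size discrepancy (`per_cue` mode, `mean` or
#'   `max` statistic) or the larger spread of combined size estimates
#'   (`combined` mode).
#' * `cooccurrence_observer()` — flags intervals whose proportion of
#'   inhibitory (low co-occurrence probability) segments exceeds
#'   `t_conflict`, choosing the uniquely flagged interval and guessing
#'   otherwise.
#'
#' Each observer carries a `sample_measurements` default: the speed and
#' co-occurrence observers propagate the measurement distributions
#' deterministically (trial variability arises from the stimulus
#' jitters), while the m-difference and size-recovery variants draw
#' noisy measurements, since their difference statistics are meaningful
#' only as noise-limited detectors (deterministically they respond to
#' systematic estimation biases instead of the conflict).
#'
#' @param noise A [noise_model()].
#' @param statistic Summary statistic over segments.
#' @param mode Size-recovery mode, see above.
#' @param params A [conflict_model_params()].
#' @param sample_measurements Draw noisy measurements per trial; see
#'   [estimate_speed()].
#' @return An object of class `observer`.
#' @name observers
NULL

#' @rdname observers
#' @export
speed_observer <- function(noise, sample_measurements = FALSE) {
  stopifnot(inherits(noise, "noise_model"))
  structure(list(noise = noise, sample_measurements = sample_measurements),
            class = c("speed_observer", "observer"))
}

#' @rdname observers
#' @export
m_difference_observer <- function(noise, statistic = c("max", "sd"),
                                  sample_measurements = TRUE) {
  stopifnot(inherits(noise, "noise_model"))
  structure(list(noise = noise, statistic = match.arg(statistic),
                 sample_measurements = sample_measurements),
            class = c("m_difference_observer", "observer"))
}

#' @rdname observers
#' @export
size_conflict_observer <- function(noise, mode = c("per_cue", "combined"),
                                   statistic = c("max", "mean"),
                                   sample_measurements = TRUE) {
  stopifnot(inherits(noise, "noise_model"))
  structure(list(noise = noise, mode = match.arg(mode),
                 statistic = match.arg(statistic),
                 sample_measurements = sample_measurements),
            class = c("size_conflict_observer", "observer"))
}

#' @rdname observers
#' @export
cooccurrence_observer <- function(params, sample_measurements = FALSE) {
  stopifnot(inherits(params, "conflict_model_params"))
  structure(list(noise = params$noise, params = params,
                 sample_measurements = sample_measurements),
            class = c("cooccurrence_observer", "observer"))
}

# ---- batch plumbing -------------------------------------------------------

# Noisy segments for a list of stimuli: one big data.frame with a `stim`
# id column. Noise is drawn boundary-wise from the current RNG stream in
# a single vectorised call, so the draw count is independent of model
# parameters (common-random-numbers fitting relies on this).
batch_noisy_segments <- function(stimuli, noise, stride_frames = 5,
                                 measure = "cumulative",
                                 sample_measurements = FALSE) {
  bounds <- lapply(stimuli, segment_boundaries, stride_frames = stride_frames)
  nb <- vapply(bounds, nrow, integer(1))
  b <- do.call(rbind, bounds)
  disp_noisy <- b$disp
  size_noisy <- b$size
  if (sample_measurements) {
    disp_noisy <- disp_noisy + stats::rnorm(nrow(b), 0, noise$n_disparity)
    size_noisy <- size_noisy + stats::rnorm(nrow(b), 0, noise$n_size)
  }
  offset <- c(0L, cumsum(nb)[-length(nb)])
  idx <- lapply(seq_along(stimuli), function(s) {
    sp <- segment_pairs(nb[s], measure)
    cbind(sp$head + offset[s], sp$tail + offset[s])
  })
  idx <- do.call(rbind, idx)
  data.frame(stim = rep(seq_along(stimuli), nb - 1L),
             disp_start = disp_noisy[idx[, 1]],
             disp_end = disp_noisy[idx[, 2]],
             size_start = size_noisy[idx[, 1]],
             size_end = size_noisy[idx[, 2]])
}

# Per-stimulus decision statistics for every observer type. Returns a
# numeric vector (one value per stimulus) except for the co-occurrence
# observer, which returns a logical conflict flag per stimulus.
observer_statistic <- function(observer, stimuli, tables, co_table = NULL,
                               stride_frames = 5, measure = "cumulative",
                               sample_measurements = NULL) {
  if (is.null(sample_measurements))
    sample_measurements <- isTRUE(observer$sample_measurements)
  seg <- batch_noisy_segments(stimuli, observer$noise, stride_frames, measure,
                              sample_measurements)
  g <- factor(seg$stim, levels = seq_along(stimuli))
  if (inherits(observer, "cooccurrence_observer")) {
    stopifnot(inherits(co_table, "cooccurrence_table"))
    p <- cooccurrence_probability(seg, observer$noise, co_table)
    inhib <- p < observer$params$t_inhibitory
    prop <- as.vector(tapply(inhib, g, mean))
    return(prop > observer$params$t_conflict)
  }
  est <- segment_estimates(seg, observer$noise, tables)
  if (inherits(observer, "speed_observer")) {
    dur <- vapply(stimuli, function(s) s$cd$duration, numeric(1))
    m_by_stim <- split(est$m_comb, g)
    return(vapply(seq_along(stimuli), function(s)
      speed_from_estimates(m_by_stim[[s]], dur[s], measure), numeric(1)))
  }
  if (inherits(observer, "m_difference_observer")) {
    d <- abs(est$m_cs - est$m_cd)
    f <- if (observer$statistic == "max") function(x) max(x, na.rm = TRUE)
         else function(x) stats::sd(x[!is.na(x)])
    return(as.vector(tapply(d, g, f)))
  }
  if (inherits(observer, "size_conflict_observer")) {
    half_rad <- (seg$size_end / RAD_TO_ARCMIN) / 2
    s_cd <- 2 * (est$v_cd - est$m_cd) * tan(half_rad)
    s_cs <- 2 * (est$v_cs - est$m_cs) * tan(half_rad)
    s_comb <- 2 * (est$v_comb - est$m_comb) * tan(half_rad)
    if (observer$mode == "per_cue") {
      d <- abs(s_cs - s_cd)
      f <- if (observer$statistic == "max") function(x) max(x, na.rm = TRUE)
           else function(x) mean(x, na.rm = TRUE)
      return(as.vector(tapply(d, g, f)))
    }
    return(as.vector(tapply(s_comb, g, function(x) stats::sd(x[!is.na(x)]))))
  }
  stop("unknown observer type")
}

# Arrange per-trial conflict/consistent stimuli into interval order.
interval_order <- function(conflict_stims, consistent_stims, conflict_interval) {
  n <- length(conflict_stims)
  first <- vector("list", n)
  second <- vector("list", n)
  c1 <- conflict_interval == 1L
  first[c1] <- conflict_stims[c1]
  first[!c1] <- consistent_stims[!c1]
  second[c1] <- consistent_stims[c1]
  second[!c1] <- conflict_stims[!c1]
  c(first, second)
}

# Choice between paired intervals given per-interval statistics: larger
# statistic wins, exact ties (and double/no conflict flags) resolved by
# the pre-drawn fair coin.
choose_interval <- function(stat1, stat2, coin) {
  ifelse(stat1 == stat2, ifelse(coin < 0.5, 1L, 2L),
         ifelse(stat1 > stat2, 1L, 2L))
}

choose_flagged <- function(flag1, flag2, coin) {
  ifelse(xor(flag1, flag2), ifelse(flag1, 1L, 2L),
         ifelse(coin < 0.5, 1L, 2L))
}

# ---- single-trial interfaces ---------------------------------------------

#' Single-trial 2IFC decisions
#'
#' One stochastic 2IFC decision between two stimulus intervals, using the
#' current RNG stream for measurement noise and tie-breaking. These are
#' single-trial wrappers over the batched machinery used by
#' [simulate_experiment()].
#'
#' `speed_2ifc_choice` chooses the interval with the larger perceived
#' speed; `conflict_2ifc_choice` chooses the interval the observer
#' considers (more) in conflict.
#'
#' @param stim1,stim2 `cue_stimulus` objects (interval 1 and 2).
#' @param observer An observer from [observers].
#' @param tables A `posterior_tables` object.
#' @param co_table A `cooccurrence_table` (co-occurrence observer only).
#' @param stride_frames Frames per sample.
#' @param measure Measurement span (see [sample_segments()]).
#' @param sample_measurements Draw noisy measurements (see
#'   [estimate_speed()]).
#' @return Chosen interval, `1L` or `2L`.
#' @export
speed_2ifc_choice <- function(stim1, stim2, observer, tables,
                              stride_frames = 5,
                              measure = c("cumulative", "consecutive"),
                              sample_measurements = NULL) {
  stopifnot(inherits(observer, "speed_observer"))
  s <- observer_statistic(observer, list(stim1, stim2), tables,
                          stride_frames = stride_frames,
                          measure = match.arg(measure),
                          sample_measurements = sample_measurements)
  choose_interval(s[1], s[2], stats::runif(1))
}

#' @rdname speed_2ifc_choice
#' @export
conflict_2ifc_choice <- function(stim1, stim2, observer, tables,
                                 co_table = NULL, stride_frames = 5,
                                 measure = c("cumulative", "consecutive"),
                                 sample_measurements = NULL) {
  s <- observer_statistic(observer, list(stim1, stim2), tables, co_table,
                          stride_frames, match.arg(measure),
                          sample_measurements)
  if (is.logical(s)) choose_flagged(s[1], s[2], stats::runif(1))
  else choose_interval(s[1], s[2], stats::runif(1))
}

#' Per-segment cue co-occurrence probability
#'
#' Expected co-occurrence mass under the measurement distributions of one
#' or more noisy segments: `sum_{cs, cd} L_cs(cs) L_cd(cd) p(CS & CD)`.
#' With noiseless (delta) weights this is the co-occurrence table value
#' at the true signal pair.
#'
#' @param segments Data.frame with columns `disp_start`, `disp_end`,
#'   `size_start`, `size_end` (see [sample_segments()]).
#' @param noise A [noise_model()].
#' @param co_table A `cooccurrence_table`.
#' @return Numeric vector of probabilities, one per segment.
#' @export
cooccurrence_probability <- function(segments, noise, co_table) {
  stopifnot(inherits(co_table, "cooccurrence_table"))
  grids <- co_table$grids
  Lcd <- cd_weight_matrix(segments$disp_start - segments$disp_end, noise,
                          grids$cd_edges)
  Lcs <- cs_weight_matrix(segments$size_end, segments$size_start, noise,
                          grids$cs_edges)
  cpp_cooccur_prob(co_table$table, Lcs, Lcd)
}

# ---- experiment simulation ------------------------------------------------

#' Simulate a full 2IFC experiment with a model observer
#'
#' Generates the complete factorial trial table of either experiment
#' design and runs the given observer on every trial.
#'
#' Experiment 1 (speed-in-depth discrimination): one interval holds an
#' amplitude cue-conflict stimulus (+/- `conflict_level` log2 units,
#' counterbalanced across CS and CD, direction randomised per trial); the
#' other a consistent-cue stimulus whose speed spans 7 ratios within
#' +/- 1.2 log2 units of standard; surface sizes 10/40/60 mm. Amplitudes
#' are jittered +/- 20 mm and durations +/- 67 ms per interval.
#'
#' Experiment 2 (conflict discrimination): one interval consistent, the
#' other with an amplitude (+/- 1 log2), frequency (-2..0 log2) or phase
#' (0..pi) conflict applied to the CS cue; surface size 40 mm jittered
#' +/- 10 mm, amplitude +/- 20 mm, duration +/- 67 ms. By default the
#' consistent interval shares the conflict interval's jittered base
#' parameters (isolating the conflict); set `share_jitter = FALSE` for
#' fully independent re-randomisation.
#'
#' @param design `"exp1"` or `"exp2"`.
#' @param observer An observer from [observers].
#' @param tables A `posterior_tables` object.
#' @param co_table A `cooccurrence_table` (co-occurrence observer only).
#' @param trials_per_level Trials per stimulus level (per size or
#'   conflict type).
#' @param seed Optional integer seed.
#' @param levels Stimulus levels; defaults to the design's 7 levels.
#' @param sizes Surface sizes (exp1), mm.
#' @param conflict_types Conflict types to include (exp2).
#' @param conflict_level Exp-1 conflict magnitude in log2 units
#'   (default 0.32).
#' @param base_amplitude,duration,frame_rate,surface_size Stimulus
#'   baseline parameters (80 mm, 1.5 s, 60 Hz, 40 mm).
#' @param geometry A [viewing_geometry()].
#' @param jitter Named list of half-ranges for the uniform trial-wise
#'   jitters: `amplitude` (mm), `size` (mm, exp2 only), `duration` (s).
#' @param share_jitter Exp 2 only: share jittered base parameters across
#'   the two intervals of a trial.
#' @param stride_frames Frames per measurement sample.
#' @param measure Measurement span (see [sample_segments()]).
#' @param sample_measurements Draw noisy measurements per trial instead
#'   of propagating distributions centred on the true values (see
#'   [estimate_speed()]); `NULL` (default) defers to the observer's own
#'   `sample_measurements` setting.
#' @return A data.frame of trial records (one row per trial): condition
#'   columns, jittered parameters, interval order, the chosen interval,
#'   and the derived response (`chose_consistent` for exp1, `correct` for
#'   exp2).
#' @export
simulate_experiment <- function(design = c("exp1", "exp2"), observer, tables,
                                co_table = NULL, trials_per_level = 30,
                                seed = NULL, levels = NULL,
                                sizes = c(10, 40, 60),
                                conflict_types = c("amplitude", "frequency", "phase"),
                                conflict_level = 0.32,
                                base_amplitude = 80, duration = 1.5,
                                frame_rate = 60, surface_size = 40,
                                geometry = viewing_geometry(),
                                jitter = list(amplitude = 20, size = 10,
                                              duration = 0.067),
                                share_jitter = TRUE, stride_frames = 5,
                                measure = c("cumulative", "consecutive"),
                                sample_measurements = NULL) {
  design <- match.arg(design)
  measure <- match.arg(measure)
  stopifnot(inherits(observer, "observer"))
  if (!is.null(seed)) set.seed(seed)
  if (design == "exp1") {
    if (is.null(levels)) levels <- seq(-1.2, 1.2, length.out = 7)
    cond <- expand.grid(size = sizes, level = levels)
    cond <- cond[rep(seq_len(nrow(cond)), each = trials_per_level), ]
    n <- nrow(cond)
    tr <- data.frame(trial = seq_len(n), size = cond$size, level = cond$level)
    tr$conflict_dir <- sample(c(-1, 1), n, replace = TRUE)
    tr$amp_conflict <- base_amplitude + stats::runif(n, -1, 1) * jitter$amplitude
    tr$dur_conflict <- duration + stats::runif(n, -1, 1) * jitter$duration
    tr$amp_consistent <- base_amplitude * 2^tr$level +
      stats::runif(n, -1, 1) * jitter$amplitude
    tr$dur_consistent <- duration + stats::runif(n, -1, 1) * jitter$duration
    tr$conflict_interval <- sample(1:2, n, replace = TRUE)
    coin <- stats::runif(n)
    conflict_stims <- lapply(seq_len(n), function(k)
      apply_conflict(triangular_trajectory(tr$amp_conflict[k],
                                           tr$dur_conflict[k], frame_rate),
                     conflict_spec("amplitude", tr$conflict_dir[k] * conflict_level),
                     "both", tr$size[k], geometry))
    consistent_stims <- lapply(seq_len(n), function(k)
      consistent_stimulus(triangular_trajectory(tr$amp_consistent[k],
                                                tr$dur_consistent[k], frame_rate),
                          tr$size[k], geometry))
    s_all <- observer_statistic(
      observer,
      interval_order(conflict_stims, consistent_stims, tr$conflict_interval),
      tables, co_table, stride_frames, measure, sample_measurements)
    tr$chosen_interval <- choose_interval(s_all[seq_len(n)],
                                          s_all[n + seq_len(n)], coin)
    tr$chose_consistent <- tr$chosen_interval != tr$conflict_interval
    # level axis normalised for conflict direction (positive = toward CS)
    tr$level_norm <- tr$level * tr$conflict_dir
    return(tr)
  }
  # exp2
  default_levels <- list(amplitude = seq(-1, 1, length.out = 7),
                         frequency = seq(-2, 0, length.out = 7),
                         phase = seq(0, pi, length.out = 7))
  conflict_types <- match.arg(conflict_types, several.ok = TRUE)
  cond <- do.call(rbind, lapply(conflict_types, function(ct) {
    lv <- if (is.null(levels)) default_levels[[ct]] else levels
    data.frame(conflict_type = ct, level = lv)
  }))
  cond <- cond[rep(seq_len(nrow(cond)), each = trials_per_level), ]
  n <- nrow(cond)
  tr <- data.frame(trial = seq_len(n), conflict_type = cond$conflict_type,
                   level = cond$level)
  tr$amp <- base_amplitude + stats::runif(n, -1, 1) * jitter$amplitude
  tr$size <- surface_size + stats::runif(n, -1, 1) * jitter$size
  tr$dur <- duration + stats::runif(n, -1, 1) * jitter$duration
  if (share_jitter) {
    tr$amp2 <- tr$amp; tr$size2 <- tr$size; tr$dur2 <- tr$dur
  } else {
    tr$amp2 <- base_amplitude + stats::runif(n, -1, 1) * jitter$amplitude
    tr$size2 <- surface_size + stats::runif(n, -1, 1) * jitter$size
    tr$dur2 <- duration + stats::runif(n, -1, 1) * jitter$duration
  }
  tr$conflict_interval <- sample(1:2, n, replace = TRUE)
  coin <- stats::runif(n)
  conflict_stims <- lapply(seq_len(n), function(k)
    apply_conflict(triangular_trajectory(tr$amp[k], tr$dur[k], frame_rate),
                   conflict_spec(as.character(tr$conflict_type[k]), tr$level[k]),
                   "cs", tr$size[k], geometry))
  consistent_stims <- lapply(seq_len(n), function(k)
    consistent_stimulus(triangular_trajectory(tr$amp2[k], tr$dur2[k], frame_rate),
                        tr$size2[k], geometry))
  s_all <- observer_statistic(
    observer,
    interval_order(conflict_stims, consistent_stims, tr$conflict_interval),
    tables, co_table, stride_frames, measure, sample_measurements)
  if (is.logical(s_all)) {
    tr$chosen_interval <- choose_flagged(s_all[seq_len(n)],
                                         s_all[n + seq_len(n)], coin)
  } else {
    tr$chosen_interval <- choose_interval(s_all[seq_len(n)],
                                          s_all[n + seq_len(n)], coin)
  }
  tr$correct <- tr$chosen_interval == tr$conflict_interval
  tr
}
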