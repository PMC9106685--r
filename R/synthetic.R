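# Synthetic observer datasets. Three generators of trial tables with the
# statistical structure the downstream analyses assume:
#   * bernoulli   — responses drawn from a known psychometric curve; the
#                   oracle for curve-fitting recovery tests
#   * linear-mle  — a closed-form maximum-likelihood linear-integration
#                   observer with known single-cue sigmas; the exact
#                   oracle for the implied-uncertainty algebra
#   * full-model  — the package's own posterior-table observers
# All emit trial tables schema-compatible with simulate_experiment().

#' Synthetic observer specification
#'
#' @param generator `"bernoulli"`, `"linear_mle"`, or `"full_model"`.
#' @param params Generator parameters: `mu`, `sigma` for bernoulli
#'   (scalars, or named by surface size / conflict type); `sigma_cd`,
#'   `sigma_cs` (level units) for linear-mle; `observer` (an
#'   [observers] object) for full-model.
#' @param trials_per_level Trials per stimulus level (default 30, the
#'   experimental minimum).
#' @return An object of class `synthetic_observer`.
#' @export
synthetic_observer <- function(generator = c("bernoulli", "linear_mle",
                                             "full_model"),
                               params = list(), trials_per_level = 30) {
  generator <- match.arg(generator)
  need <- switch(generator,
                 bernoulli = c("mu", "sigma"),
                 linear_mle = c("sigma_cd", "sigma_cs"),
                 full_model = "observer")
  if (!all(need %in% names(params)))
    stop("generator '", generator, "' needs params: ",
         paste(need, collapse = ", "))
  structure(list(generator = generator, params = params,
                 trials_per_level = trials_per_level),
            class = "synthetic_observer")
}

# Parameter lookup allowing per-condition values: scalar, or named
# vector/list indexed by condition label.
cond_param <- function(p, cond) {
  if (length(p) == 1L && is.null(names(p))) return(as.numeric(p))
  if (!is.null(names(p)) && as.character(cond) %in% names(p))
    return(as.numeric(p[[as.character(cond)]]))
  as.numeric(p[[1]])
}

#' Generate a synthetic speed-discrimination (Exp 1 design) trial table
#'
#' @param spec A [synthetic_observer()].
#' @param seed Optional seed.
#' @param tables A `posterior_tables` object (full-model generator only).
#' @param levels Speed-ratio levels (log2 units).
#' @param sizes Surface sizes, mm.
#' @param conflict_level Conflict magnitude, log2 units.
#' @param ... Passed to [simulate_experiment()] (full-model generator).
#' @return A trial data.frame (see [simulate_experiment()]).
#' @export
generate_exp1_dataset <- function(spec, seed = NULL, tables = NULL,
                                  levels = seq(-1.2, 1.2, length.out = 7),
                                  sizes = c(10, 40, 60),
                                  conflict_level = 0.32, ...) {
  stopifnot(inherits(spec, "synthetic_observer"))
  if (spec$generator == "full_model") {
    stopifnot(!is.null(tables))
    return(simulate_experiment("exp1", spec$params$observer, tables,
                               trials_per_level = spec$trials_per_level,
                               seed = seed, levels = levels, sizes = sizes,
                               conflict_level = conflict_level, ...))
  }
  if (!is.null(seed)) set.seed(seed)
  cond <- expand.grid(size = sizes, level = levels)
  cond <- cond[rep(seq_len(nrow(cond)), each = spec$trials_per_level), ]
  n <- nrow(cond)
  tr <- data.frame(trial = seq_len(n), size = cond$size, level = cond$level)
  tr$conflict_dir <- sample(c(-1, 1), n, replace = TRUE)
  tr$conflict_interval <- sample(1:2, n, replace = TRUE)
  tr$level_norm <- tr$level * tr$conflict_dir
  # P(consistent judged faster | r, dir) = Phi((r - dir * PSE) / sigma):
  # the PSE mirrors with the conflict direction, so the direction-
  # normalised curve (axis and response flipped for dir = -1) has PSE mu
  if (spec$generator == "bernoulli") {
    mu <- vapply(tr$size, function(sz) cond_param(spec$params$mu, sz),
                 numeric(1))
    sig <- vapply(tr$size, function(sz) cond_param(spec$params$sigma, sz),
                  numeric(1))
    p <- stats::pnorm((tr$level - tr$conflict_dir * mu) / sig)
  } else {
    s2cd <- spec$params$sigma_cd^2
    s2cs <- spec$params$sigma_cs^2
    w_cd <- s2cs / (s2cd + s2cs)      # w_CD / w_CS = sigma2_CS / sigma2_CD
    pse <- (1 - w_cd) * conflict_level + w_cd * (-conflict_level)
    sigma_comb <- sqrt(s2cd * s2cs / (s2cd + s2cs))
    p <- stats::pnorm((tr$level - tr$conflict_dir * pse) / sigma_comb)
  }
  tr$chose_consistent <- stats::runif(n) < p
  tr$chosen_interval <- ifelse(tr$chose_consistent,
                               3L - tr$conflict_interval, tr$conflict_interval)
  tr
}

#' Generate a synthetic conflict-discrimination (Exp 2 design) trial table
#'
#' The bernoulli generator draws correct/incorrect responses from
#' `0.5 + 0.5 Phi((c - mu) / sigma)` where `c` is the conflict magnitude
#' on the folded axis (|log2 ratio| for amplitude and frequency, radians
#' for phase); `mu` and `sigma` may be named per conflict type.
#'
#' @param spec A [synthetic_observer()] (`bernoulli` or `full_model`).
#' @param seed Optional seed.
#' @param tables,co_table Distribution tables (full-model generator).
#' @param conflict_types Conflict types to include.
#' @param ... Passed to [simulate_experiment()] (full-model generator).
#' @return A trial data.frame.
#' @export
generate_exp2_dataset <- function(spec, seed = NULL, tables = NULL,
                                  co_table = NULL,
                                  conflict_types = c("amplitude", "frequency",
                                                     "phase"), ...) {
  stopifnot(inherits(spec, "synthetic_observer"))
  if (spec$generator == "linear_mle")
    stop("the linear-mle generator is defined for the speed task only")
  if (spec$generator == "full_model") {
    stopifnot(!is.null(tables))
    return(simulate_experiment("exp2", spec$params$observer, tables, co_table,
                               trials_per_level = spec$trials_per_level,
                               seed = seed, conflict_types = conflict_types,
                               ...))
  }
  if (!is.null(seed)) set.seed(seed)
  default_levels <- list(amplitude = seq(-1, 1, length.out = 7),
                         frequency = seq(-2, 0, length.out = 7),
                         phase = seq(0, pi, length.out = 7))
  cond <- do.call(rbind, lapply(conflict_types, function(ct)
    data.frame(conflict_type = ct, level = default_levels[[ct]])))
  cond <- cond[rep(seq_len(nrow(cond)), each = spec$trials_per_level), ]
  n <- nrow(cond)
  tr <- data.frame(trial = seq_len(n), conflict_type = cond$conflict_type,
                   level = cond$level)
  tr$conflict_interval <- sample(1:2, n, replace = TRUE)
  mag <- conflict_magnitude(tr$conflict_type, tr$level)
  mu <- vapply(seq_len(n), function(k) cond_param(spec$params$mu,
                                                  tr$conflict_type[k]),
               numeric(1))
  sig <- vapply(seq_len(n), function(k) cond_param(spec$params$sigma,
                                                   tr$conflict_type[k]),
                numeric(1))
  p <- 0.5 + 0.5 * stats::pnorm((mag - mu) / sig)
  tr$correct <- stats::runif(n) < p
  tr$chosen_interval <- ifelse(tr$correct, tr$conflict_interval,
                               3L - tr$conflict_interval)
  tr
}

#' Conflict magnitude on the folded analysis axis
#'
#' Amplitude and frequency conflicts are analysed by their absolute log2
#' ratio; phase conflicts by the phase offset itself.
#'
#' @param conflict_type Character vector of types.
#' @param level Signed conflict levels.
#' @return Non-negative magnitudes.
#' @export
conflict_magnitude <- function(conflict_type, level) {
  ifelse(as.character(conflict_type) == "phase", level, abs(level))
}

#' Validate a trial table's schema
#'
#' Checks that a trial table (simulated or synthetic) carries the columns
#' the psychometric analyses require.
#'
#' @param trials A data.frame.
#' @param task `"speed"` or `"conflict"`.
#' @return Invisibly TRUE; errors otherwise.
#' @export
validate_trials <- function(trials, task = c("speed", "conflict")) {
  task <- match.arg(task)
  need <- if (task == "speed")
    c("size", "level", "conflict_dir", "conflict_interval",
      "chosen_interval", "chose_consistent", "level_norm")
  else c("conflict_type", "level", "conflict_interval", "chosen_interval",
         "correct")
  missing <- setdiff(need, names(trials))
  if (length(missing))
    stop("trial table is missing columns: ", paste(missing, collapse = ", "))
  if (!all(trials$chosen_interval %in% 1:2))
    stop("chosen_interval must be 1 or 2")
  invisible(TRUE)
}
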