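# Fitting observer-model parameters to psychometric data by minimising
# the mean squared error between model and observed proportions, with
# common random numbers across objective evaluations so the stochastic
# objective is a deterministic function of the parameters for a fixed
# seed.

#' Fit specification
#'
#' Free parameters, bounds, and simulation budget for [fit_observer()].
#' Noise parameters (and `t_inhibitory`) are searched on the log scale,
#' `t_conflict` on the logit scale.
#'
#' @param init Named numeric vector of initial values on the natural
#'   scale. For the speed task: `n_disparity`, `n_size` (arcmin). For the
#'   conflict task additionally `t_inhibitory`, `t_conflict`.
#' @param lower,upper Named bounds on the natural scale (same names as
#'   `init`).
#' @param model_trials Model trials per level per objective evaluation.
#' @param n_starts Number of jittered simplex starts.
#' @param maxit Iteration cap per start.
#' @return An object of class `fit_spec`.
#' @export
fit_spec <- function(init = c(n_disparity = 0.5, n_size = 2),
                     lower = NULL, upper = NULL,
                     model_trials = 100, n_starts = 3, maxit = 60) {
  stopifnot(!is.null(names(init)), all(init > 0 | names(init) == "t_conflict"))
  if (is.null(lower))
    lower <- c(n_disparity = 0.02, n_size = 0.1, t_inhibitory = 1e-9,
               t_conflict = 0.01)[names(init)]
  if (is.null(upper))
    upper <- c(n_disparity = 10, n_size = 30, t_inhibitory = 0.5,
               t_conflict = 0.95)[names(init)]
  structure(list(init = init, lower = lower, upper = upper,
                 model_trials = model_trials, n_starts = n_starts,
                 maxit = maxit),
            class = "fit_spec")
}

par_transform <- function(p) {
  out <- log(p)
  if ("t_conflict" %in% names(p)) out["t_conflict"] <- stats::qlogis(p["t_conflict"])
  out
}

par_untransform <- function(tp) {
  out <- exp(tp)
  if ("t_conflict" %in% names(tp)) out["t_conflict"] <- stats::plogis(tp["t_conflict"])
  out
}

observer_from_params <- function(design, p) {
  noise <- noise_model(p[["n_disparity"]], p[["n_size"]])
  if (design == "exp1") speed_observer(noise)
  else cooccurrence_observer(conflict_model_params(noise, p[["t_inhibitory"]],
                                                   p[["t_conflict"]]))
}

# Model psychometric proportions at the dataset's conditions, using a
# fixed seed (common random numbers).
model_proportions <- function(design, p, data, tables, co_table, spec, seed,
                              ...) {
  obs <- observer_from_params(design, p)
  if (design == "exp1") {
    tr <- simulate_experiment("exp1", obs, tables,
                              trials_per_level = spec$model_trials,
                              seed = seed, levels = sort(unique(data$level)),
                              sizes = sort(unique(data$size)), ...)
    agg <- aggregate_trials(tr, "speed")
    key <- paste(agg$size, round(agg$level, 8))
    ref <- paste(data$size, round(data$level, 8))
  } else {
    tr <- simulate_experiment("exp2", obs, tables, co_table,
                              trials_per_level = spec$model_trials,
                              seed = seed,
                              conflict_types = unique(as.character(data$conflict_type)),
                              ...)
    agg <- aggregate_trials(tr, "conflict")
    key <- paste(agg$conflict_type, round(agg$level, 8))
    ref <- paste(data$conflict_type, round(data$level, 8))
  }
  idx <- match(ref, key)
  if (anyNA(idx)) stop("model simulation did not cover the dataset's conditions")
  (agg$k / agg$n)[idx]
}

#' Fit an observer model to psychometric data
#'
#' Minimises the mean squared error between model and observed
#' proportions over all levels (and sizes or conflict types) using a
#' derivative-free simplex search on transformed parameters, with
#' multiple jittered starts and common random numbers across objective
#' evaluations.
#'
#' @param data Aggregated psychometric data from [aggregate_trials()].
#' @param tables A `posterior_tables` object.
#' @param spec A [fit_spec()].
#' @param design `"exp1"` (speed task, free parameters `n_disparity`,
#'   `n_size`) or `"exp2"` (conflict task, additionally `t_inhibitory`,
#'   `t_conflict`).
#' @param seed Integer seed controlling both the common-random-numbers
#'   stream of the objective and the start jitter.
#' @param co_table A `cooccurrence_table` (exp2).
#' @param ... Passed through to [simulate_experiment()].
#' @return An object of class `fit_result`: `par` (natural scale),
#'   `objective` (MSE at optimum), `evals`, `converged`, per-condition
#'   model proportions at the optimum, and per-start diagnostics.
#' @export
fit_observer <- function(data, tables, spec = fit_spec(),
                         design = c("exp1", "exp2"), seed = 1,
                         co_table = NULL, ...) {
  design <- match.arg(design)
  if (design == "exp2" &&
      !all(c("t_inhibitory", "t_conflict") %in% names(spec$init)))
    stop("exp2 fits require t_inhibitory and t_conflict in the fit spec")
  p_obs <- data$k / data$n
  evals <- 0L
  tl <- par_transform(spec$lower)
  tu <- par_transform(spec$upper)
  objective <- function(tp) {
    tp <- pmin(pmax(tp, tl), tu)
    p <- par_untransform(tp)
    evals <<- evals + 1L
    pm <- model_proportions(design, p, data, tables, co_table, spec, seed, ...)
    mean((pm - p_obs)^2)
  }
  set.seed(seed + 1000L)
  starts <- lapply(seq_len(spec$n_starts), function(ss) {
    tp0 <- par_transform(spec$init)
    if (ss > 1) tp0 <- tp0 + stats::rnorm(length(tp0), 0, 0.3)
    pmin(pmax(tp0, tl), tu)
  })
  runs <- lapply(starts, function(tp0)
    stats::optim(tp0, objective, method = "Nelder-Mead",
                 control = list(maxit = spec$maxit, reltol = 1e-4)))
  best <- runs[[which.min(vapply(runs, `[[`, numeric(1), "value"))]]
  par <- par_untransform(pmin(pmax(best$par, tl), tu))
  structure(list(par = par, objective = best$value, evals = evals,
                 converged = best$convergence == 0,
                 model_proportions = model_proportions(design, par, data,
                                                       tables, co_table,
                                                       spec, seed, ...),
                 data = data,
                 starts = data.frame(
                   start = seq_along(runs),
                   objective = vapply(runs, `[[`, numeric(1), "value"),
                   convergence = vapply(runs, `[[`, numeric(1), "convergence"))),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("fit_result:\n  parameters:\n")
  for (nm in names(x$par)) cat(sprintf("    %-12s %.4g\n", nm, x$par[[nm]]))
  cat(sprintf("  MSE = %.5g  (%d objective evaluations)\n", x$objective, x$evals))
  invisible(x)
}

#' Parameter-recovery study
#'
#' Repeatedly generates synthetic data from the full model at known
#' parameters, re-fits, and reports the distribution of recovered minus
#' true parameters.
#'
#' @param true_params Named vector of generating parameters.
#' @param tables,co_table Distribution tables.
#' @param design `"exp1"` or `"exp2"`.
#' @param n_repeats Number of generate-and-refit repeats.
#' @param trials_per_level Trials per level in each generated dataset.
#' @param spec A [fit_spec()].
#' @param seed Base seed; repeat r uses `seed + r` for generation and
#'   `seed + 5000 + r` for fitting.
#' @param ... Passed to [simulate_experiment()].
#' @return A list with `recovered` (data.frame, one row per repeat) and
#'   `summary` (bias and spread per parameter).
#' @export
parameter_recovery <- function(true_params, tables, design = c("exp1", "exp2"),
                               n_repeats = 5, trials_per_level = 200,
                               spec = fit_spec(), seed = 1, co_table = NULL,
                               ...) {
  design <- match.arg(design)
  rows <- lapply(seq_len(n_repeats), function(r) {
    obs <- observer_from_params(design, true_params)
    tr <- simulate_experiment(design, obs, tables, co_table,
                              trials_per_level = trials_per_level,
                              seed = seed + r, ...)
    agg <- aggregate_trials(tr, if (design == "exp1") "speed" else "conflict")
    fit <- fit_observer(agg, tables, spec, design, seed = seed + 5000L + r,
                        co_table = co_table, ...)
    out <- as.list(fit$par)
    out$objective <- fit$objective
    out$repeat_id <- r
    as.data.frame(out)
  })
  recovered <- do.call(rbind, rows)
  nm <- names(true_params)
  summary <- data.frame(
    parameter = nm,
    true = as.numeric(true_params),
    mean_recovered = vapply(nm, function(p) mean(recovered[[p]]), numeric(1)),
    sd_recovered = vapply(nm, function(p) stats::sd(recovered[[p]]), numeric(1)))
  summary$bias <- summary$mean_recovered - summary$true
  list(recovered = recovered, summary = summary)
}
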