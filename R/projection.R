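#' Long-run projection of the base model
#'
#' Integrates the base dynamics from a fitted (or supplied) initial state to
#' a horizon year and reports terminal values, the female-to-male victim gap
#' `g(t) = V_F(t) / V_M(t)`, and the distance of the terminal victim levels
#' from their saturation values.
#'
#' @param params A [model_params].
#' @param state0 Initial [state_vec] at `t0`.
#' @param horizon Final calendar year.
#' @param t0 Calendar year of `state0` (default 2010).
#' @param step Output spacing in years (default 0.25).
#' @return A list of class `projection_report`: `trajectory`
#'   (`violence_trajectory`), `gap` (per output time), `min_gap`,
#'   `min_gap_year`, `terminal` (state at horizon), and
#'   `saturation_gap` (relative distance of terminal victims from
#'   equilibrium, when defined).
#' @export
project <- function(params, state0, horizon, t0 = 2010, step = 0.25) {
  if (horizon < t0) stop("horizon must not precede t0")
  times <- if (horizon == t0) t0 else unique(c(seq(t0, horizon, by = step), horizon))
  tr <- integrate_model(state0, params, time_grid(t0, times), model = "base")
  projection_report(tr, params, model = "base")
}

projection_report <- function(tr, params, model) {
  gap <- ifelse(tr$V_M > 0, tr$V_F / tr$V_M, Inf)
  i <- which.min(gap)
  terminal <- unlist(tr[nrow(tr), state_fields])
  sat_gap <- NULL
  eq <- try(recovery_equilibrium(params, model = model), silent = TRUE)
  if (!inherits(eq, "try-error") && isTRUE(eq$converged)) {
    vstar <- eq$state[c("V_M", "V_F")]
    sat_gap <- ifelse(vstar > 0,
                      abs(terminal[c("V_M", "V_F")] - vstar) / vstar,
                      abs(terminal[c("V_M", "V_F")]))
    names(sat_gap) <- c("V_M", "V_F")
  }
  structure(list(trajectory = tr, gap = gap, min_gap = gap[i],
                 min_gap_year = tr$year[i], terminal = terminal,
                 saturation_gap = sat_gap, equilibrium = eq),
            class = "projection_report")
}

#' Intervention schedule for the recovery models
#'
#' @param recovery_year Calendar year at which the recovery dynamics switch
#'   on (hard switch, state handed over exactly).
#' @param gamma_F Female victim recovery rate (1/year).
#' @param delta_A Aggressor recovery rate (1/year); 0 selects the
#'   female-only recovery model.
#' @return A list of class `recovery_schedule`.
#' @export
recovery_schedule <- function(recovery_year, gamma_F, delta_A = 0) {
  if (gamma_F < 0 || delta_A < 0) stop("recovery rates must be nonnegative")
  structure(list(recovery_year = recovery_year, gamma_F = gamma_F,
                 delta_A = delta_A),
            class = "recovery_schedule")
}

#' Projection with a recovery-year regime switch
#'
#' Runs the base dynamics from `t0` up to the recovery year, then hands the
#' state over exactly (no jump) to the female-recovery model (if
#' `delta_A = 0`) or the complete recovery model, and continues to the
#' horizon.
#'
#' @param fit A `fit_result` from the base model, or a list with elements
#'   `params`, `state0` and `t0`.
#' @param schedule A [recovery_schedule].
#' @param horizon Final calendar year (default 2034).
#' @param step Output spacing in years.
#' @return A `projection_report`; its trajectory covers `t0` to `horizon`
#'   with the switch applied.
#' @export
project_with_recovery <- function(fit, schedule, horizon = 2034,
                                  t0 = fit$t0, step = 0.25) {
  if (schedule$recovery_year < t0 || schedule$recovery_year > horizon)
    stop("recovery_year must lie within [t0, horizon]")
  p <- fit$params
  p[["gamma_F"]] <- schedule$gamma_F
  p[["delta_A"]] <- schedule$delta_A
  model <- if (schedule$delta_A > 0) "complete" else "female"

  ry <- schedule$recovery_year
  pre_times <- unique(c(seq(t0, ry, by = step), ry))
  pre <- integrate_model(fit$state0, fit$params, time_grid(t0, pre_times),
                         model = "base")
  handover <- state_vec(A = pre$A[nrow(pre)], S = pre$S[nrow(pre)],
                        V_M = pre$V_M[nrow(pre)], V_F = pre$V_F[nrow(pre)])
  if (horizon > ry) {
    post_times <- unique(c(seq(ry, horizon, by = step), horizon))
    post <- integrate_model(handover, p, time_grid(ry, post_times),
                            model = model)
    tr <- rbind(pre[pre$year < ry, ], post)
  } else {
    tr <- pre
  }
  rownames(tr) <- NULL
  class(tr) <- c("violence_trajectory", "data.frame")
  rep_ <- projection_report(tr, p, model = model)
  rep_$schedule <- schedule
  rep_
}

#' Sweep recovery rates and recovery years
#'
#' Runs [project_with_recovery()] over the Cartesian grid of `gamma_F`,
#' `delta_A` and recovery years and summarizes each cell.
#'
#' @param fit A `fit_result` (base model).
#' @param gammas,deltas Numeric vectors of recovery rates (1/year).
#' @param recovery_years Vector of switch years.
#' @param horizon Final calendar year.
#' @return A list with `summary` (data frame: `gamma_F, delta_A,
#'   recovery_year, terminal_V_F, terminal_V_M, min_gap, gap_year`) and
#'   `reports` (list of `projection_report`s in row order).
#' @export
sweep_recovery <- function(fit, gammas, deltas = 0, recovery_years,
                           horizon = 2034) {
  if (!length(gammas) || !length(deltas) || !length(recovery_years))
    stop("grids must be nonempty")
  cells <- expand.grid(gamma_F = gammas, delta_A = deltas,
                       recovery_year = recovery_years)
  reports <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sch <- recovery_schedule(cells$recovery_year[i], cells$gamma_F[i],
                             cells$delta_A[i])
    reports[[i]] <- project_with_recovery(fit, sch, horizon = horizon)
  }
  cells$terminal_V_F <- vapply(reports, function(r) r$terminal[["V_F"]], 1)
  cells$terminal_V_M <- vapply(reports, function(r) r$terminal[["V_M"]], 1)
  cells$min_gap <- vapply(reports, function(r) r$min_gap, 1)
  cells$gap_year <- vapply(reports, function(r) r$min_gap_year, 1)
  list(summary = cells, reports = reports)
}

#' Smallest female recovery rate achieving victim equality
#'
#' Two complementary answers to "how strong must female-victim recovery be
#' for female victims to fall to the male level?" (aggressor recovery off):
#'
#' * An asymptotic closed form from the equilibrium ratio
#'   `V_F*/V_M* = beta_F alpha_M / (beta_M (alpha_F + gamma_F))`:
#'   equality requires `gamma_F >= alpha_M beta_F / beta_M - alpha_F`.
#' * A finite-horizon bisection on `gamma_F` (reported as a multiple of
#'   `alpha_F`) for the smallest rate with `V_F(t) <= V_M(t)` at some time
#'   within `within_years` after the recovery year.
#'
#' @param fit A `fit_result` (base model).
#' @param recovery_year Switch year for the finite-horizon search.
#' @param within_years Window after the switch in which equality must occur
#'   (default 10).
#' @param max_multiplier Upper end of the bisection bracket, as a multiple
#'   of `alpha_F` (default 1e4).
#' @param tol Bisection tolerance on the multiplier.
#' @return List with `asymptotic_gamma` (closed form, floored at 0),
#'   `asymptotic_multiplier` (same over `alpha_F`), `achievable` (logical,
#'   finite-horizon), `multiplier` and `gamma_F` (finite-horizon bisection
#'   results, `NA` when not achievable).
#' @export
equality_threshold <- function(fit, recovery_year = 2023, within_years = 10,
                               max_multiplier = 1e4, tol = 1e-3) {
  p <- fit$params
  if (p[["delta_A"]] != 0) stop("equality_threshold assumes delta_A = 0")
  gamma_star <- max(0, p[["alpha_M"]] * p[["beta_F"]] / p[["beta_M"]] -
                      p[["alpha_F"]])
  horizon <- recovery_year + within_years

  reaches <- function(mult) {
    sch <- recovery_schedule(recovery_year, gamma_F = mult * p[["alpha_F"]])
    rep_ <- project_with_recovery(fit, sch, horizon = horizon, step = 0.1)
    post <- rep_$trajectory$year >= recovery_year
    any(rep_$trajectory$V_F[post] <= rep_$trajectory$V_M[post])
  }

  if (reaches(0)) {
    mult <- 0
  } else if (!reaches(max_multiplier)) {
    return(list(asymptotic_gamma = gamma_star,
                asymptotic_multiplier = gamma_star / p[["alpha_F"]],
                achievable = FALSE, multiplier = NA_real_,
                gamma_F = NA_real_))
  } else {
    lo <- 0; hi <- max_multiplier
    while (hi - lo > tol * max(1, hi)) {
      mid <- (lo + hi) / 2
      if (reaches(mid)) hi <- mid else lo <- mid
    }
    mult <- hi
  }
  list(asymptotic_gamma = gamma_star,
       asymptotic_multiplier = gamma_star / p[["alpha_F"]],
       achievable = TRUE, multiplier = mult,
       gamma_F = mult * p[["alpha_F"]])
}
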