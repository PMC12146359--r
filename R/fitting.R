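#' Configuration for the two-stage least-squares fit
#'
#' Stage 1 fits the uncoupled aggressor logistic (`r_A`, `k_A`, `A0`) to the
#' aggressor target series by ordinary least squares on the closed-form
#' solution. Stage 2 freezes those values and estimates the remaining six
#' rates plus (optionally) the initial conditions of the coupled
#' compartments by bounded trust-region least squares on the integrated
#' trajectory. Victim death rates are bounded above by 1 to exclude
#' unrealistically fast removal.
#'
#' @param bounds Named list of `c(lower, upper)` pairs overriding the
#'   defaults for any of `r_S`, `k_S`, `beta_F`, `beta_M`, `alpha_F`,
#'   `alpha_M`. Defaults: rates in `[1e-4, 2]`, capacities relative to the
#'   observed susceptible maximum, interaction rates in `[1e-9, 1e-2]`,
#'   death rates in `[1e-3, alpha_max]`.
#' @param alpha_max Upper bound for the victim death rates (default 1).
#' @param optimize_initial_conditions Optimize `S0`, `V_M0`, `V_F0` within
#'   `[0.25, 4] x` the first observation of each compartment (default TRUE).
#' @param residual_blocks Compartments entering the stage-2 objective; any
#'   subset of `c("S", "V_M", "V_F")`.
#' @param normalization Per-block residual scaling: `"mean"` (default;
#'   divide each block by the mean of its observations so the small victim
#'   blocks are not drowned by the susceptible block), `"std"`, or `"none"`.
#' @param multistart Number of optimizer starts (one data-driven start plus
#'   Latin-hypercube draws within bounds).
#' @param seed Integer seed making the multistart draws reproducible.
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param rtol,atol Integration tolerances used inside the objective.
#' @return A list of class `fit_config`.
#' @export
fit_config <- function(bounds = list(), alpha_max = 1,
                       optimize_initial_conditions = TRUE,
                       residual_blocks = c("S", "V_M", "V_F"),
                       normalization = c("mean", "std", "none"),
                       multistart = 8, seed = 1, maxiter = 80,
                       rtol = 1e-8, atol = 1e-10) {
  normalization <- match.arg(normalization)
  if (!all(residual_blocks %in% c("S", "V_M", "V_F")) ||
      length(residual_blocks) == 0)
    stop("residual_blocks must be a nonempty subset of S, V_M, V_F")
  if (alpha_max <= 0) stop("alpha_max must be positive")
  if (any(vapply(bounds, function(b) any(b < 0), logical(1))))
    stop("all bounds must be nonnegative")
  structure(list(bounds = bounds, alpha_max = alpha_max,
                 optimize_initial_conditions = optimize_initial_conditions,
                 residual_blocks = residual_blocks,
                 normalization = normalization,
                 multistart = multistart, seed = seed, maxiter = maxiter,
                 rtol = rtol, atol = atol),
            class = "fit_config")
}

stage2_bounds <- function(series, cfg) {
  smax <- max(series$fit$S_obs)
  defaults <- list(
    r_S     = c(1e-4, 2),
    k_S     = c(0.5 * smax, 50 * smax),
    beta_F  = c(1e-9, 1e-2),
    beta_M  = c(1e-9, 1e-2),
    alpha_F = c(1e-3, cfg$alpha_max),
    alpha_M = c(1e-3, cfg$alpha_max)
  )
  for (nm in names(cfg$bounds)) defaults[[nm]] <- cfg$bounds[[nm]]
  defaults
}

#' Stage 1: logistic fit of the aggressor series
#'
#' Minimizes the sum of squared differences between the closed-form logistic
#' solution and the aggressor target series over `(r_A, k_A, A0)`. A constant
#' series is a degenerate logistic: the carrying capacity is identified as
#' the constant but the growth rate is not; this is flagged rather than
#' failing.
#'
#' @param series A `scenario_series` (see [build_scenario()]).
#' @param cfg A [fit_config].
#' @return List with `r_A`, `k_A`, `A0`, `rss`, `identifiable`, `converged`.
#' @export
fit_aggressor_logistic <- function(series, cfg = fit_config()) {
  obs <- series$fit
  if (nrow(obs) < 3) stop("need at least 3 fit years for the logistic fit")
  t0 <- obs$year[1]
  tt <- obs$year - t0
  y <- obs$A_obs

  if (stats::sd(y) / mean(y) < 1e-10) {
    return(list(r_A = 0, k_A = mean(y), A0 = mean(y), rss = 0,
                identifiable = FALSE, converged = TRUE,
                message = "constant aggressor series: growth rate unidentifiable"))
  }

  resid_fun <- function(th) {
    p <- model_params(r_A = exp(th[1]), k_A = exp(th[2]),
                      r_S = 1, k_S = 1, beta_F = 0, beta_M = 0,
                      alpha_F = 1, alpha_M = 1)
    aggressor_closed_form(exp(th[3]), p, tt) - y
  }
  lower <- log(c(r_A = 1e-5, k_A = 0.2 * max(y), A0 = 0.1 * y[1]))
  upper <- log(c(r_A = 5,    k_A = 100 * max(y), A0 = 5 * y[1]))
  growth0 <- max((log(y[length(y)]) - log(y[1])) / max(tt), 1e-4)
  starts <- lapply(c(1.2, 1.5, 3, 10), function(km)
    log(c(r_A = growth0, k_A = km * max(y), A0 = y[1])))
  best <- NULL
  for (st in starts) {
    ans <- try(suppressWarnings(minpack.lm::nls.lm(
      par = pmin(pmax(st, lower), upper), lower = lower, upper = upper,
      fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200))), silent = TRUE)
    if (inherits(ans, "try-error")) next
    if (is.null(best) || ans$deviance < best$deviance) best <- ans
  }
  if (is.null(best)) stop("aggressor logistic fit failed to converge")
  th <- best$par
  list(r_A = exp(th[[1]]), k_A = exp(th[[2]]), A0 = exp(th[[3]]),
       rss = best$deviance, identifiable = TRUE,
       converged = best$info %in% 1:4,
       message = best$message)
}

# Map a stage-2 parameter vector (log scale for rates, linear for initial
# conditions) to model params + initial state.
stage2_decode <- function(th, fixed, obs1, cfg) {
  p <- model_params(r_A = fixed$r_A, k_A = fixed$k_A,
                    r_S = exp(th[["r_S"]]), k_S = exp(th[["k_S"]]),
                    beta_F = exp(th[["beta_F"]]), beta_M = exp(th[["beta_M"]]),
                    alpha_F = exp(th[["alpha_F"]]), alpha_M = exp(th[["alpha_M"]]))
  if (cfg$optimize_initial_conditions) {
    s0 <- state_vec(A = fixed$A0, S = th[["S0"]],
                    V_M = th[["V_M0"]], V_F = th[["V_F0"]])
  } else {
    s0 <- state_vec(A = fixed$A0, S = obs1$S_obs,
                    V_M = obs1$V_M_obs, V_F = obs1$V_F_obs)
  }
  list(params = p, state0 = s0)
}

block_norms <- function(obs, blocks, mode) {
  vapply(blocks, function(b) {
    x <- obs[[paste0(b, "_obs")]]
    switch(mode,
           mean = max(mean(x), .Machine$double.eps),
           std  = max(stats::sd(x), .Machine$double.eps),
           none = 1)
  }, numeric(1))
}

#' Stage 2: full-model trajectory fit
#'
#' With the aggressor logistic frozen from stage 1, estimates
#' `(r_S, k_S, beta_F, beta_M, alpha_F, alpha_M)` — and by default the
#' initial conditions `S0`, `V_M0`, `V_F0` — by bounded Levenberg-Marquardt
#' least squares on the stacked, block-normalized residuals between the
#' integrated base-model trajectory and the target series over the fit
#' years. Rates are optimized on the log scale (the interaction rates span
#' orders of magnitude); bounds are enforced throughout, including the
#' death-rate cap `alpha <= alpha_max`. Integration failures during a trial
#' are penalized, not fatal.
#'
#' @param series A `scenario_series`.
#' @param aggressor_fit Output of [fit_aggressor_logistic()].
#' @param cfg A [fit_config].
#' @return A list of class `fit_result`: `params` ([model_params]),
#'   `state0`, `t0`, per-block `rmse` on fit years, `objective`,
#'   `diagnostics` (start index, iterations, convergence, monotone
#'   objective trace, integration-failure count) and the `series` it was
#'   fitted to.
#' @export
fit_full_model <- function(series, aggressor_fit, cfg = fit_config()) {
  obs <- series$fit
  t0 <- obs$year[1]
  fixed <- list(r_A = aggressor_fit$r_A, k_A = aggressor_fit$k_A,
                A0 = aggressor_fit$A0)
  blocks <- cfg$residual_blocks
  norms <- block_norms(obs, blocks, cfg$normalization)
  grid <- time_grid(t0, obs$year)

  bl <- stage2_bounds(series, cfg)
  rate_names <- c("r_S", "k_S", "beta_F", "beta_M", "alpha_F", "alpha_M")
  lower <- log(vapply(bl, `[`, numeric(1), 1))[rate_names]
  upper <- log(vapply(bl, `[`, numeric(1), 2))[rate_names]
  names(lower) <- names(upper) <- rate_names
  obs1 <- obs[1, ]
  if (cfg$optimize_initial_conditions) {
    ic0 <- c(S0 = obs1$S_obs, V_M0 = obs1$V_M_obs, V_F0 = obs1$V_F_obs)
    lower <- c(lower, 0.25 * ic0)
    upper <- c(upper, 4 * ic0)
  }

  n_fail <- 0L
  resid_fun <- function(th) {
    names(th) <- names(lower)
    dec <- stage2_decode(th, fixed, obs1, cfg)
    tr <- try(integrate_model(dec$state0, dec$params, grid, model = "base",
                              rtol = cfg$rtol, atol = cfg$atol), silent = TRUE)
    if (inherits(tr, "try-error")) {
      n_fail <<- n_fail + 1L
      return(rep(1e6, length(blocks) * nrow(obs)))
    }
    unlist(lapply(seq_along(blocks), function(i) {
      b <- blocks[i]
      (tr[[b]] - obs[[paste0(b, "_obs")]]) / norms[i]
    }))
  }

  starts <- stage2_starts(obs, fixed, lower, upper, cfg)
  best <- NULL; best_idx <- NA_integer_
  for (i in seq_along(starts)) {
    ans <- try(suppressWarnings(minpack.lm::nls.lm(
      par = starts[[i]], lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = cfg$maxiter,
                                           ftol = 1e-12, ptol = 1e-12))),
      silent = TRUE)
    if (inherits(ans, "try-error")) next
    if (is.null(best) || ans$deviance < best$deviance) {
      best <- ans; best_idx <- i
    }
  }
  if (is.null(best)) stop("all stage-2 optimizer starts failed")

  th <- best$par
  names(th) <- names(lower)
  dec <- stage2_decode(th, fixed, obs1, cfg)
  tr <- integrate_model(dec$state0, dec$params, grid, model = "base",
                        rtol = cfg$rtol, atol = cfg$atol)
  rmse <- vapply(c("S", "V_M", "V_F"), function(b)
    sqrt(mean((tr[[b]] - obs[[paste0(b, "_obs")]])^2)), numeric(1))
  structure(list(
    params = dec$params, state0 = dec$state0, t0 = t0,
    rmse = rmse, objective = best$deviance,
    fitted_trajectory = tr,
    diagnostics = list(start_used = best_idx,
                       n_starts = length(starts),
                       iterations = best$niter,
                       converged = best$info %in% 1:4,
                       objective_trace = best$rsstrace,
                       integration_failures = n_fail,
                       message = best$message),
    series = series,
    aggressor_fit = aggressor_fit,
    config = cfg),
    class = "fit_result")
}

# One data-driven start (quasi-equilibrium victim balance) plus
# Latin-hypercube draws within bounds.
stage2_starts <- function(obs, fixed, lower, upper, cfg) {
  alpha0 <- 0.5
  AS <- mean(obs$A_obs * obs$S_obs)
  heur <- c(r_S = max(fixed$r_A, 1e-3),
            k_S = 1.2 * max(obs$S_obs),
            beta_F = max(alpha0 * mean(obs$V_F_obs) / AS, 1e-9),
            beta_M = max(alpha0 * mean(obs$V_M_obs) / AS, 1e-9),
            alpha_F = alpha0, alpha_M = alpha0)
  th0 <- log(heur)
  if (cfg$optimize_initial_conditions)
    th0 <- c(th0, S0 = obs$S_obs[1], V_M0 = obs$V_M_obs[1],
             V_F0 = obs$V_F_obs[1])
  th0 <- pmin(pmax(th0, lower), upper)
  starts <- list(th0)
  n_extra <- max(0L, cfg$multistart - 1L)
  if (n_extra > 0) {
    set.seed(cfg$seed)
    u <- lhs::randomLHS(n_extra, length(lower))
    for (j in seq_len(n_extra)) {
      starts[[j + 1L]] <- lower + u[j, ] * (upper - lower)
      names(starts[[j + 1L]]) <- names(lower)
    }
  }
  starts
}

#' @export
print.fit_result <- function(x, ...) {
  cat("Two-stage violence model fit (", x$series$config$violence_type,
      ", ", nrow(x$series$fit), " fit years from ", x$t0, ")\n", sep = "")
  print(x$params)
  cat("initial state (millions):\n"); print(signif(unclass(x$state0), 6))
  cat("objective:", format(x$objective, digits = 6),
      "| converged:", x$diagnostics$converged,
      "| start", x$diagnostics$start_used, "of", x$diagnostics$n_starts, "\n")
  if (!is.null(x$holdout)) {
    cat("holdout relative errors:\n"); print(signif(x$holdout$relative_error, 4))
  }
  invisible(x)
}

#' Holdout validation of a fitted model
#'
#' Integrates the fitted model forward through the holdout years (no
#' refitting) and reports the relative error per compartment and the victim
#' RMSE there.
#'
#' @param result A `fit_result`.
#' @param series Optional `scenario_series`; defaults to the one stored in
#'   the fit.
#' @return The `fit_result` with a `holdout` element: `year`,
#'   `relative_error` (matrix, compartments x years), `rmse`.
#' @export
validate_holdout <- function(result, series = result$series) {
  hold <- series$holdout
  if (nrow(hold) == 0) stop("no holdout years in the series")
  grid <- time_grid(result$t0, hold$year)
  tr <- integrate_model(result$state0, result$params, grid, model = "base",
                        rtol = result$config$rtol, atol = result$config$atol)
  comps <- c("A", "S", "V_M", "V_F")
  rel <- sapply(seq_len(nrow(hold)), function(i) {
    o <- c(hold$A_obs[i], hold$S_obs[i], hold$V_M_obs[i], hold$V_F_obs[i])
    m <- as.numeric(tr[i, comps])
    (m - o) / ifelse(o == 0, 1, o)
  })
  rel <- matrix(rel, nrow = 4, dimnames = list(comps, hold$year))
  rmse <- sqrt(mean((as.numeric(tr[, c("V_M", "V_F")]) -
                       c(hold$V_M_obs, hold$V_F_obs))^2))
  result$holdout <- list(year = hold$year, relative_error = rel, rmse = rmse)
  result
}

#' Compare fit quality across violence types
#'
#' Summarizes each fit by the RMSE of its stacked victim residuals with each
#' sex block normalized by the mean of its own observations — the same block
#' scaling the stage-2 objective uses, so male and female series of very
#' different magnitudes contribute comparably — and ranks the fits. The
#' self-inflicted series, where aggressor and victim coincide and so violate
#' the model's compartment separation, is expected to rank worst.
#'
#' @param results Named list of `fit_result` objects fitted under the same
#'   scenario configuration.
#' @return Data frame with `type`, `normalized_rmse`, `rank`, and a
#'   `tie` flag.
#' @export
compare_fit_quality <- function(results) {
  if (is.null(names(results)) || any(names(results) == ""))
    stop("results must be a named list")
  nrmse <- vapply(results, function(r) {
    obs <- r$series$fit
    resid <- with(r, c((fitted_trajectory$V_M - obs$V_M_obs) / mean(obs$V_M_obs),
                       (fitted_trajectory$V_F - obs$V_F_obs) / mean(obs$V_F_obs)))
    sqrt(mean(resid^2))
  }, numeric(1))
  ord <- rank(nrmse, ties.method = "min")
  data.frame(type = names(results), normalized_rmse = nrmse, rank = ord,
             tie = duplicated(nrmse) | duplicated(nrmse, fromLast = TRUE),
             row.names = NULL)
}

#' One-call pipeline: scenario construction, two-stage fit, holdout
#'
#' @param table Incidence table (see [load_incidence()]).
#' @param traj A [population_trajectory].
#' @param scenario A [scenario_config].
#' @param cfg A [fit_config].
#' @return A `fit_result` with holdout metrics attached (when the scenario
#'   has holdout years).
#' @export
fit_violence_model <- function(table, traj, scenario = scenario_config(),
                               cfg = fit_config()) {
  series <- build_scenario(table, traj, scenario)
  ag <- fit_aggressor_logistic(series, cfg)
  res <- fit_full_model(series, ag, cfg)
  if (nrow(series$holdout) > 0) res <- validate_holdout(res)
  res
}
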