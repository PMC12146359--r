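#' Right-hand sides of the violence compartmental models
#'
#' Three nested systems describe the flow of people between aggressor (A),
#' susceptible (S) and gender-segregated victim (V_M, V_F) compartments:
#'
#' * `base_rhs()` — aggressors grow logistically, susceptibles grow
#'   logistically and are victimized by mass action (`beta * A * S`), victims
#'   are removed at rates `alpha_M`, `alpha_F`.
#' * `female_recovery_rhs()` — adds a pathway returning female victims to the
#'   susceptible class at rate `gamma_F`.
#' * `complete_recovery_rhs()` — additionally rehabilitates aggressors into
#'   the susceptible class at rate `delta_A`.
#'
#' With `gamma_F = delta_A = 0` all three coincide exactly.
#'
#' @param state A [state_vec] (or named vector with fields A, S, V_M, V_F),
#'   all components finite and nonnegative.
#' @param params A [model_params] object.
#' @return Named numeric vector of derivatives (millions/year) for
#'   (A, S, V_M, V_F).
#' @export
base_rhs <- function(state, params) {
  check_state(state)
  d <- rhs_terms(state, params, gamma_F = 0, delta_A = 0)
  d
}

#' @rdname base_rhs
#' @export
female_recovery_rhs <- function(state, params) {
  check_state(state)
  rhs_terms(state, params, gamma_F = params[["gamma_F"]], delta_A = 0)
}

#' @rdname base_rhs
#' @export
complete_recovery_rhs <- function(state, params) {
  check_state(state)
  rhs_terms(state, params,
            gamma_F = params[["gamma_F"]], delta_A = params[["delta_A"]])
}

check_state <- function(state) {
  if (!all(state_fields %in% names(state)))
    stop("state requires fields A, S, V_M, V_F")
  s <- state[state_fields]
  if (any(!is.finite(s))) stop("state components must be finite")
  if (any(s < 0)) stop("state components must be nonnegative")
  invisible(state)
}

# Shared flux arithmetic; recovery rates are passed explicitly so each model
# variant activates only its own transfer terms.
rhs_terms <- function(state, params, gamma_F, delta_A) {
  A <- state[["A"]]; S <- state[["S"]]
  V_M <- state[["V_M"]]; V_F <- state[["V_F"]]
  p <- unclass(params)
  inter <- (p[["beta_M"]] + p[["beta_F"]]) * A * S
  c(A   = p[["r_A"]] * A * (1 - A / p[["k_A"]]) - delta_A * A,
    S   = p[["r_S"]] * S * (1 - S / p[["k_S"]]) - inter +
          gamma_F * V_F + delta_A * A,
    V_M = p[["beta_M"]] * A * S - p[["alpha_M"]] * V_M,
    V_F = p[["beta_F"]] * A * S - (p[["alpha_F"]] + gamma_F) * V_F)
}

#' Closed-form logistic solution for the aggressor compartment
#'
#' The aggressor equation is uncoupled from the rest of the system (when
#' `delta_A = 0`), so its trajectory is the standard logistic curve
#' `k_A A0 e^(r_A t) / (k_A + A0 (e^(r_A t) - 1))`. Evaluated in the
#' numerically stable form `k_A / (1 + ((k_A - A0)/A0) e^(-r_A t))`.
#'
#' @param A0 Initial aggressor population (millions), `A0 >= 0`.
#' @param params A [model_params] object (uses `r_A`, `k_A`; requires
#'   `delta_A = 0`).
#' @param t Elapsed time in years since the initial condition (vectorized).
#' @return Aggressor population (millions) at each `t`.
#' @export
aggressor_closed_form <- function(A0, params, t) {
  if (!is.finite(A0) || A0 < 0) stop("A0 must be finite and nonnegative")
  if (params[["delta_A"]] != 0)
    stop("closed form requires delta_A = 0 (uncoupled logistic growth)")
  if (any(t < 0)) stop("t must be nonnegative")
  if (A0 == 0) return(rep(0, length(t)))
  k <- params[["k_A"]]; r <- params[["r_A"]]
  k / (1 + ((k - A0) / A0) * exp(-r * t))
}

#' Integrate a violence model over a time grid
#'
#' Solves the chosen system with an adaptive solver (deSolve's `lsoda`) and
#' returns the state at each grid time. Components that undershoot zero by
#' less than `1e-10` (solver round-off) are clamped to zero; larger negative
#' values abort with an error rather than propagating spurious sign flips
#' through the mass-action terms.
#'
#' @param state0 Initial [state_vec] at `grid$t0`.
#' @param params A [model_params] object.
#' @param grid A [time_grid]; trajectory is reported at `grid$times`.
#' @param model One of `"base"`, `"female"` (female recovery) or
#'   `"complete"` (female + aggressor recovery).
#' @param rtol,atol Relative and absolute solver tolerances.
#' @return A data frame of class `violence_trajectory` with columns
#'   `year, A, S, V_M, V_F` (populations in millions).
#' @export
integrate_model <- function(state0, params, grid,
                            model = c("base", "female", "complete"),
                            rtol = 1e-8, atol = 1e-10) {
  model <- match.arg(model)
  check_state(state0)
  validate_model_params(params)
  gam <- if (model %in% c("female", "complete")) params[["gamma_F"]] else 0
  del <- if (model == "complete") params[["delta_A"]] else 0

  times <- grid$times
  t_int <- unique(c(grid$t0, times))
  if (length(t_int) == 1L) {
    out <- data.frame(year = times, A = state0[["A"]], S = state0[["S"]],
                      V_M = state0[["V_M"]], V_F = state0[["V_F"]])
    class(out) <- c("violence_trajectory", "data.frame")
    return(out)
  }
  ode_fun <- function(t, y, parms) {
    y <- pmax(y, 0)  # shield fluxes from solver round-off undershoot
    list(rhs_terms(y, params, gamma_F = gam, delta_A = del))
  }
  sol <- deSolve::ode(y = unclass(state0)[state_fields], times = t_int,
                      func = ode_fun, parms = NULL,
                      method = "lsoda", rtol = rtol, atol = atol)
  if (attr(sol, "istate")[1] < 0)
    stop("ODE integration failed (solver istate ",
         attr(sol, "istate")[1], "); try looser tolerances")
  sol <- as.data.frame(sol)
  names(sol) <- c("year", state_fields)
  if (any(vapply(sol[state_fields], function(x) any(x < -1e-10), logical(1))))
    stop("integration produced negative populations beyond round-off")
  sol[state_fields] <- lapply(sol[state_fields], pmax, 0)
  out <- sol[match(times, sol$year), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("violence_trajectory", "data.frame")
  out
}

#' @export
plot.violence_trajectory <- function(x, log = "", ...) {
  graphics::matplot(x$year, as.matrix(x[state_fields]), type = "l", lty = 1,
                    col = c("black", "cyan3", "blue", "red"),
                    xlab = "year", ylab = "population (millions)", log = log, ...)
  graphics::legend("topleft", legend = state_fields, lty = 1,
                   col = c("black", "cyan3", "blue", "red"), bty = "n")
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' Columns `year,A,S,V_M,V_F` in millions, 6 significant digits.
#'
#' @param traj A `violence_trajectory`.
#' @param path Output path.
#' @export
write_trajectory_csv <- function(traj, path) {
  out <- traj
  out[state_fields] <- lapply(out[state_fields], signif, digits = 6)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
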