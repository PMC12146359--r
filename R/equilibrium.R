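#' Susceptible steady state of the base model
#'
#' At the nontrivial equilibrium the aggressors sit at their carrying capacity
#' `A* = k_A`, and the susceptible logistic growth balances the victimization
#' drain, giving `S* = k_S (1 - (beta_M + beta_F) k_A / r_S)`, floored at zero
#' when the drain exceeds the growth rate (extinction branch).
#'
#' @param params A [model_params] with `gamma_F = delta_A = 0`.
#' @return Susceptible equilibrium population (millions).
#' @export
susceptible_equilibrium <- function(params) {
  if (params[["gamma_F"]] != 0 || params[["delta_A"]] != 0)
    stop("base-model equilibrium requires gamma_F = delta_A = 0; ",
         "use recovery_equilibrium() for the extended systems")
  if (params[["r_S"]] == 0) stop("degenerate parameters: r_S must be positive")
  drain <- (params[["beta_M"]] + params[["beta_F"]]) * params[["k_A"]]
  max(0, params[["k_S"]] * (1 - drain / params[["r_S"]]))
}

#' Victim saturation levels
#'
#' Long-run victim compartment sizes with aggressors saturated at `k_A` and
#' susceptibles at their equilibrium: inflow `beta k_A S*` balanced against
#' removal, so `V_M* = beta_M k_A S* / alpha_M` and
#' `V_F* = beta_F k_A S* / (alpha_F + gamma_F)`.
#'
#' @param params A [model_params] with `delta_A = 0` (`gamma_F` may be
#'   positive: female recovery deepens the effective removal rate).
#' @return Named vector `c(V_M, V_F)` in millions.
#' @export
victim_equilibria <- function(params) {
  if (params[["delta_A"]] != 0)
    stop("requires delta_A = 0; use recovery_equilibrium() otherwise")
  p_norec <- params
  p_norec[["gamma_F"]] <- 0
  S_star <- susceptible_equilibrium(p_norec)
  inflow_M <- params[["beta_M"]] * params[["k_A"]] * S_star
  inflow_F <- params[["beta_F"]] * params[["k_A"]] * S_star
  if (params[["alpha_M"]] == 0 && inflow_M > 0)
    stop("unbounded equilibrium: alpha_M = 0 with positive male inflow")
  if (params[["alpha_F"]] + params[["gamma_F"]] == 0 && inflow_F > 0)
    stop("unbounded equilibrium: alpha_F + gamma_F = 0 with positive female inflow")
  c(V_M = if (inflow_M == 0) 0 else inflow_M / params[["alpha_M"]],
    V_F = if (inflow_F == 0) 0 else
      inflow_F / (params[["alpha_F"]] + params[["gamma_F"]]))
}

# The susceptible-equilibrium condition with gamma_F > 0, delta_A = 0 stays
# closed-form: the recovered outflow gamma_F V_F* feeds back into S, reducing
# the net drain per susceptible.
susceptible_equilibrium_gamma <- function(params, A_star) {
  p <- unclass(params)
  drain <- (p[["beta_M"]] + p[["beta_F"]]) * A_star
  feedback <- p[["gamma_F"]] * p[["beta_F"]] * A_star /
    (p[["alpha_F"]] + p[["gamma_F"]])
  max(0, p[["k_S"]] * (1 - (drain - feedback) / p[["r_S"]]))
}

#' Equilibrium of the complete recovery model
#'
#' Fixed point of the system with both recovery pathways active. The
#' aggressor equation gives `A* = max(0, k_A (1 - delta_A / r_A))`; the
#' susceptible steady state solves a scalar balance equation (closed form
#' when `delta_A = 0`, bracketed bisection otherwise); victims follow from
#' the inflow/removal balance. The report carries the Jacobian eigenvalues
#' and a residual check of the fixed-point condition.
#'
#' @param params A [model_params]; any nonnegative `gamma_F`, `delta_A`.
#' @param model Which system the equilibrium refers to (affects which
#'   recovery terms are active); defaults to `"complete"`.
#' @return An `equilibrium_report` list: `state` ([state_vec]),
#'   `eigenvalues`, `stable`, `residual` (max-norm of the rhs at the fixed
#'   point) and `converged`.
#' @export
recovery_equilibrium <- function(params, model = c("complete", "female", "base")) {
  model <- match.arg(model)
  p <- unclass(params)
  gam <- if (model %in% c("female", "complete")) p[["gamma_F"]] else 0
  del <- if (model == "complete") p[["delta_A"]] else 0
  if (p[["r_A"]] == 0 && del > 0) {
    A_star <- 0
  } else if (p[["r_A"]] == 0) {
    stop("degenerate parameters: r_A = 0 leaves the aggressor level undefined")
  } else {
    A_star <- max(0, p[["k_A"]] * (1 - del / p[["r_A"]]))
  }

  if (del == 0) {
    S_star <- if (gam == 0) {
      p0 <- params; p0[["gamma_F"]] <- 0; p0[["delta_A"]] <- 0
      if (A_star == 0) p[["k_S"]] else susceptible_equilibrium(p0)
    } else {
      susceptible_equilibrium_gamma(params, A_star)
    }
    converged <- TRUE
  } else {
    # g(S) = rS S (1 - S/kS) - (bM+bF) A* S + gamma_F V_F*(S) + delta_A A*
    # with V_F*(S) = bF A* S / (aF + gamma_F)
    g <- function(S) {
      VFs <- if (p[["alpha_F"]] + gam > 0)
        p[["beta_F"]] * A_star * S / (p[["alpha_F"]] + gam) else 0
      p[["r_S"]] * S * (1 - S / p[["k_S"]]) -
        (p[["beta_M"]] + p[["beta_F"]]) * A_star * S +
        gam * VFs + del * A_star
    }
    grid <- seq(0, 2 * p[["k_S"]], length.out = 1001)
    vals <- vapply(grid, g, numeric(1))
    sgn <- sign(vals)
    idx <- which(sgn[-1] * sgn[-length(sgn)] < 0)
    if (length(idx) == 0) {
      zero_at <- which(vals == 0)
      if (length(zero_at)) {
        S_star <- grid[zero_at[length(zero_at)]]
        converged <- TRUE
      } else {
        return(equilibrium_report(params, gam, del,
                                  state = c(A = A_star, S = NA_real_,
                                            V_M = NA_real_, V_F = NA_real_),
                                  converged = FALSE,
                                  message = "no sign change in [0, 2 k_S]"))
      }
    } else {
      i <- idx[length(idx)]  # outermost root: the attracting positive branch
      root <- stats::uniroot(g, lower = grid[i], upper = grid[i + 1],
                             tol = 1e-12)
      S_star <- root$root
      converged <- TRUE
    }
  }

  V_M_star <- if (p[["alpha_M"]] > 0)
    p[["beta_M"]] * A_star * S_star / p[["alpha_M"]] else 0
  V_F_star <- if (p[["alpha_F"]] + gam > 0)
    p[["beta_F"]] * A_star * S_star / (p[["alpha_F"]] + gam) else 0
  equilibrium_report(params, gam, del,
                     state = c(A = A_star, S = S_star,
                               V_M = V_M_star, V_F = V_F_star),
                     converged = converged)
}

equilibrium_report <- function(params, gam, del, state, converged,
                               message = NULL) {
  if (converged && all(is.finite(state))) {
    res <- max(abs(rhs_terms(state, params, gamma_F = gam, delta_A = del)))
    J <- model_jacobian(state, params, gamma_F = gam, delta_A = del)
    ev <- eigen(J, only.values = TRUE)$values
    stable <- all(Re(ev) < 0)
  } else {
    res <- NA_real_; ev <- rep(NA_complex_, 4); stable <- NA
  }
  structure(list(state = state, eigenvalues = ev, stable = stable,
                 residual = res, converged = converged, message = message),
            class = "equilibrium_report")
}

#' @export
print.equilibrium_report <- function(x, ...) {
  cat("Equilibrium (millions):\n")
  print(signif(x$state, 8))
  cat("residual (max-norm of rhs):", format(x$residual, digits = 3), "\n")
  cat("eigenvalue real parts:",
      paste(signif(Re(x$eigenvalues), 4), collapse = ", "), "\n")
  cat("locally stable:", x$stable, "\n")
  invisible(x)
}

# Analytic Jacobian of the complete system; gamma_F/delta_A passed explicitly
# so the same matrix serves all three variants.
model_jacobian <- function(state, params, gamma_F, delta_A) {
  A <- state[["A"]]; S <- state[["S"]]
  p <- unclass(params)
  B <- p[["beta_M"]] + p[["beta_F"]]
  matrix(c(
    p[["r_A"]] * (1 - 2 * A / p[["k_A"]]) - delta_A, 0, 0, 0,
    -B * S + delta_A,
    p[["r_S"]] * (1 - 2 * S / p[["k_S"]]) - B * A, 0, gamma_F,
    p[["beta_M"]] * S, p[["beta_M"]] * A, -p[["alpha_M"]], 0,
    p[["beta_F"]] * S, p[["beta_F"]] * A, 0, -(p[["alpha_F"]] + gamma_F)
  ), nrow = 4, byrow = TRUE,
  dimnames = list(state_fields, state_fields))
}

#' Local stability of a fixed point
#'
#' Eigenvalues of the analytic 4x4 Jacobian at a fixed point of the chosen
#' model variant. Errors if the supplied state is not a fixed point
#' (rhs max-norm must be below `1e-8`).
#'
#' @param params A [model_params].
#' @param state_star Candidate fixed point ([state_vec] or named vector).
#' @param model Model variant, as in [integrate_model()].
#' @return List with `eigenvalues` (complex) and `stable` (all real parts
#'   negative).
#' @export
stability <- function(params, state_star, model = c("base", "female", "complete")) {
  model <- match.arg(model)
  gam <- if (model %in% c("female", "complete")) params[["gamma_F"]] else 0
  del <- if (model == "complete") params[["delta_A"]] else 0
  res <- max(abs(rhs_terms(state_star, params, gamma_F = gam, delta_A = del)))
  if (res >= 1e-8)
    stop("state_star is not a fixed point (rhs max-norm ", format(res), ")")
  J <- model_jacobian(state_star, params, gamma_F = gam, delta_A = del)
  ev <- eigen(J, only.values = TRUE)$values
  list(eigenvalues = ev, stable = all(Re(ev) < 0))
}
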