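# Lightweight fit-like object: projections only need params, state0 and t0.
proj_fit <- function(params = fam_params(), state0 = synth_state0()) {
  list(params = params, state0 = state0, t0 = 2010)
}

test_that("base projection reaches saturation and handles edge horizons", {
  p <- fam_params()
  pr <- project(p, synth_state0(), 2200)
  V <- victim_equilibria(p)
  expect_lt(abs(pr$terminal[["V_F"]] - V[["V_F"]]) / V[["V_F"]], 1e-3)
  expect_lt(abs(pr$terminal[["V_M"]] - V[["V_M"]]) / V[["V_M"]], 1e-3)

  # starting at equilibrium the gap stays flat
  st <- state_vec(p[["k_A"]], susceptible_equilibrium(p), V[["V_M"]], V[["V_F"]])
  flat <- project(p, st, 2050)
  expect_lt(diff(range(flat$gap)), 1e-6)

  # zero-length horizon returns the initial state
  pr0 <- project(p, synth_state0(), 2010)
  expect_equal(unname(pr0$terminal), unname(unclass(synth_state0())))
  expect_error(project(p, synth_state0(), 2005), "horizon")
})

test_that("the recovery switch hands the state over exactly and reduces cleanly", {
  fit <- proj_fit()
  base <- project(fit$params, fit$state0, 2034)
  off <- project_with_recovery(fit, recovery_schedule(2020, 0, 0), 2034)
  yrs <- intersect(base$trajectory$year, off$trajectory$year)
  ib <- match(yrs, base$trajectory$year); io <- match(yrs, off$trajectory$year)
  expect_equal(off$trajectory$V_F[io], base$trajectory$V_F[ib], tolerance = 1e-8)
  expect_equal(off$trajectory$S[io], base$trajectory$S[ib], tolerance = 1e-8)

  # continuity: no jump at the switch (the switch year appears once, state
  # continuous across it)
  on <- project_with_recovery(fit, recovery_schedule(2023, 0.5, 0.1), 2034)
  expect_equal(sum(on$trajectory$year == 2023), 1)
  tr <- on$trajectory
  i <- which(tr$year == 2023)
  # derivative changes, state does not: compare to a pre-switch-only run
  pre <- project(fit$params, fit$state0, 2023)
  expect_equal(unname(tr[i, c("A", "S", "V_M", "V_F")]),
               unname(pre$trajectory[nrow(pre$trajectory),
                                     c("A", "S", "V_M", "V_F")]),
               tolerance = 1e-8)

  # strong female recovery: V_F drops immediately after the switch
  fast <- project_with_recovery(fit, recovery_schedule(2020, 0.5), 2034)
  j <- which(fast$trajectory$year == 2020)
  expect_lt(fast$trajectory$V_F[j + 1], fast$trajectory$V_F[j])

  expect_error(project_with_recovery(fit, recovery_schedule(2005, 0.1), 2034),
               "recovery_year")
})

test_that("both recovery channels pull the system toward the extended equilibrium", {
  fit <- proj_fit()
  sch <- recovery_schedule(2023, gamma_F = 0.1, delta_A = 0.3)
  rp <- project_with_recovery(fit, sch, horizon = 2500)
  p <- fit$params; p[["gamma_F"]] <- 0.1; p[["delta_A"]] <- 0.3
  eq <- recovery_equilibrium(p)
  expect_lt(max(abs(rp$terminal - eq$state)), 1e-5)
  # with delta_A = 0.3 > r_A the aggressor class empties and victims vanish
  expect_lt(rp$terminal[["V_F"]], 1e-6)

  # male victims respond only to aggressor recovery
  g_only <- project_with_recovery(fit, recovery_schedule(2023, 0.3, 0), 2034)
  both <- project_with_recovery(fit, recovery_schedule(2023, 0.3, 0.05), 2034)
  expect_lt(both$terminal[["V_M"]], g_only$terminal[["V_M"]])
})

test_that("sweeps are deterministic grids with monotone terminal female victims", {
  fit <- proj_fit()
  sw <- sweep_recovery(fit, gammas = c(0, 0.1, 0.3, 1), deltas = c(0, 0.02),
                       recovery_years = 2023, horizon = 2034)
  expect_equal(nrow(sw$summary), 8)
  for (d in unique(sw$summary$delta_A)) {
    sub <- sw$summary[sw$summary$delta_A == d, ]
    expect_true(all(diff(sub$terminal_V_F[order(sub$gamma_F)]) <= 0))
  }
  for (g in unique(sw$summary$gamma_F)) {
    sub <- sw$summary[sw$summary$gamma_F == g, ]
    expect_true(all(diff(sub$terminal_V_F[order(sub$delta_A)]) <= 0))
  }
  # degenerate single-cell grid equals the base projection
  sw0 <- sweep_recovery(fit, 0, 0, 2020, horizon = 2034)
  base <- project(fit$params, fit$state0, 2034)
  expect_equal(sw0$summary$terminal_V_F, base$terminal[["V_F"]],
               tolerance = 1e-8)
  expect_error(sweep_recovery(fit, numeric(0), 0, 2020), "nonempty")
})

test_that("equality thresholds: symmetric models need none, real asymmetry a lot", {
  # symmetric sexes: victims already equal asymptotically
  p_sym <- fam_params(beta_M = fam_params()[["beta_F"]],
                      alpha_M = fam_params()[["alpha_F"]])
  s0 <- synth_state0(); s0[["V_M"]] <- s0[["V_F"]]
  et_sym <- equality_threshold(list(params = p_sym, state0 = s0, t0 = 2010),
                               recovery_year = 2023)
  expect_equal(et_sym$asymptotic_gamma, 0)
  expect_equal(et_sym$multiplier, 0)

  # asymmetric case: closed-form threshold checked by long-run integration
  fit <- proj_fit()
  et <- equality_threshold(fit, recovery_year = 2023)
  g_star <- et$asymptotic_gamma
  expect_equal(g_star,
               fit$params[["alpha_M"]] * fit$params[["beta_F"]] /
                 fit$params[["beta_M"]] - fit$params[["alpha_F"]])
  ratio_at <- function(g) {
    p <- fam_params(gamma_F = g)
    tr <- integrate_model(synth_state0(), p, time_grid(0, 3000),
                          model = "female")
    tr$V_F / tr$V_M
  }
  expect_gt(ratio_at(0.9 * g_star), 1)
  expect_lt(ratio_at(1.1 * g_star), 1)

  expect_true(et$achievable)
  expect_gt(et$multiplier, 10)  # an order of magnitude above the death rate
})
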