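test_that("base derivatives match hand arithmetic and structural limits", {
  p <- fam_params()

  # origin is a fixed point; aggressors at capacity stall
  expect_equal(unname(base_rhs(state_vec(0, 0, 0, 0), p)), rep(0, 4))
  d <- base_rhs(state_vec(p[["k_A"]], 12, 0.3, 0.2), p)
  expect_equal(d[["A"]], 0)

  # no interaction: victims decay exponentially
  p0 <- fam_params(beta_F = 0, beta_M = 0)
  d0 <- base_rhs(state_vec(10, 20, 0.4, 0.7), p0)
  expect_equal(d0[["V_M"]], -p0[["alpha_M"]] * 0.4)
  expect_equal(d0[["V_F"]], -p0[["alpha_F"]] * 0.7)

  # frozen values from an arbitrary-precision evaluation of the four
  # algebraic expressions at the near-saturation state
  d2 <- base_rhs(state_vec(30.325876, 60.65, 0.009988, 0.145262), p)
  expect_equal(d2[["A"]], 0)
  # dS is a near-cancellation of two O(0.05) fluxes; double precision keeps
  # about 10 digits of the difference
  expect_equal(d2[["S"]], 5.2550018175061366e-7, tolerance = 1e-9)
  expect_equal(d2[["V_M"]], -9.162746980e-5, tolerance = 1e-12)
  expect_equal(d2[["V_F"]], 6.0627987520e-4, tolerance = 1e-12)

  expect_error(base_rhs(c(A = -1, S = 1, V_M = 0, V_F = 0), p), "nonnegative")
})

test_that("recovery variants add exactly their transfer terms", {
  p <- fam_params(gamma_F = 0.5)
  st <- c(A = 25, S = 55, V_M = 0.008, V_F = 0.09)
  d <- female_recovery_rhs(st, p)
  # frozen decimal-arithmetic values
  expect_equal(d[["S"]], 0.32903663614056971, tolerance = 1e-12)
  expect_equal(d[["V_F"]], -0.03803186, tolerance = 1e-12)

  # gamma terms cancel in the S + V_F column sum for any state
  for (i in 1:20) {
    s <- random_state()
    db <- base_rhs(s, p)
    df <- female_recovery_rhs(s, p)
    expect_equal(df[["S"]] + df[["V_F"]], db[["S"]] + db[["V_F"]],
                 tolerance = 1e-12)
    pc <- p; pc[["delta_A"]] <- 0.2
    dc <- complete_recovery_rhs(s, pc)
    expect_equal(dc[["A"]] + dc[["S"]] + dc[["V_F"]],
                 db[["A"]] + db[["S"]] + db[["V_F"]], tolerance = 1e-12)
  }

  # reduction chain: with both recovery rates zero all three coincide
  p0 <- fam_params()
  for (i in 1:100) {
    s <- random_state()
    expect_identical(base_rhs(s, p0), female_recovery_rhs(s, p0))
    expect_identical(base_rhs(s, p0), complete_recovery_rhs(s, p0))
  }
})

test_that("strong aggressor rehabilitation drives dA/dt negative everywhere", {
  p <- fam_params(delta_A = fam_params()[["r_A"]] * 1.01)
  for (A in seq(0.01, p[["k_A"]], length.out = 25)) {
    d <- complete_recovery_rhs(state_vec(A, 10, 0.1, 0.1), p)
    expect_lt(d[["A"]], 0)
  }
})

test_that("aggressor closed form is the logistic solution", {
  p <- fam_params()
  # fixed point and monotone saturation
  expect_equal(aggressor_closed_form(p[["k_A"]], p, c(0, 5, 500)),
               rep(p[["k_A"]], 3))
  tt <- seq(0, 10 / p[["r_A"]], length.out = 50)
  a <- aggressor_closed_form(5, p, tt)
  expect_true(all(diff(a) > 0))
  expect_equal(a[length(a)], p[["k_A"]], tolerance = 1e-3)
  expect_equal(aggressor_closed_form(0, p, 1:3), rep(0, 3))
  expect_error(aggressor_closed_form(-1, p, 1), "nonnegative")

  # numerical integration agrees to 1e-8 relative over 2010-2034
  g <- time_grid(2010, 2010:2034)
  tr <- integrate_model(synth_state0(), p, g)
  cf <- aggressor_closed_form(synth_state0()[["A"]], p, g$times - 2010)
  expect_lt(max(abs(tr$A - cf) / cf), 1e-8)
})

test_that("integration preserves fixed points, nonnegativity and converges in tolerance", {
  p <- fam_params()
  Vst <- victim_equilibria(p)
  st <- state_vec(p[["k_A"]], susceptible_equilibrium(p),
                  Vst[["V_M"]], Vst[["V_F"]])
  tr <- integrate_model(st, p, time_grid(0, c(1, 10, 50)))
  for (f in c("A", "S", "V_M", "V_F"))
    expect_equal(tr[[f]], rep(st[[f]], 3), tolerance = 1e-7)

  # forward invariance over random draws
  set.seed(202)
  for (i in 1:100) {
    tr <- integrate_model(random_state(), random_params(),
                          time_grid(0, c(2, 5, 20)))
    expect_true(all(as.matrix(tr[c("A", "S", "V_M", "V_F")]) >= -1e-10))
  }

  # aggressor monotonicity from below and above capacity
  lo <- integrate_model(state_vec(1, 10, 0, 0), p, time_grid(0, seq(1, 100, 5)))
  hi <- integrate_model(state_vec(50, 10, 0, 0), p, time_grid(0, seq(1, 100, 5)))
  expect_true(all(diff(lo$A) > 0))
  expect_true(all(diff(hi$A) < 0))

  # self-convergence: halving tolerances moves the result by less than 10x rtol
  s0 <- synth_state0()
  t1 <- integrate_model(s0, p, time_grid(2010, 2034), rtol = 1e-8, atol = 1e-10)
  t2 <- integrate_model(s0, p, time_grid(2010, 2034), rtol = 5e-9, atol = 5e-11)
  expect_lt(max(abs(unlist(t1[-1]) - unlist(t2[-1])) / unlist(t2[-1])), 1e-7)
})

test_that("trajectory CSV round-trips through the documented format", {
  p <- fam_params()
  tr <- integrate_model(synth_state0(), p, time_grid(2010, 2010:2015))
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  back <- read.csv(path)
  expect_identical(names(back), c("year", "A", "S", "V_M", "V_F"))
  expect_equal(back$V_F, signif(tr$V_F, 6))
})

test_that("parameter files load from YAML and JSON", {
  p <- fam_params()
  yml <- tempfile(fileext = ".yaml")
  writeLines(yaml::as.yaml(as.list(unclass(p))), yml)
  expect_equal(unclass(read_model_params(yml)), unclass(p))
  js <- tempfile(fileext = ".json")
  jsonlite::write_json(as.list(unclass(p)[1:8]), js, auto_unbox = TRUE,
                       digits = NA)
  q <- read_model_params(js)
  expect_equal(q[["beta_F"]], p[["beta_F"]])
  expect_equal(q[["gamma_F"]], 0)
})
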