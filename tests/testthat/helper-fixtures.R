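# Shared fixtures: parameter draws, synthetic anchors, and lazily cached
# real-data fits (the three violence types share one scenario config, so the
# asymmetry and fit-quality tests reuse the same fits).

fam_params <- function(...) {
  p <- family_violence_params()
  extra <- list(...)
  for (nm in names(extra)) p[[nm]] <- extra[[nm]]
  p
}

# A plausible national-population anchor set for tests (synthetic; spans the
# 110-130 M range of the study period).
test_anchors <- function() {
  population_trajectory(data.frame(year = c(2010, 2015, 2020),
                                   millions = c(112.3, 119.9, 126.0)))
}

# Initial state under the 20/40 scenario at 2010 for synthetic generation.
synth_state0 <- function(pop2010 = 112.336538) {
  state_vec(A = 0.2 * pop2010, S = 0.4 * pop2010,
            V_M = 0.002395, V_F = 0.016240)
}

random_params <- function() {
  model_params(r_A = runif(1, 0.01, 0.5), k_A = runif(1, 5, 60),
               r_S = runif(1, 0.01, 0.5), k_S = runif(1, 20, 120),
               beta_F = 10^runif(1, -6, -4), beta_M = 10^runif(1, -7, -5),
               alpha_F = runif(1, 0.05, 1), alpha_M = runif(1, 0.05, 1),
               gamma_F = 0, delta_A = 0)
}

random_state <- function() {
  state_vec(A = runif(1, 0, 40), S = runif(1, 0, 100),
            V_M = runif(1, 0, 0.5), V_F = runif(1, 0, 0.5))
}

# Real-data fits are expensive; compute each violence type at most once per
# test run.
.fit_cache <- new.env(parent = emptyenv())
real_fit <- function(type) {
  if (is.null(.fit_cache[[type]])) {
    .fit_cache[[type]] <- fit_violence_model(
      load_incidence(), test_anchors(),
      scenario_config(violence_type = type),
      fit_config(multistart = 8, seed = 42))
  }
  .fit_cache[[type]]
}
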