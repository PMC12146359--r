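#' Published point estimates for the Mexican violence series
#'
#' Parameter values estimated from the 2010-2022 medical-attention counts
#' under the scenario in which aggressors are 20% and susceptibles 40% of the
#' national population. `family_violence_params()` is the gender-based
#' family-violence fit (female interaction rate an order of magnitude above
#' the male one); `nonfamily_violence_params()` is the non-family fit, where
#' the asymmetry reverses. Note the interaction rates are reported to few
#' significant figures, so equilibria computed from them land within a couple
#' of percent — not exactly — on the saturation levels quoted alongside them.
#'
#' @return A [model_params] object (`gamma_F = delta_A = 0`).
#' @export
family_violence_params <- function() {
  model_params(r_A = 0.054631, k_A = 30.325876,
               r_S = 0.054604, k_S = 61.712497,
               beta_F = 0.000028, beta_M = 0.000003,
               alpha_F = 0.350354, alpha_M = 0.561616)
}

#' @rdname family_violence_params
#' @export
nonfamily_violence_params <- function() {
  model_params(r_A = 0.054622, k_A = 30.327267,
               r_S = 0.054602, k_S = 61.510064,
               beta_F = 0.000002, beta_M = 0.000023,
               alpha_F = 0.111478, alpha_M = 0.927221)
}
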