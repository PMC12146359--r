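#' Model parameters for the gender-segregated violence system
#'
#' Bundles the eight rates and capacities of the base model together with the
#' two intervention (recovery) rates. All populations are measured in millions
#' of people and all rates in 1/year, so the interaction rates `beta_F` and
#' `beta_M` carry units of 1/(million x year).
#'
#' @param r_A Aggressor logistic growth rate (1/year).
#' @param k_A Aggressor carrying capacity (millions).
#' @param r_S Susceptible logistic growth rate (1/year).
#' @param k_S Susceptible carrying capacity (millions).
#' @param beta_F Female victimization interaction rate (1/(million x year)).
#' @param beta_M Male victimization interaction rate (1/(million x year)).
#' @param alpha_F Female victim removal (death) rate (1/year).
#' @param alpha_M Male victim removal (death) rate (1/year).
#' @param gamma_F Female victim recovery rate (1/year). Zero disables the
#'   female-recovery pathway, reducing the extended models to the base model.
#' @param delta_A Aggressor recovery rate (1/year). Zero disables aggressor
#'   rehabilitation.
#'
#' @return An object of class `model_params`: a named numeric vector with the
#'   ten fields above.
#' @examples
#' p <- model_params(r_A = 0.05, k_A = 30, r_S = 0.05, k_S = 60,
#'                   beta_F = 3e-5, beta_M = 3e-6,
#'                   alpha_F = 0.35, alpha_M = 0.56)
#' @export
model_params <- function(r_A, k_A, r_S, k_S, beta_F, beta_M,
                         alpha_F, alpha_M, gamma_F = 0, delta_A = 0) {
  p <- c(r_A = unname(r_A), k_A = unname(k_A), r_S = unname(r_S),
         k_S = unname(k_S), beta_F = unname(beta_F), beta_M = unname(beta_M),
         alpha_F = unname(alpha_F), alpha_M = unname(alpha_M),
         gamma_F = unname(gamma_F), delta_A = unname(delta_A))
  validate_model_params(p)
  class(p) <- c("model_params", "numeric")
  p
}

param_fields <- c("r_A", "k_A", "r_S", "k_S", "beta_F", "beta_M",
                  "alpha_F", "alpha_M", "gamma_F", "delta_A")

validate_model_params <- function(p) {
  if (!all(param_fields %in% names(p)))
    stop("model_params requires fields: ", paste(param_fields, collapse = ", "))
  v <- unclass(p)[param_fields]
  if (any(!is.finite(v))) stop("model parameters must be finite")
  if (any(v < 0)) stop("model parameters must be nonnegative")
  invisible(p)
}

#' @export
print.model_params <- function(x, ...) {
  cat("Gender-segregated violence model parameters (millions, 1/year):\n")
  print(signif(unclass(x), 6))
  invisible(x)
}

#' @rdname model_params
#' @param x A list or named vector carrying the ten parameter fields.
#' @export
as_model_params <- function(x) {
  x <- unlist(x)
  miss <- setdiff(c("r_A", "k_A", "r_S", "k_S", "beta_F", "beta_M",
                    "alpha_F", "alpha_M"), names(x))
  if (length(miss)) stop("missing parameter fields: ", paste(miss, collapse = ", "))
  if (!"gamma_F" %in% names(x)) x <- c(x, gamma_F = 0)
  if (!"delta_A" %in% names(x)) x <- c(x, delta_A = 0)
  do.call(model_params, as.list(x[param_fields]))
}

#' Read model parameters from a flat YAML or JSON file
#'
#' The file must contain the ten parameter names as top-level keys
#' (`gamma_F` and `delta_A` may be omitted and default to zero).
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A [model_params] object.
#' @export
read_model_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    stop("unsupported parameter file extension: ", ext)
  )
  as_model_params(raw)
}

#' System state at one time point
#'
#' @param A Aggressors (millions).
#' @param S Susceptibles (millions).
#' @param V_M Male victims (millions).
#' @param V_F Female victims (millions).
#' @return Named numeric vector of class `state_vec`.
#' @export
state_vec <- function(A, S, V_M, V_F) {
  s <- c(A = unname(A), S = unname(S), V_M = unname(V_M), V_F = unname(V_F))
  if (any(!is.finite(s))) stop("state components must be finite")
  if (any(s < 0)) stop("state components must be nonnegative")
  class(s) <- c("state_vec", "numeric")
  s
}

state_fields <- c("A", "S", "V_M", "V_F")

#' Evaluation grid for trajectory integration
#'
#' Times are calendar years; `times` must start at or after `t0` and be
#' strictly increasing.
#'
#' @param t0 Start of the integration (calendar year, may be fractional).
#' @param times Strictly increasing evaluation times (calendar years).
#' @return A list of class `time_grid`.
#' @export
time_grid <- function(t0, times) {
  if (length(times) < 1L) stop("times must be nonempty")
  if (times[1] < t0) stop("times must start at or after t0")
  if (length(times) > 1L && any(diff(times) <= 0))
    stop("times must be strictly increasing")
  structure(list(t0 = t0, times = as.numeric(times)), class = "time_grid")
}
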