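#' Scenario configuration for building fitting targets
#'
#' The aggressor and susceptible compartments are unobserved; scenarios posit
#' them as fixed percentages of the national population (e.g. aggressors 20%,
#' susceptibles 40%), applied to the interpolated population of each
#' observation year. Victim targets come from the incidence counts converted
#' to millions.
#'
#' @param pct_aggressor Fraction of the total population taken as aggressors
#'   (in (0, 1)).
#' @param pct_susceptible Fraction taken as susceptible (in (0, 1)).
#' @param violence_type One of `"family"`, `"non_family"`, `"self_inflicted"`.
#' @param fit_years Years used for fitting (default 2010-2022).
#' @param holdout_years Years reserved for validation (default 2023).
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(pct_aggressor = 0.20, pct_susceptible = 0.40,
                            violence_type = "family",
                            fit_years = 2010:2022, holdout_years = 2023) {
  if (pct_aggressor <= 0 || pct_aggressor >= 1 ||
      pct_susceptible <= 0 || pct_susceptible >= 1)
    stop("scenario percentages must lie strictly between 0 and 1")
  violence_type <- match.arg(violence_type, incidence_types)
  if (length(intersect(fit_years, holdout_years)))
    stop("fit and holdout years must be disjoint")
  structure(list(pct_aggressor = pct_aggressor,
                 pct_susceptible = pct_susceptible,
                 violence_type = violence_type,
                 fit_years = sort(fit_years),
                 holdout_years = sort(holdout_years)),
            class = "scenario_config")
}

#' Build the observed series a fit is run against
#'
#' For each fit and holdout year: `A_obs = pct_aggressor x population(year)`,
#' `S_obs = pct_susceptible x population(year)` (millions), and the victim
#' series are the incidence counts of the configured violence type divided
#' by 1e6.
#'
#' @param table Incidence data frame (see [load_incidence()]).
#' @param traj A [population_trajectory].
#' @param cfg A [scenario_config].
#' @return A list of class `scenario_series` with data frames `fit` and
#'   `holdout`, each with columns `year, A_obs, S_obs, V_M_obs, V_F_obs`.
#' @export
build_scenario <- function(table, traj, cfg) {
  table <- validate_incidence(table)
  sub <- table[table$violence_type == cfg$violence_type, ]
  one <- function(years) {
    if (length(years) == 0)
      return(data.frame(year = numeric(0), A_obs = numeric(0),
                        S_obs = numeric(0), V_M_obs = numeric(0),
                        V_F_obs = numeric(0)))
    missing_years <- setdiff(years, sub$year)
    if (length(missing_years))
      stop("incidence table lacks years: ", paste(missing_years, collapse = ", "))
    pop <- population_at(traj, years)
    vf <- sub$count[match(paste(years, "F"), paste(sub$year, sub$sex))]
    vm <- sub$count[match(paste(years, "M"), paste(sub$year, sub$sex))]
    data.frame(year = years,
               A_obs = cfg$pct_aggressor * pop,
               S_obs = cfg$pct_susceptible * pop,
               V_M_obs = vm / 1e6,
               V_F_obs = vf / 1e6)
  }
  structure(list(fit = one(cfg$fit_years), holdout = one(cfg$holdout_years),
                 config = cfg),
            class = "scenario_series")
}
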