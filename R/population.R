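#' Piecewise-linear national population trajectory
#'
#' The aggressor and susceptible fitting targets are built as fixed
#' percentages of the national population, which is supplied as sparse
#' (year, millions) anchors — typically census years — and interpolated
#' linearly. Linear extrapolation beyond the anchor range is allowed (and
#' needed for projection years) within a guarded window.
#'
#' @param anchors A data frame or two-column matrix with columns
#'   `year` and `millions` (strictly increasing years, positive populations),
#'   or a list of `list(year=, millions=)` entries as read from a config file.
#' @return An object of class `population_trajectory`.
#' @export
population_trajectory <- function(anchors) {
  if (is.list(anchors) && !is.data.frame(anchors) &&
      all(vapply(anchors, is.list, logical(1)))) {
    anchors <- data.frame(
      year = vapply(anchors, function(a) as.numeric(a$year), numeric(1)),
      millions = vapply(anchors, function(a) as.numeric(a$millions), numeric(1)))
  }
  anchors <- as.data.frame(anchors)
  if (nrow(anchors) == 0) stop("configuration error: no population anchors")
  if (!all(c("year", "millions") %in% names(anchors)))
    stop("anchors need columns 'year' and 'millions'")
  if (nrow(anchors) > 1 && any(diff(anchors$year) <= 0))
    stop("anchor years must be strictly increasing")
  if (any(anchors$millions <= 0)) stop("anchor populations must be positive")
  structure(list(anchors = anchors), class = "population_trajectory")
}

#' Evaluate a population trajectory
#'
#' Piecewise-linear interpolation between anchors, exact at anchors, with
#' linear extrapolation up to 5 years before the first anchor and 15 years
#' after the last.
#'
#' @param traj A [population_trajectory].
#' @param year Calendar year(s), possibly fractional.
#' @return Population in millions at each `year`.
#' @export
population_at <- function(traj, year) {
  a <- traj$anchors
  if (any(year < min(a$year) - 5 | year > max(a$year) + 15))
    stop("year outside the supported extrapolation window [first anchor - 5, ",
         "last anchor + 15]")
  if (nrow(a) == 1) return(rep(a$millions, length(year)))
  # linear extrapolation using the terminal segment slopes
  lo_slope <- (a$millions[2] - a$millions[1]) / (a$year[2] - a$year[1])
  n <- nrow(a)
  hi_slope <- (a$millions[n] - a$millions[n - 1]) / (a$year[n] - a$year[n - 1])
  out <- stats::approx(a$year, a$millions, xout = pmin(pmax(year, a$year[1]),
                                                       a$year[n]))$y
  below <- year < a$year[1]; above <- year > a$year[n]
  out[below] <- a$millions[1] + lo_slope * (year[below] - a$year[1])
  out[above] <- a$millions[n] + hi_slope * (year[above] - a$year[n])
  out
}

#' Read population anchors from a YAML or JSON config
#'
#' Expects a top-level key `population_anchors`: a list of `{year, millions}`
#' entries (or the list itself at top level).
#'
#' @param path Config file path.
#' @return A [population_trajectory].
#' @export
read_population_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml  = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = FALSE),
    stop("unsupported config extension: ", ext))
  if (!is.null(raw$population_anchors)) raw <- raw$population_anchors
  population_trajectory(raw)
}
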