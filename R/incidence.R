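#' Annual counts of people treated in Mexican medical units for
#' violence-related injuries, 2010-2023
#'
#' Gender-segregated annual counts of individuals who required medical
#' attention in Mexico, classified by the intentionality of the injury:
#' family violence, non-family violence, or self-inflicted violence
#' (INEGI/SIESVIM surveillance series). These counts are the fitting targets
#' for the victim compartments; family-violence counts show the one-to-two
#' order-of-magnitude excess of female over male victims that motivates the
#' gender-segregated model.
#'
#' @return A data frame with 84 rows and columns `year` (2010-2023),
#'   `violence_type` (`family`, `non_family`, `self_inflicted`), `sex`
#'   (`F`/`M`) and `count` (persons).
#' @export
incidence_fixture <- function() {
  years <- 2010:2023
  # columns: family F, family M, non-family F, non-family M, self F, self M
  counts <- matrix(c(
     16240, 2395,  3703, 17850, 1395, 1449,
     22765, 2983,  4790, 21775, 1582, 1410,
     33177, 3491,  5428, 22299, 1505, 1501,
     44683, 4686,  7763, 28114, 1837, 2134,
     62434, 5902,  9302, 30034, 2158, 1930,
     76934, 7139,  9976, 29963, 2224, 2271,
    101178, 8458, 11453, 32612, 2886, 2721,
     96651, 6695, 10818, 28654, 2497, 2210,
     96700, 6018, 12038, 27731, 2635, 2440,
    110210, 6538, 13541, 28410, 2974, 2642,
     65242, 4702, 10432, 23403, 2271, 2191,
     86284, 6040, 15286, 33190, 4264, 3487,
     87591, 6782, 17275, 34268, 5879, 4113,
     79295, 7485, 18354, 39497, 7132, 5305
  ), ncol = 6, byrow = TRUE)
  out <- data.frame(
    year = rep(years, each = 6),
    violence_type = rep(c("family", "family", "non_family", "non_family",
                          "self_inflicted", "self_inflicted"), times = 14),
    sex = rep(c("F", "M"), times = 42),
    count = as.integer(t(counts)),
    stringsAsFactors = FALSE
  )
  validate_incidence(out)
}

incidence_types <- c("family", "non_family", "self_inflicted")

validate_incidence <- function(df) {
  need <- c("year", "violence_type", "sex", "count")
  if (!all(need %in% names(df)))
    stop("incidence table requires columns: ", paste(need, collapse = ", "))
  if (any(!df$violence_type %in% incidence_types))
    stop("violence_type must be one of: ", paste(incidence_types, collapse = ", "))
  if (any(!df$sex %in% c("F", "M"))) stop("sex must be 'F' or 'M'")
  if (any(df$count < 0)) stop("counts must be nonnegative")
  if (any(df$count != round(df$count))) stop("counts must be integers")
  combos <- with(df, paste(year, violence_type, sex))
  if (anyDuplicated(combos)) stop("duplicated year/type/sex combination")
  # every listed year must be complete across the types x sexes present
  for (ty in unique(df$violence_type)) {
    sub <- df[df$violence_type == ty, ]
    full <- expand.grid(year = unique(df$year), sex = c("F", "M"))
    have <- with(sub, paste(year, sex))
    want <- with(full, paste(year, sex))
    if (!all(want %in% have))
      stop("incomplete incidence table for type '", ty, "'")
  }
  df[order(df$year, df$violence_type, df$sex), , drop = FALSE]
}

#' Load an incidence table
#'
#' @param source `"fixture"` for the bundled 2010-2023 series
#'   ([incidence_fixture]), or a path to a CSV with header
#'   `year,violence_type,sex,count`.
#' @return Validated incidence data frame.
#' @export
load_incidence <- function(source = "fixture") {
  if (identical(source, "fixture")) return(incidence_fixture())
  df <- utils::read.csv(source, stringsAsFactors = FALSE)
  validate_incidence(df)
}

#' Write an incidence table to CSV
#'
#' @param table Incidence data frame.
#' @param path Output path.
#' @export
write_incidence_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
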