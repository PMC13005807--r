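#' Count cases per administrative unit for one exposure window
#'
#' @param assignments Exposure-assignment table from [assign_windows()].
#' @param cell_to_unit Named vector (or two-column data.frame `cell_id`,
#'   `unit_id`) mapping every grid cell to its unit.
#' @param window Which exposure window to count.
#' @return Named integer vector of case counts, one entry per unit in the
#'   map (zeros included). Counts sum to the number of cases assigned in
#'   that window.
#' @export
count_cases_by_unit <- function(assignments, cell_to_unit, window) {
  window <- match.arg(window, exposure_windows())
  if (is.data.frame(cell_to_unit))
    cell_to_unit <- setNames(cell_to_unit$unit_id, cell_to_unit$cell_id)
  a <- assignments[assignments$window == window, , drop = FALSE]
  units <- sort(unique(unname(cell_to_unit)))
  counts <- setNames(integer(length(units)), units)
  if (nrow(a) > 0L) {
    u <- cell_to_unit[as.character(a$cell_id)]
    if (anyNA(u)) {
      bad <- a$cell_id[is.na(u)][1]
      stop(sprintf("data integrity: cell %s has no unit mapping", bad),
           call. = FALSE)
    }
    tb <- table(u)
    counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
  }
  counts
}

#' Crude incidence per 100,000 person-years
#'
#' @param cases Case count.
#' @param population Mean persons at risk.
#' @param years Length of the observation period in years.
#' @return `cases / (population * years) * 100000`.
#' @export
crude_incidence <- function(cases, population, years) {
  if (any(population <= 0)) stop("undefined rate: population must be > 0", call. = FALSE)
  if (years <= 0) stop("undefined rate: years must be > 0", call. = FALSE)
  cases / (population * years) * 1e5
}

#' Expected cases and observed-vs-expected difference
#'
#' Expected cases are the product of unit population, national incidence (on
#' the per-person-year scale) and period length; the difference is expressed
#' as a percentage of the expectation.
#'
#' @param cases Observed cases.
#' @param population Mean persons at risk.
#' @param national_incidence National rate per person-year (e.g. `36 / 1e5`).
#' @param years Period length in years.
#' @return List with `expected` and `obs_vs_exp_pct`.
#' @export
expected_and_difference <- function(cases, population, national_incidence, years) {
  expected <- population * national_incidence * years
  if (any(expected <= 0))
    stop("undefined difference: expected cases must be > 0", call. = FALSE)
  list(expected = expected, obs_vs_exp_pct = (cases - expected) / expected * 100)
}

#' Percent change between two rates
#'
#' @param from,to Rates on a common scale.
#' @return `(to - from) / from * 100`.
#' @export
percent_change <- function(from, to) {
  if (any(from == 0)) stop("undefined change: baseline rate is 0", call. = FALSE)
  (to - from) / from * 100
}

#' Quintile and top-2% display classes
#'
#' Breaks at the 20/40/60/80th percentiles (linear interpolation between
#' order statistics); values exactly on a break fall in the lower quintile.
#' The top-2% flag uses a closed comparison against the 98th percentile, so
#' when all values are equal every unit is flagged (documented edge case).
#'
#' @param values Numeric vector of per-unit values (at least 5 units).
#' @return Data.frame with `quintile` (1-5) and `top2pct` (logical).
#' @export
classify_display <- function(values) {
  if (length(values) < 5L)
    stop("classification error: need at least 5 units", call. = FALSE)
  br <- quantile(values, c(0.2, 0.4, 0.6, 0.8), type = 7, names = FALSE)
  quintile <- 1L + (values > br[1]) + (values > br[2]) +
    (values > br[3]) + (values > br[4])
  thr <- quantile(values, 0.98, type = 7, names = FALSE)
  data.frame(quintile = as.integer(quintile), top2pct = values >= thr)
}

#' Directly standardised incidence rate
#'
#' @param stratum_cases,stratum_populations Aligned per-stratum counts and
#'   mean populations at risk.
#' @param reference_weights Reference-population weights, summing to 1.
#' @param years Period length in years.
#' @return The weighted sum of stratum-specific crude rates, per 100,000
#'   person-years.
#' @export
standardised_incidence <- function(stratum_cases, stratum_populations,
                                   reference_weights, years) {
  k <- length(stratum_cases)
  if (length(stratum_populations) != k || length(reference_weights) != k)
    stop("strata not aligned", call. = FALSE)
  if (abs(sum(reference_weights) - 1) > 1e-8)
    stop("reference weights must sum to 1", call. = FALSE)
  if (any(stratum_populations == 0 & stratum_cases > 0))
    stop("data error: stratum with zero population but nonzero cases", call. = FALSE)
  rates <- ifelse(stratum_populations > 0,
                  stratum_cases / (stratum_populations * years) * 1e5, 0)
  sum(reference_weights * rates)
}

#' Partition cases by nativity
#'
#' @param cases One-row-per-case data.frame carrying a logical `native`
#'   column (see [case_summary()]).
#' @return List with elements `native` and `non_native`; the two subsets
#'   partition the input.
#' @export
stratify_native <- function(cases) {
  if (anyNA(cases$native))
    stop("data error: missing nativity flag", call. = FALSE)
  list(native = cases[cases$native, , drop = FALSE],
       non_native = cases[!cases$native, , drop = FALSE])
}

#' Per-unit incidence table for one exposure window
#'
#' Assembles the full unit-level result: counts, person-years, crude
#' incidence, expected cases against the national rate computed from the
#' analysed data itself, observed-vs-expected percentage, and display
#' classes.
#'
#' @param assignments Exposure assignments ([assign_windows()]).
#' @param grid Population grid ([generate_grid()]).
#' @param window Exposure window name.
#' @param years Period length in years.
#' @return Data.frame with one row per unit: `unit_id`, `window`, `cases`,
#'   `population`, `person_years`, `crude_incidence`, `expected`,
#'   `obs_vs_exp_pct`, `quintile`, `top2pct`.
#' @export
unit_incidence <- function(assignments, grid, window, years) {
  window <- match.arg(window, exposure_windows())
  counts <- count_cases_by_unit(assignments, grid[, c("cell_id", "unit_id")], window)
  unit_pop <- tapply(grid$population, grid$unit_id, sum)
  units <- as.integer(names(counts))
  pop <- as.numeric(unit_pop[names(counts)])
  total_cases <- sum(counts)
  national <- total_cases / (sum(pop) * years)   # per person-year
  cr <- crude_incidence(as.numeric(counts), pop, years)
  ed <- expected_and_difference(as.numeric(counts), pop, national, years)
  cls <- classify_display(cr)
  data.frame(unit_id = units, window = window, cases = as.integer(counts),
             population = pop, person_years = pop * years,
             crude_incidence = cr, expected = ed$expected,
             obs_vs_exp_pct = ed$obs_vs_exp_pct,
             quintile = cls$quintile, top2pct = cls$top2pct)
}
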