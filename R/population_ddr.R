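#' Proportional age distribution over the DDR-defined focal ages
#'
#' \eqn{w_x(t) = n(x,t) / \sum_{x' \in focal\_ages} n(x',t)}: the population's
#' age structure restricted to the focal ages at which the age-specific DDR
#' is computed, renormalized to sum to 1.
#'
#' @param n Population: a named vector over ages, or an age-by-year matrix
#'   (then `year` selects the column).
#' @param focal_ages Ages included in the average (default 16:64).
#' @param year Calendar year when `n` is a matrix.
#' @return Named weight vector over `focal_ages` summing to 1.
#' @export
age_weights <- function(n, focal_ages = 16:64, year = NULL) {
  if (is.matrix(n)) {
    if (is.null(year)) stop("`year` is required with a matrix", call. = FALSE)
    n <- n[, as.character(year)]
  }
  sel <- n[as.character(focal_ages)]
  if (anyNA(sel))
    stop("population missing some focal ages", call. = FALSE)
  s <- sum(sel)
  if (!is.finite(s) || s <= 0)
    stop("population mass over the focal ages is zero", call. = FALSE)
  w <- sel / s
  names(w) <- focal_ages
  w
}

#' Population-weighted Dementia Dependency Ratio for one year
#'
#' \eqn{DDR^{pop}(t) = \sum_x w_x(t)\, DDR(x,t)}: the expected DDR of an
#' individual drawn at random from the population's age distribution.
#' Undefined age-specific cells (`NA`) are excluded and the remaining weights
#' renormalized; the result always lies within the range of the included
#' age-specific values.
#'
#' @param ddr A `ddr_series` from [ddr()].
#' @param weights Age weights from [age_weights()] (names give the focal
#'   ages).
#' @param year Calendar year.
#' @return Scalar population DDR.
#' @export
population_ddr <- function(ddr, weights, year) {
  stopifnot(inherits(ddr, "ddr_series"))
  if (!year %in% ddr$years)
    stop("year ", year, " not in the DDR series", call. = FALSE)
  dv <- ddr$ddr[names(weights), as.character(year)]
  ok <- !is.na(dv)
  if (!any(ok))
    stop("DDR undefined at every weighted age in ", year, call. = FALSE)
  w <- weights[ok] / sum(weights[ok])
  sum(w * dv[ok])
}

#' Specify a factual or counterfactual DDR scenario
#'
#' A scenario names which group supplies each ingredient of the
#' population-weighted DDR: the kinship structure (kin tensor), the dementia
#' prevalence, and the population age weights.  Factual scenarios use one
#' group for all three; counterfactual scenarios swap one ingredient to
#' isolate its contribution to a between-group gap.
#'
#' @param kinship_source,prevalence_source,weights_source Group labels.
#' @param scheme Kin-weighting scheme, see [kin_weight_scheme()].
#' @param years Years of the series.
#' @param working_ages Working ages for the DDR denominator (default 16:64).
#' @param focal_ages Focal ages over which the population average runs
#'   (default 16:64, the ages at which the DDR is defined).
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kinship_source, prevalence_source, weights_source,
                          scheme = "all_kin", years, working_ages = 16:64,
                          focal_ages = 16:64) {
  structure(list(kinship_source = kinship_source,
                 prevalence_source = prevalence_source,
                 weights_source = weights_source, scheme = scheme,
                 years = as.integer(years),
                 working_ages = as.integer(working_ages),
                 focal_ages = as.integer(focal_ages)),
            class = "scenario_spec")
}

#' Run a (counter)factual population-DDR scenario
#'
#' Computes the age-specific DDR with the kinship structure of one group and
#' the prevalence of another, then averages with a third group's population
#' age weights, year by year.
#'
#' @param spec A [scenario_spec()].
#' @param data Named list of group inputs; each element is a list with `kin`
#'   (a [kin_tensor()]), `prevalence` (age-by-year matrix), and `population`
#'   (age-by-year matrix).
#' @return Data frame with columns `year` and `ddr_pop`.
#' @export
run_scenario <- function(spec, data) {
  stopifnot(inherits(spec, "scenario_spec"))
  for (src in c(spec$kinship_source, spec$prevalence_source,
                spec$weights_source))
    if (!src %in% names(data))
      stop("scenario source '", src, "' not among loaded groups", call. = FALSE)
  kin <- data[[spec$kinship_source]]$kin
  psi <- data[[spec$prevalence_source]]$prevalence
  pop <- data[[spec$weights_source]]$population
  if (!all(spec$years %in% kin$years))
    stop("kin tensor missing scenario years", call. = FALSE)
  if (!all(as.character(spec$years) %in% colnames(pop)))
    stop("population missing scenario years", call. = FALSE)
  dd <- ddr(kin, psi, spec$scheme, spec$working_ages)
  vals <- vapply(spec$years, function(t) {
    population_ddr(dd, age_weights(pop, spec$focal_ages, t), t)
  }, numeric(1))
  data.frame(year = spec$years, ddr_pop = vals)
}

#' Difference between two aligned DDR time series
#'
#' @param series_a,series_b Data frames with a `year` column and a value
#'   column, over identical years.
#' @param value Name of the value column (default `"ddr_pop"`).
#' @return Data frame with columns `year` and `gap` (`a - b`).
#' @export
gap_series <- function(series_a, series_b, value = "ddr_pop") {
  if (!identical(series_a$year, series_b$year))
    stop("series years are not aligned", call. = FALSE)
  data.frame(year = series_a$year,
             gap = series_a[[value]] - series_b[[value]])
}
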