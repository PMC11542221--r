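#' Assemble regularized demographic schedules for one group
#'
#' A rate set carries, for one population group, fertility, one-year survival,
#' survivorship, dementia prevalence, and population structure on a shared
#' single-year age axis `0:omega` and a contiguous calendar-year axis.  All
#' downstream projection and overlay functions consume this container.
#'
#' @param group Group label.
#' @param ages Integer age axis, contiguous, starting at 0.
#' @param years Integer year axis, contiguous.
#' @param fertility Age-by-year matrix of births per woman per year (>= 0).
#' @param survival Age-by-year matrix of one-year survival probabilities
#'   `p(x,t)` in \[0,1\].
#' @param lx Optional survivorship matrix; computed from `survival` when
#'   omitted (`l(0)=1`, cumulative product down each column).
#' @param prevalence Optional age-by-year dementia prevalence matrix in
#'   \[0,1\], zero below `prev_onset`.
#' @param population Optional age-by-year population matrix (>= 0, at least
#'   one positive entry per year).
#' @param prev_onset First age at which prevalence may be positive
#'   (default 65).
#' @return An object of class `rate_set`.
#' @export
rate_set <- function(group, ages, years, fertility, survival, lx = NULL,
                     prevalence = NULL, population = NULL, prev_onset = 65L) {
  ages <- as.integer(ages)
  years <- as.integer(years)
  if (ages[1L] != 0L || any(diff(ages) != 1L))
    stop("`ages` must be contiguous integers starting at 0", call. = FALSE)
  if (length(years) > 1L && any(diff(years) != 1L))
    stop("`years` must be contiguous", call. = FALSE)
  A <- length(ages)
  Ty <- length(years)
  dn <- list(ages, years)
  chk <- function(m, what) {
    m <- as.matrix(m)
    if (nrow(m) != A || ncol(m) != Ty)
      stop(sprintf("`%s` must be a %d x %d age-by-year matrix", what, A, Ty),
           call. = FALSE)
    if (any(!is.finite(m)))
      stop(sprintf("`%s` contains non-finite values", what), call. = FALSE)
    dimnames(m) <- dn
    m
  }
  fertility <- chk(fertility, "fertility")
  if (any(fertility < 0)) stop("fertility must be non-negative", call. = FALSE)
  survival <- chk(survival, "survival")
  if (any(survival < 0 | survival > 1))
    stop("survival probabilities must lie in [0, 1]", call. = FALSE)
  if (is.null(lx))
    lx <- apply(survival, 2L, function(col) cumprod(c(1, col))[seq_along(col)])
  lx <- chk(lx, "lx")
  if (any(abs(lx[1L, ] - 1) > 1e-10))
    stop("survivorship must satisfy l(0) = 1", call. = FALSE)
  if (any(apply(lx, 2L, function(col) any(diff(col) > 1e-12))))
    stop("survivorship must be non-increasing in age", call. = FALSE)
  if (!is.null(prevalence)) {
    prevalence <- chk(prevalence, "prevalence")
    if (any(prevalence < 0 | prevalence > 1))
      stop("prevalence must lie in [0, 1]", call. = FALSE)
    young <- ages < prev_onset
    if (any(prevalence[young, ] != 0))
      stop(sprintf("prevalence must be zero below age %d", prev_onset),
           call. = FALSE)
  }
  if (!is.null(population)) {
    population <- chk(population, "population")
    if (any(population < 0))
      stop("population must be non-negative", call. = FALSE)
    if (any(colSums(population) <= 0))
      stop("population must have a positive entry in every year", call. = FALSE)
  }
  structure(
    list(group = as.character(group), ages = ages, years = years,
         fertility = fertility, survival = survival, lx = lx,
         prevalence = prevalence, population = population,
         prev_onset = as.integer(prev_onset)),
    class = "rate_set"
  )
}

#' @export
print.rate_set <- function(x, ...) {
  cat(sprintf("<rate_set> group '%s': ages %d-%d, years %d-%d\n", x$group,
              min(x$ages), max(x$ages), min(x$years), max(x$years)))
  cat(sprintf("  schedules: fertility, survival%s%s\n",
              if (is.null(x$prevalence)) "" else ", prevalence",
              if (is.null(x$population)) "" else ", population"))
  invisible(x)
}

#' Regularize raw schedule tables into a rate set
#'
#' Applies the standard preprocessing rules to raw published tables for one
#' group: grouped fertility rates are expanded to single ages (zero outside
#' the observed window); abridged survivorship is linearly interpolated to
#' single ages and, when the table stops short of the top age, converted to
#' hazards, extended with the Kannisto model, and rebuilt; grouped prevalence
#' is interpolated at group midpoints with gap-year carry-forward; and every
#' schedule is extended to the full analysis window by boundary copying.
#'
#' @param fertility Data frame with columns `year`, `value`, and either `age`
#'   (single ages) or `age_lo`/`age_hi` (grouped rates).
#' @param mortality Data frame with columns `year`, `age`, `lx` (abridged or
#'   complete survivorship).
#' @param population Data frame with columns `year`, `age`, `value`.
#' @param prevalence Optional data frame with columns `year`, `age_lo`,
#'   `age_hi`, `value`.
#' @param group Group label.
#' @param analysis_years Year window the rate set must cover; schedules are
#'   boundary-extended to it.
#' @param ages Output age axis (default 0:100).
#' @param kannisto_fit_ages Fit window for the old-age extension (default
#'   70:85).
#' @return A [rate_set()].
#' @export
regularize_rates <- function(fertility, mortality, population,
                             prevalence = NULL, group = "group",
                             analysis_years, ages = 0:100,
                             kannisto_fit_ages = 70:85) {
  omega <- max(ages)
  per_year <- function(df, fun) {
    yrs <- sort(unique(df$year))
    cols <- vapply(yrs, function(t) fun(df[df$year == t, , drop = FALSE]),
                   numeric(length(ages)))
    colnames(cols) <- yrs
    rownames(cols) <- ages
    cols
  }
  fmat <- per_year(fertility, function(d) {
    if (all(c("age_lo", "age_hi") %in% names(d))) {
      expand_grouped_rates(d[, c("age_lo", "age_hi", "value")], ages = ages)
    } else {
      out <- numeric(length(ages))
      names(out) <- ages
      out[as.character(d$age)] <- d$value
      out
    }
  })
  surv <- per_year(mortality, function(d) {
    d <- d[order(d$age), , drop = FALSE]
    a_top <- max(d$age)
    lx1 <- interpolate_abridged_survivorship(d$age, d$lx)
    if (a_top < omega) {
      # hazards observed for ages 0..a_top-1; extend to omega-1, rebuild l(x)
      haz_ages <- 0:(a_top - 1L)
      haz <- -log(survivorship_to_p(lx1)[seq_along(haz_ages)])
      ext <- kannisto_extrapolate(haz, ages = haz_ages,
                                  fit_ages = intersect(kannisto_fit_ages, haz_ages),
                                  extend_to = omega - 1L)
      cumprod(c(1, exp(-ext$hazard)))[seq_along(ages)]
    } else {
      lx1[as.character(ages)]
    }
  })
  pmat <- apply(surv, 2L, survivorship_to_p)
  nmat <- per_year(population, function(d) {
    out <- numeric(length(ages))
    names(out) <- ages
    out[as.character(d$age)] <- d$value
    out
  })
  psi <- if (!is.null(prevalence)) {
    build_prevalence(prevalence, ages = ages,
                     through_year = max(analysis_years))
  }
  ext <- function(m) if (is.null(m)) NULL else extend_rates_boundary(m, analysis_years)
  rate_set(group, ages, analysis_years,
           fertility = ext(fmat), survival = ext(pmat), lx = ext(surv),
           prevalence = ext(psi), population = ext(nmat))
}

#' Tidy long-format table of a rate set's schedules
#'
#' @param rates A [rate_set()].
#' @return Data frame with columns `group`, `year`, `age`, `fertility`,
#'   `survival`, `survivorship`, `prevalence`, `population`.
#' @export
schedules_table <- function(rates) {
  stopifnot(inherits(rates, "rate_set"))
  grid <- expand.grid(age = rates$ages, year = rates$years,
                      KEEP.OUT.ATTRS = FALSE)
  data.frame(
    group = rates$group,
    year = grid$year,
    age = grid$age,
    fertility = as.vector(rates$fertility),
    survival = as.vector(rates$survival),
    survivorship = as.vector(rates$lx),
    prevalence = if (is.null(rates$prevalence)) NA_real_ else
      as.vector(rates$prevalence),
    population = if (is.null(rates$population)) NA_real_ else
      as.vector(rates$population)
  )
}
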