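#' Interpolate an abridged survivorship column to single ages
#'
#' Life tables published only at abridged (e.g. 5-year) ages are expanded to a
#' single-year age grid by linear interpolation of the survivorship function
#' `l(x)`, exactly reproducing the published values at the abridged knots.
#'
#' @param ages Integer vector of abridged ages, strictly increasing, starting
#'   at 0.
#' @param lx Survivorship at `ages`; must start at 1 and be non-increasing.
#' @param out_ages Ages at which to evaluate; defaults to every integer age
#'   from the first to the last knot.
#' @return Named numeric vector of survivorship at `out_ages`.
#' @examples
#' interpolate_abridged_survivorship(c(0, 5, 10), c(1, 0.9, 0.8))
#' @export
interpolate_abridged_survivorship <- function(ages, lx, out_ages = NULL) {
  if (length(ages) != length(lx))
    stop("`ages` and `lx` must have equal length", call. = FALSE)
  if (length(ages) < 2L)
    stop("need at least two abridged ages", call. = FALSE)
  if (is.unsorted(ages, strictly = TRUE))
    stop("abridged ages must be strictly increasing", call. = FALSE)
  up <- which(diff(lx) > 0)
  if (length(up))
    stop(sprintf(
      "survivorship increases between ages %s; l(x) must be non-increasing",
      paste(sprintf("%g-%g", ages[up], ages[up + 1L]), collapse = ", ")
    ), call. = FALSE)
  if (ages[1L] != 0 || abs(lx[1L] - 1) > 1e-8)
    stop("abridged table must start at age 0 with l(0) = 1", call. = FALSE)
  if (is.null(out_ages)) out_ages <- seq(min(ages), max(ages))
  out <- stats::approx(ages, lx, xout = out_ages, method = "linear", rule = 2)$y
  names(out) <- out_ages
  out
}

#' Extend an old-age mortality schedule with the Kannisto model
#'
#' Fits the logistic Kannisto hazard \eqn{\mu(x) = a e^{bx} / (1 + a e^{bx})}
#' by ordinary least squares on logit-transformed hazards over a fit window,
#' and extends the schedule beyond the last observed age.  Historical life
#' tables that stop at age 85 are extended to age 100 this way.
#'
#' If the fitted slope is not positive (e.g. a constant-hazard input), the fit
#' is degenerate for extrapolation; a warning is issued and the last observed
#' hazard is held constant instead.
#'
#' @param m Age-specific mortality hazards (per-year rates, in (0,1) over the
#'   fit window).
#' @param ages Ages corresponding to `m`; defaults to `0:(length(m)-1)`.
#' @param fit_ages Ages used for the regression; defaults to ages 70--85
#'   (falling back to the last 16 observed ages when those are unavailable).
#' @param extend_to Last age of the extended schedule (default 100).
#' @return A list with `ages`, `hazard` (the input followed by fitted values),
#'   the fitted `a` and `b`, and a logical `fallback`.
#' @export
kannisto_extrapolate <- function(m, ages = seq_along(m) - 1L, fit_ages = NULL,
                                 extend_to = 100L) {
  if (length(m) != length(ages))
    stop("`m` and `ages` must have equal length", call. = FALSE)
  a_max <- max(ages)
  if (a_max >= extend_to)
    return(list(ages = ages, hazard = unname(m), a = NA_real_, b = NA_real_,
                fallback = FALSE))
  if (is.null(fit_ages)) {
    fit_ages <- intersect(70:85, ages)
    if (length(fit_ages) < 2L) fit_ages <- utils::tail(ages, 16L)
  }
  if (length(fit_ages) < 2L)
    stop("fit window must contain at least two ages", call. = FALSE)
  sel <- match(fit_ages, ages)
  if (anyNA(sel))
    stop("fit window contains ages absent from the schedule", call. = FALSE)
  mu <- m[sel]
  if (any(!is.finite(mu)) || any(mu <= 0) || any(mu >= 1))
    stop("hazards in the fit window must lie strictly in (0, 1)", call. = FALSE)
  co <- stats::lm.fit(cbind(1, fit_ages), log(mu / (1 - mu)))$coefficients
  b <- unname(co[2L])
  ext_ages <- (a_max + 1L):extend_to
  if (!is.finite(b) || b <= 0) {
    warning("Kannisto fit degenerate (b <= 0); holding last observed hazard constant",
            call. = FALSE)
    ext <- rep(m[length(m)], length(ext_ages))
    a <- NA_real_
    b <- NA_real_
    fallback <- TRUE
  } else {
    a <- unname(exp(co[1L]))
    eb <- a * exp(b * ext_ages)
    ext <- eb / (1 + eb)
    fallback <- FALSE
  }
  list(ages = c(ages, ext_ages), hazard = unname(c(m, ext)), a = a, b = b,
       fallback = fallback)
}

#' Expand rates published in age groups to a single-year schedule
#'
#' Each single age receives its group's rate (constant within group).  Ages
#' not covered by any group, or outside `window`, are set to zero: fertility
#' is taken to be zero beyond the observed age range of the source.
#'
#' @param groups Data frame with columns `age_lo`, `age_hi`, `value`; groups
#'   must be contiguous or disjoint, never overlapping.
#' @param window Length-2 vector of the observed age range; rates outside it
#'   are zeroed.  Defaults to the range spanned by `groups`.
#' @param ages Output age axis (default 0:100).
#' @return Named numeric vector over `ages`.
#' @export
expand_grouped_rates <- function(groups, window = NULL, ages = 0:100) {
  need <- c("age_lo", "age_hi", "value")
  if (!all(need %in% names(groups)))
    stop("`groups` must have columns age_lo, age_hi, value", call. = FALSE)
  g <- groups[order(groups$age_lo), , drop = FALSE]
  if (any(g$age_hi < g$age_lo))
    stop("age_hi must be >= age_lo in every group", call. = FALSE)
  if (nrow(g) > 1L && any(g$age_lo[-1L] <= g$age_hi[-nrow(g)]))
    stop("overlapping age groups", call. = FALSE)
  if (is.null(window)) window <- c(min(g$age_lo), max(g$age_hi))
  out <- numeric(length(ages))
  names(out) <- ages
  for (i in seq_len(nrow(g)))
    out[ages >= g$age_lo[i] & ages <= g$age_hi[i]] <- g$value[i]
  out[ages < window[1L] | ages > window[2L]] <- 0
  out
}

#' Build a single-age dementia prevalence surface from grouped estimates
#'
#' Grouped prevalence estimates (5-year age groups between 65 and 100, for a
#' possibly gappy set of estimate years) are converted to a complete
#' age-by-year matrix: within each year the group values are anchored at the
#' group midpoints and linearly interpolated across single ages, held constant
#' beyond the outermost midpoints (within the onset--100 range); prevalence is
#' zero below the onset age (65); years without an estimate carry the
#' preceding year's schedule forward; years after the last estimate hold the
#' last schedule constant through `through_year`.
#'
#' @param grouped Data frame with columns `year`, `age_lo`, `age_hi`, `value`
#'   (`value` in \[0,1\]).
#' @param onset First age with nonzero prevalence (default 65).
#' @param ages Output age axis (default 0:100).
#' @param through_year Extend the surface to this year, holding the last
#'   estimate constant (default: last estimate year).
#' @return Matrix of prevalence, rows = `ages`, columns = years.
#' @export
build_prevalence <- function(grouped, onset = 65L, ages = 0:100,
                             through_year = NULL) {
  need <- c("year", "age_lo", "age_hi", "value")
  if (!all(need %in% names(grouped)))
    stop("`grouped` must have columns year, age_lo, age_hi, value", call. = FALSE)
  if (any(grouped$value < 0 | grouped$value > 1))
    stop("prevalence values must lie in [0, 1]", call. = FALSE)
  est_years <- sort(unique(grouped$year))
  if (is.null(through_year)) through_year <- max(est_years)
  years <- min(est_years):max(max(est_years), through_year)
  psi <- matrix(0, length(ages), length(years),
                dimnames = list(ages, years))
  onset_sel <- ages >= onset
  cur <- NULL
  for (t in years) {
    if (t %in% est_years) {
      df <- grouped[grouped$year == t, , drop = FALSE]
      mid <- (df$age_lo + df$age_hi) / 2
      o <- order(mid)
      cur <- if (nrow(df) == 1L) {
        rep(df$value, sum(onset_sel))
      } else {
        stats::approx(mid[o], df$value[o], xout = ages[onset_sel],
                      method = "linear", rule = 2)$y
      }
    }
    psi[onset_sel, as.character(t)] <- cur
  }
  psi
}

#' Convert age-specific mortality rates to survival
#'
#' One-year survival probabilities use the constant-hazard-within-age
#' convention \eqn{p(x) = e^{-m(x)}}, which keeps `p` in (0,1\] for any
#' non-negative rate; survivorship is the cumulative product with `l(0) = 1`.
#'
#' @param m Non-negative mortality rates: a vector over ages, or an
#'   age-by-year matrix.
#' @return List with `p` (one-year survival, same shape as `m`) and `lx`
#'   (survivorship from birth, same shape).
#' @export
mortality_to_survival <- function(m) {
  if (any(!is.finite(m)) || any(m < 0))
    stop("mortality rates must be finite and non-negative", call. = FALSE)
  p <- exp(-m)
  if (is.matrix(m)) {
    lx <- apply(p, 2L, function(col) cumprod(c(1, col))[seq_along(col)])
    dimnames(lx) <- dimnames(m)
  } else {
    lx <- cumprod(c(1, p))[seq_along(p)]
    names(lx) <- names(m)
  }
  list(p = p, lx = lx)
}

#' One-year survival probabilities from a survivorship column
#'
#' `p(x) = l(x+1)/l(x)`; ages where `l(x) = 0` get `p(x) = 0`, and the final
#' age has no onward transition.
#'
#' @param lx Survivorship over a contiguous single-year age axis.
#' @return Vector of one-year survival probabilities, same length as `lx`
#'   (last entry 0: survivors beyond the top age are dropped).
#' @export
survivorship_to_p <- function(lx) {
  n <- length(lx)
  p <- numeric(n)
  ok <- lx[-n] > 0
  p[-n][ok] <- lx[-1L][ok] / lx[-n][ok]
  names(p) <- names(lx)
  p
}

#' Extend a schedule to a wider year window by boundary copying
#'
#' Years before the first data year copy the first data year; years after the
#' last copy the last.  Kin of old cohorts require rates decades before the
#' first observed year, so the earliest observed schedule is backfilled.
#'
#' @param mat Age-by-year matrix with year column names.
#' @param target_years Integer years the output must cover (a superset of the
#'   data window).
#' @return Age-by-year matrix over `target_years`.
#' @export
extend_rates_boundary <- function(mat, target_years) {
  yrs <- as.integer(colnames(mat))
  if (!length(yrs)) stop("empty data window", call. = FALSE)
  src <- pmin(pmax(target_years, min(yrs)), max(yrs))
  pos <- match(src, yrs)
  if (anyNA(pos))
    stop("years missing from the interior of the schedule: ",
         paste(src[is.na(pos)], collapse = ", "), call. = FALSE)
  out <- mat[, pos, drop = FALSE]
  colnames(out) <- target_years
  out
}
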