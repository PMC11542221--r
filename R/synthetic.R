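#' Parameters of a synthetic demographic group
#'
#' Describes one group's schedules in closed form: a bell-shaped fertility
#' schedule integrating to a target total fertility rate over the fertile age
#' window; Gompertz-Makeham mortality hazards (background plus exponentially
#' senescent); dementia prevalence that is zero before the onset age and
#' rises logistically to a plateau; and optional linear secular trend
#' multipliers per calendar year.  The generated rate set is fully
#' deterministic given the spec.
#'
#' @param label Group label.
#' @param omega Top age of the axis (default 100).
#' @param tfr Total fertility rate (daughters and sons per woman; the model
#'   uses it directly as the female schedule's integral).
#' @param fert_mean,fert_sd Mean and spread (years) of the fertility age
#'   schedule.
#' @param fert_ages Length-2 fertile age window (default 14--54); fertility
#'   is zero outside it.
#' @param gompertz_a,gompertz_b Gompertz baseline hazard and senescence slope
#'   (per year).
#' @param makeham Age-independent background hazard (per year).
#' @param prev_plateau Prevalence plateau approached by age 100 (<= 1).
#' @param prev_steep Logistic steepness of the prevalence rise (per year).
#' @param prev_mid Age at half-plateau.
#' @param prev_onset First age with nonzero prevalence (default 65).
#' @param trend_fert,trend_mort,trend_prev Linear secular multipliers per
#'   year relative to `ref_year` (e.g. `-0.002` scales a schedule by
#'   `1 - 0.002 (t - ref)`); multipliers are floored at zero.
#' @param ref_year Reference year for trends (default: first generated year).
#' @return An object of class `synth_group_spec`.
#' @export
synth_group_spec <- function(label = "A", omega = 100L,
                             tfr = 1.9, fert_mean = 28, fert_sd = 6,
                             fert_ages = c(14L, 54L),
                             gompertz_a = 3e-5, gompertz_b = 0.095,
                             makeham = 4e-4,
                             prev_plateau = 0.35, prev_steep = 0.13,
                             prev_mid = 86, prev_onset = 65L,
                             trend_fert = 0, trend_mort = 0, trend_prev = 0,
                             ref_year = NULL) {
  if (tfr <= 0 || fert_sd <= 0)
    stop("tfr and fert_sd must be positive", call. = FALSE)
  if (gompertz_a < 0 || gompertz_b < 0 || makeham < 0)
    stop("hazard parameters must be non-negative", call. = FALSE)
  if (prev_plateau < 0 || prev_plateau > 1)
    stop("prevalence plateau must lie in [0, 1]", call. = FALSE)
  if (prev_steep <= 0)
    stop("prevalence steepness must be positive", call. = FALSE)
  structure(list(label = label, omega = as.integer(omega), tfr = tfr,
                 fert_mean = fert_mean, fert_sd = fert_sd,
                 fert_ages = as.integer(fert_ages),
                 gompertz_a = gompertz_a, gompertz_b = gompertz_b,
                 makeham = makeham, prev_plateau = prev_plateau,
                 prev_steep = prev_steep, prev_mid = prev_mid,
                 prev_onset = as.integer(prev_onset),
                 trend_fert = trend_fert, trend_mort = trend_mort,
                 trend_prev = trend_prev, ref_year = ref_year),
            class = "synth_group_spec")
}

#' Generate a synthetic rate set
#'
#' Builds the closed-form schedules described by a [synth_group_spec()] on a
#' year window.  Fertility is a truncated-normal shape scaled so that the
#' sum over ages equals the (trend-adjusted) total fertility rate exactly;
#' survival comes from Gompertz-Makeham hazards via the constant-hazard
#' convention; prevalence is zero before the onset age and logistic above it;
#' the population structure is the stationary population implied by the
#' year's survivorship.
#'
#' @param spec A [synth_group_spec()].
#' @param years Integer year window.
#' @return A [rate_set()].
#' @export
synth_rates <- function(spec, years) {
  stopifnot(inherits(spec, "synth_group_spec"))
  years <- as.integer(years)
  ages <- 0:spec$omega
  A <- length(ages)
  ref <- if (is.null(spec$ref_year)) years[1L] else spec$ref_year
  shape <- stats::dnorm(ages, spec$fert_mean, spec$fert_sd)
  shape[ages < spec$fert_ages[1L] | ages > spec$fert_ages[2L]] <- 0
  if (sum(shape) <= 0)
    stop("fertile age window excludes the whole schedule", call. = FALSE)
  shape <- shape / sum(shape)
  trend <- function(slope, t) pmax(0, 1 + slope * (t - ref))
  f <- vapply(years, function(t) shape * spec$tfr * trend(spec$trend_fert, t),
              numeric(A))
  haz <- spec$makeham + spec$gompertz_a * exp(spec$gompertz_b * ages)
  m <- vapply(years, function(t) haz * trend(spec$trend_mort, t), numeric(A))
  sv <- mortality_to_survival(m)
  psi0 <- ifelse(ages < spec$prev_onset, 0,
                 spec$prev_plateau /
                   (1 + exp(-spec$prev_steep * (ages - spec$prev_mid))))
  psi <- vapply(years, function(t) pmin(1, psi0 * trend(spec$trend_prev, t)),
                numeric(A))
  rate_set(spec$label, ages, years,
           fertility = f, survival = sv$p, lx = sv$lx,
           prevalence = psi, population = sv$lx,
           prev_onset = spec$prev_onset)
}

#' Two synthetic groups with controlled demographic gaps
#'
#' Returns an "advantaged" and a "disadvantaged" rate set differing by
#' stylized gaps: the disadvantaged group has higher fertility, earlier
#' childbearing, proportionally higher mortality hazards, and pointwise
#' higher dementia prevalence (higher plateau, earlier rise).  Zero gaps
#' reproduce the advantaged schedules exactly.
#'
#' @param years Year window of the generated rate sets.
#' @param base [synth_group_spec()] of the advantaged group.
#' @param gap List of gap parameters applied to `base`: `tfr_delta` (added to
#'   the TFR), `fert_mean_delta` (years added to the fertility mean age),
#'   `mort_scale` (multiplies both hazard components), `prev_plateau_delta`
#'   and `prev_mid_delta` (added to the prevalence plateau and midpoint age).
#' @return Named list of two [rate_set()]s: `advantaged`, `disadvantaged`.
#' @export
two_group_fixture <- function(years = 1940:2060,
                              base = synth_group_spec(label = "advantaged"),
                              gap = list()) {
  gd <- utils::modifyList(
    list(tfr_delta = 0.4, fert_mean_delta = -3, mort_scale = 1.5,
         prev_plateau_delta = 0.10, prev_mid_delta = -2),
    gap
  )
  dis <- base
  dis$label <- "disadvantaged"
  dis$tfr <- base$tfr + gd$tfr_delta
  dis$fert_mean <- base$fert_mean + gd$fert_mean_delta
  dis$gompertz_a <- base$gompertz_a * gd$mort_scale
  dis$makeham <- base$makeham * gd$mort_scale
  dis$prev_plateau <- min(1, base$prev_plateau + gd$prev_plateau_delta)
  dis$prev_mid <- base$prev_mid + gd$prev_mid_delta
  list(advantaged = synth_rates(base, years),
       disadvantaged = synth_rates(dis, years))
}

#' Stochastic matrilineal kinship microsimulation
#'
#' Independent check of the matrix projections: simulates, replicate by
#' replicate, the female branching process around a focal individual under
#' the time-invariant rates of one year -- the mother's age at the focal
#' birth is drawn from the mothers' age distribution, every individual
#' survives year by year according to the one-year survival probabilities
#' (survivors beyond the top age are dropped), and births are Bernoulli
#' events per age of a living woman with probability `min(f, 1)`.  Tracked
#' kin: mothers, daughters, granddaughters, grandmothers, older and younger
#' sisters, aunts (those alive or born by the focal birth, matching the
#' projection's boundary condition), and nieces.  Great-granddaughters,
#' great-grandmothers, and cousins are not simulated; they are listed in
#' `excluded_types`.
#'
#' @param rates A [rate_set()].
#' @param year Year whose schedules drive the simulation (default: first
#'   year of the rate set).
#' @param n_reps Number of replicates (>= 1).
#' @param seed Integer seed; results are fully reproducible given the seed.
#' @param mothers_dist Optional mothers' age distribution overriding the one
#'   computed from fertility and population.
#' @return Object of class `microsim_result`: list with `mean` and `se`
#'   (kin-type by focal-age matrices of Monte-Carlo means and standard
#'   errors of total living kin), `by_kin_age` (kin-age x type x focal-age
#'   array of mean counts), `per_rep` (replicate x type x focal-age integer
#'   array), `types`, `excluded_types`, `n_reps`, `seed`, `year`.
#' @export
microsim_kinship <- function(rates, year = min(rates$years), n_reps = 10000L,
                             seed = 1L, mothers_dist = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  if (n_reps < 1) stop("n_reps must be >= 1", call. = FALSE)
  R <- as.integer(n_reps)
  ages <- rates$ages
  omega <- max(ages)
  A <- length(ages)
  f <- unname(rates$fertility[, as.character(year)])
  p <- unname(rates$survival[, as.character(year)])
  p[A] <- 0  # survivors beyond omega are dropped
  lx <- cumprod(c(1, p))[1:A]
  pi0 <- if (is.null(mothers_dist)) {
    mothers_age_distribution(rates$fertility[, as.character(year)],
                             rates$population[, as.character(year)])
  } else {
    mothers_dist
  }
  set.seed(seed)

  # conditional death-age tables: P(last completed age = d | alive at age s)
  dieq <- 1 - p
  ldist <- vector("list", A)
  for (s0 in 0:(A - 1L)) {
    if (lx[s0 + 1L] <= 0) {
      ldist[[s0 + 1L]] <- c(1, rep(0, omega - s0))  # dies at once
    } else {
      pr <- (lx[(s0 + 1L):A] / lx[s0 + 1L]) * dieq[(s0 + 1L):A]
      ldist[[s0 + 1L]] <- pr / sum(pr)
    }
  }
  draw_last <- function(start_ages) {
    out <- integer(length(start_ages))
    for (s0 in unique(start_ages)) {
      k <- which(start_ages == s0)
      out[k] <- s0 + sample.int(omega - s0 + 1L, length(k), replace = TRUE,
                                prob = ldist[[s0 + 1L]]) - 1L
    }
    out
  }

  fpos <- which(f > 0)
  has_fert <- length(fpos) > 0L
  fl <- if (has_fert) min(fpos) - 1L else 0L
  fh <- if (has_fert) max(fpos) - 1L else -1L
  # Bernoulli births of parents over alive fertile age windows [lo, hi]
  births <- function(lo, hi) {
    len <- pmax(0L, hi - lo + 1L)
    keep <- which(len > 0L)
    if (!length(keep) || !has_fert)
      return(list(parent = integer(0), age = integer(0)))
    pid <- rep(keep, len[keep])
    age <- sequence(len[keep]) - 1L + rep(lo[keep], len[keep])
    hit <- stats::runif(length(age)) < pmin(1, f[age + 1L])
    list(parent = pid[hit], age = age[hit])
  }

  draw_pi <- function(n) sample.int(A, n, replace = TRUE, prob = pi0) - 1L

  # Individuals are rows of (rep, type, afb, last): afb = age at the focal
  # birth (negative when born later: a birth to a parent aged a enters at
  # age 0 one year later, matching the projection's recruitment timing),
  # last = last completed age alive.
  types <- c("mothers", "daughters", "granddaughters", "grandmothers",
             "older_sisters", "younger_sisters", "aunts", "nieces")
  rep_v <- integer(0); type_v <- integer(0)
  afb_v <- integer(0); last_v <- integer(0)
  add <- function(rep, type, afb, last) {
    rep_v <<- c(rep_v, rep)
    type_v <<- c(type_v, rep.int(match(type, types), length(rep)))
    afb_v <<- c(afb_v, as.integer(afb))
    last_v <<- c(last_v, as.integer(last))
  }

  m_age <- draw_pi(R)
  m_last <- draw_last(m_age)
  add(1:R, "mothers", m_age, m_last)

  # sisters: mother's other births while alive (alive below m_age by
  # conditioning); born at mother age a => age m_age - a - 1 at focal birth
  sb <- births(rep.int(fl, R), pmin(fh, m_last))
  s_rep <- sb$parent
  s_afb <- m_age[s_rep] - sb$age - 1L
  s_last <- draw_last(rep.int(0L, length(s_afb)))
  s_older <- s_afb >= 0L
  add(s_rep[s_older], "older_sisters", s_afb[s_older], s_last[s_older])
  add(s_rep[!s_older], "younger_sisters", s_afb[!s_older], s_last[!s_older])

  # grandmother: age at the mother's birth drawn from pi; conditioned alive
  # then, counted while she survives
  g_age <- draw_pi(R)
  g_last <- draw_last(g_age)
  add(1:R, "grandmothers", g_age + m_age, g_last)

  # aunts: grandmother's other daughters born by the focal birth (no aunt
  # recruitment afterwards, matching the projection's boundary condition)
  ab <- births(rep.int(fl, R), pmin(fh, g_last, g_age + m_age - 1L))
  add(ab$parent, "aunts", g_age[ab$parent] + m_age[ab$parent] - ab$age - 1L,
      draw_last(rep.int(0L, length(ab$parent))))

  # daughters: the focal's own births (the focal is conditioned alive)
  db <- births(rep.int(fl, R), rep.int(fh, R))
  d_rep <- db$parent
  d_afb <- -(db$age + 1L)
  d_last <- draw_last(rep.int(0L, length(d_rep)))
  add(d_rep, "daughters", d_afb, d_last)

  # granddaughters: daughters' births while the daughter is alive
  if (length(d_rep)) {
    d_lo <- rep.int(fl, length(d_rep))
    gb <- births(d_lo, pmin(fh, d_last))
    add(d_rep[gb$parent], "granddaughters",
        d_afb[gb$parent] - gb$age - 1L,
        draw_last(rep.int(0L, length(gb$parent))))
  }

  # nieces: sisters' births while the sister is alive
  if (length(s_rep)) {
    nb <- births(rep.int(fl, length(s_rep)), pmin(fh, s_last))
    add(s_rep[nb$parent], "nieces",
        s_afb[nb$parent] - nb$age - 1L,
        draw_last(rep.int(0L, length(nb$parent))))
  }

  ntypes <- length(types)
  per_rep <- array(0L, c(R, ntypes, A),
                   dimnames = list(NULL, types, ages))
  by_kin_age <- array(0, c(A, ntypes, A),
                      dimnames = list(ages, types, ages))
  cap <- pmin(last_v, omega)
  for (x in 0:omega) {
    age <- afb_v + x
    alive <- age >= 0L & age <= cap
    idx <- rep_v[alive] + R * (type_v[alive] - 1L)
    per_rep[, , x + 1L] <- tabulate(idx, nbins = R * ntypes)
    idx2 <- (age[alive] + 1L) + A * (type_v[alive] - 1L)
    by_kin_age[, , x + 1L] <- tabulate(idx2, nbins = A * ntypes) / R
  }
  mean_tot <- colMeans(per_rep)                      # ntypes x A
  var_tot <- apply(per_rep, c(2L, 3L), stats::var)
  se_tot <- sqrt(var_tot / R)
  dimnames(mean_tot) <- dimnames(se_tot) <- list(types, ages)
  structure(list(mean = mean_tot, se = se_tot, by_kin_age = by_kin_age,
                 per_rep = per_rep, types = types,
                 excluded_types = c("great_granddaughters",
                                    "great_grandmothers", "cousins"),
                 n_reps = R, seed = seed, year = year),
            class = "microsim_result")
}

#' @export
print.microsim_result <- function(x, ...) {
  cat(sprintf("<microsim_result> %d replicates, year %d, seed %d\n",
              x$n_reps, x$year, x$seed))
  cat("  simulated:", paste(x$types, collapse = ", "), "\n")
  cat("  excluded:", paste(x$excluded_types, collapse = ", "), "\n")
  invisible(x)
}
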