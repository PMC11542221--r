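#' @name kin_types
#' @title Kin type labels
#' @description One-sex (matrilineal) kin types projected by the model, the
#'   two-sex labels they map onto under the Goodman-Keyfitz-Pullum
#'   approximation, and the corresponding scaling factors (powers of two that
#'   count both sexes through both parental lines, assuming identical male
#'   and female rates).
#' @export
KIN_TYPES_ONE_SEX <- c(
  "daughters", "granddaughters", "great_granddaughters",
  "mothers", "grandmothers", "great_grandmothers",
  "older_sisters", "younger_sisters", "nieces", "aunts", "cousins"
)

#' @rdname kin_types
#' @export
KIN_TYPES_TWO_SEX <- c(
  "children", "grandchildren", "great_grandchildren",
  "parents", "grandparents", "great_grandparents",
  "siblings", "nieces_nephews", "aunts_uncles", "cousins"
)

#' @rdname kin_types
#' @export
ONE_TO_TWO_SEX <- c(
  daughters = "children", granddaughters = "grandchildren",
  great_granddaughters = "great_grandchildren", mothers = "parents",
  grandmothers = "grandparents", great_grandmothers = "great_grandparents",
  older_sisters = "siblings", younger_sisters = "siblings",
  nieces = "nieces_nephews", aunts = "aunts_uncles", cousins = "cousins"
)

#' @rdname kin_types
#' @export
GKP_FACTORS <- c(
  children = 2, grandchildren = 4, great_grandchildren = 8,
  parents = 2, grandparents = 4, great_grandparents = 8,
  siblings = 2, nieces_nephews = 4, aunts_uncles = 4, cousins = 8
)

#' Age-structured survival projection matrix for one year
#'
#' Builds the square operator `U(t)` that moves age-x survivors to age x+1
#' with probability `p(x,t)`; only the subdiagonal is nonzero, and survivors
#' beyond the top age are dropped.
#'
#' @param x A [rate_set()] (with `year` giving the column) or a numeric vector
#'   of one-year survival probabilities over the age axis.
#' @param year Calendar year, required when `x` is a rate set.
#' @return A square matrix of dimension `length(ages)`.
#' @export
build_projection_matrix <- function(x, year = NULL) {
  p <- if (inherits(x, "rate_set")) {
    if (is.null(year)) stop("`year` is required with a rate_set", call. = FALSE)
    if (!year %in% x$years) stop("year ", year, " not in rate set", call. = FALSE)
    x$survival[, as.character(year)]
  } else {
    x
  }
  if (any(p < 0 | p > 1)) stop("survival probabilities must lie in [0, 1]",
                               call. = FALSE)
  A <- length(p)
  U <- matrix(0, A, A)
  U[cbind(2:A, 1:(A - 1L))] <- p[1:(A - 1L)]
  U
}

#' Age distribution of mothers at a birth
#'
#' The probability that a birth in year `t` is to a mother of age `x`:
#' \eqn{\pi_x = f(x) n(x) / \sum_y f(y) n(y)}.  Seeds the ancestor kin at the
#' focal individual's birth.
#'
#' @param fertility A [rate_set()] or a numeric fertility vector over ages.
#' @param population Population vector over ages (ignored when `fertility` is
#'   a rate set).
#' @param year Calendar year, required when `fertility` is a rate set.
#' @return Probability vector over ages, summing to 1.
#' @export
mothers_age_distribution <- function(fertility, population = NULL, year = NULL) {
  if (inherits(fertility, "rate_set")) {
    rs <- fertility
    if (is.null(year)) stop("`year` is required with a rate_set", call. = FALSE)
    if (is.null(rs$population))
      stop("rate set has no population structure", call. = FALSE)
    fertility <- rs$fertility[, as.character(year)]
    population <- rs$population[, as.character(year)]
  }
  w <- fertility * population
  s <- sum(w)
  if (!is.finite(s) || s <= 0)
    stop("no births: fertility times population sums to zero", call. = FALSE)
  unname(w / s)
}

# Kin grids at one instant: a named list of A x A matrices, K[[type]][a, x+1]
# = expected kin of that type aged a-1 when the focal individual is aged x.

# Stationary kin grids under time-invariant rates: each type is solved column
# by column in topological order of its boundary/recruitment dependencies.
kin_seed_invariant <- function(f, p, pi0, A) {
  solve_type <- function(init, recruit = NULL) {
    K <- matrix(0, A, A)
    K[, 1L] <- init
    ps <- p[1:(A - 1L)]
    for (cc in 1:(A - 1L)) {
      K[2:A, cc + 1L] <- ps * K[1:(A - 1L), cc]
      if (!is.null(recruit)) K[1L, cc + 1L] <- recruit(cc)
    }
    K
  }
  g <- list()
  g$daughters <- solve_type(numeric(A), function(cc) f[cc])
  g$mothers <- solve_type(pi0)
  g$older_sisters <- solve_type(as.vector(g$daughters %*% pi0))
  g$younger_sisters <- solve_type(numeric(A),
                                  function(cc) sum(f * g$mothers[, cc]))
  g$granddaughters <- solve_type(numeric(A),
                                 function(cc) sum(f * g$daughters[, cc]))
  g$great_granddaughters <- solve_type(numeric(A),
                                       function(cc) sum(f * g$granddaughters[, cc]))
  g$grandmothers <- solve_type(as.vector(g$mothers %*% pi0))
  g$great_grandmothers <- solve_type(as.vector(g$grandmothers %*% pi0))
  sis <- g$older_sisters + g$younger_sisters
  g$nieces <- solve_type(as.vector(g$granddaughters %*% pi0),
                         function(cc) sum(f * sis[, cc]))
  g$aunts <- solve_type(as.vector(sis %*% pi0))
  g$cousins <- solve_type(as.vector(g$nieces %*% pi0),
                          function(cc) sum(f * g$aunts[, cc]))
  g[KIN_TYPES_ONE_SEX]
}

# One projection step: grids at year t -> grids at year t+1 under the year-t
# survival f/p and the year-t+1 mothers' age distribution.
kin_step <- function(g, f, p, pi_next, A) {
  ps <- p[1:(A - 1L)]
  adv <- function(K, b = NULL) {
    Kn <- matrix(0, A, A)
    Kn[2:A, 2:A] <- ps * K[1:(A - 1L), 1:(A - 1L), drop = FALSE]
    if (!is.null(b)) Kn[1L, 2:A] <- b
    Kn
  }
  rec <- function(K) as.vector(f %*% K[, 1:(A - 1L), drop = FALSE])
  sis <- g$older_sisters + g$younger_sisters
  n <- list()
  n$daughters <- adv(g$daughters, f[1:(A - 1L)])
  n$granddaughters <- adv(g$granddaughters, rec(g$daughters))
  n$great_granddaughters <- adv(g$great_granddaughters, rec(g$granddaughters))
  n$mothers <- adv(g$mothers)
  n$grandmothers <- adv(g$grandmothers)
  n$great_grandmothers <- adv(g$great_grandmothers)
  n$older_sisters <- adv(g$older_sisters)
  n$younger_sisters <- adv(g$younger_sisters, rec(g$mothers))
  n$nieces <- adv(g$nieces, rec(sis))
  n$aunts <- adv(g$aunts)
  n$cousins <- adv(g$cousins, rec(g$aunts))
  # age-0 boundary conditions for the new year, in dependency order
  n$mothers[, 1L] <- pi_next
  n$older_sisters[, 1L] <- as.vector(n$daughters %*% pi_next)
  n$grandmothers[, 1L] <- as.vector(n$mothers %*% pi_next)
  n$great_grandmothers[, 1L] <- as.vector(n$grandmothers %*% pi_next)
  n$nieces[, 1L] <- as.vector(n$granddaughters %*% pi_next)
  n$aunts[, 1L] <- as.vector((n$older_sisters + n$younger_sisters) %*% pi_next)
  n$cousins[, 1L] <- as.vector(n$nieces %*% pi_next)
  n[KIN_TYPES_ONE_SEX]
}

#' Construct a kin tensor
#'
#' Container for expected kin counts indexed by kin age, focal age, and
#' calendar year.  Normally produced by [project_kin()]; the constructor is
#' exported so that small tensors can be built directly, e.g. for worked
#' examples of the overlay operations.
#'
#' @param counts Named list of 3-d arrays, one per kin type, with dimensions
#'   kin age x focal age x year.
#' @param ages Integer age axis shared by kin and focal dimensions.
#' @param years Integer years of the third dimension.
#' @param group Group label.
#' @param sex `"one"` for matrilineal counts, `"two"` for
#'   Goodman-Keyfitz-Pullum scaled counts.
#' @return An object of class `kin_tensor`.
#' @export
kin_tensor <- function(counts, ages, years, group = "group",
                       sex = c("one", "two")) {
  sex <- match.arg(sex)
  ages <- as.integer(ages)
  years <- as.integer(years)
  A <- length(ages)
  Ty <- length(years)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("`counts` must be a named list of arrays", call. = FALSE)
  counts <- lapply(counts, function(a) {
    a <- as.array(a)
    if (length(dim(a)) == 2L) dim(a) <- c(dim(a), 1L)
    if (!identical(dim(a), c(A, A, Ty)))
      stop("each counts array must be kin age x focal age x year", call. = FALSE)
    if (any(!is.finite(a)) || any(a < 0))
      stop("kin counts must be finite and non-negative", call. = FALSE)
    dimnames(a) <- list(ages, ages, years)
    a
  })
  structure(list(counts = counts, ages = ages, years = years,
                 group = as.character(group), sex = sex),
            class = "kin_tensor")
}

#' @export
print.kin_tensor <- function(x, ...) {
  cat(sprintf("<kin_tensor> group '%s' (%s-sex): %d kin types, ages %d-%d, years %d-%d\n",
              x$group, x$sex, length(x$counts), min(x$ages), max(x$ages),
              min(x$years), max(x$years)))
  cat("  types:", paste(names(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Project expected kin age distributions under time-varying rates
#'
#' Treats each kin type of a focal individual as its own age-structured
#' population and projects it across focal ages and calendar years with
#' matrix population models.  Kin survive according to the year's survival
#' probabilities; newborn kin enter at age 0 through type-specific
#' recruitment (the focal's own fertility for daughters, fertility applied to
#' the current daughter distribution for granddaughters, and so on); ancestor
#' types and older sisters are fixed at the focal's birth from the mothers'
#' age distribution and receive no recruitment.  The grid is seeded at
#' `t_start` with the stationary solution under constant `t_start` rates,
#' which is equivalent to an infinite burn-in under boundary-extended rates.
#' The focal individual is conditioned to be alive at every age.
#'
#' @param rates A [rate_set()] covering `t_start:t_end` (population structure
#'   required unless `mothers_dist` is given).
#' @param t_start,t_end First and last projection years (defaults: the rate
#'   set's year range).
#' @param output_years Years to retain in the returned tensor (default all of
#'   `t_start:t_end`).
#' @param kin_types Kin types to return; all types are always computed since
#'   recruitment couples them.
#' @param mothers_dist Optional mothers' age distribution overriding the one
#'   computed from fertility and population: a probability vector (used for
#'   every year) or an age-by-year matrix.
#' @return A one-sex [kin_tensor()].
#' @export
project_kin <- function(rates, t_start = min(rates$years),
                        t_end = max(rates$years),
                        output_years = t_start:t_end,
                        kin_types = KIN_TYPES_ONE_SEX,
                        mothers_dist = NULL) {
  stopifnot(inherits(rates, "rate_set"))
  kin_types <- match.arg(kin_types, KIN_TYPES_ONE_SEX, several.ok = TRUE)
  if (!all(t_start:t_end %in% rates$years))
    stop("rate set does not cover the projection window", call. = FALSE)
  if (!all(output_years %in% t_start:t_end))
    stop("`output_years` must lie inside the projection window", call. = FALSE)
  ages <- rates$ages
  A <- length(ages)
  getf <- function(t) rates$fertility[, as.character(t)]
  getp <- function(t) rates$survival[, as.character(t)]
  getpi <- function(t) {
    if (is.null(mothers_dist))
      return(mothers_age_distribution(getf(t), rates$population[, as.character(t)]))
    pi0 <- if (is.matrix(mothers_dist)) mothers_dist[, as.character(t)] else mothers_dist
    if (length(pi0) != A || any(pi0 < 0) || abs(sum(pi0) - 1) > 1e-8)
      stop("`mothers_dist` must be a probability vector over the age axis",
           call. = FALSE)
    pi0
  }
  output_years <- sort(as.integer(output_years))
  out <- lapply(KIN_TYPES_ONE_SEX,
                function(tp) array(0, c(A, A, length(output_years))))
  names(out) <- KIN_TYPES_ONE_SEX
  grid <- kin_seed_invariant(getf(t_start), getp(t_start), getpi(t_start), A)
  store <- function(grid, t) {
    yi <- match(t, output_years)
    if (!is.na(yi))
      for (tp in KIN_TYPES_ONE_SEX) out[[tp]][, , yi] <<- grid[[tp]]
  }
  store(grid, t_start)
  if (t_end > t_start) {
    for (t in t_start:(t_end - 1L)) {
      grid <- kin_step(grid, getf(t), getp(t), getpi(t + 1L), A)
      store(grid, t + 1L)
    }
  }
  kin_tensor(out[kin_types], ages, output_years, rates$group, "one")
}

#' Scale one-sex kin counts to approximate kin of both sexes
#'
#' Applies the Goodman-Keyfitz-Pullum factors -- powers of two that count kin
#' of both sexes through both parental lines under identical male and female
#' rates: 2 for children, parents, and siblings (older and younger combined);
#' 4 for grandchildren, grandparents, nieces/nephews, and aunts/uncles; 8 for
#' great-grandchildren, great-grandparents, and cousins.
#'
#' @param kin A one-sex [kin_tensor()]; applying the scaling twice is an
#'   error.
#' @return A two-sex [kin_tensor()] with two-sex kin type labels.
#' @export
two_sex_scale <- function(kin) {
  stopifnot(inherits(kin, "kin_tensor"))
  if (kin$sex == "two")
    stop("kin tensor is already two-sex scaled", call. = FALSE)
  cnt <- list()
  for (tp in names(kin$counts)) {
    tw <- ONE_TO_TWO_SEX[[tp]]
    add <- kin$counts[[tp]] * GKP_FACTORS[[tw]]
    cnt[[tw]] <- if (is.null(cnt[[tw]])) add else cnt[[tw]] + add
  }
  kin_tensor(cnt[intersect(KIN_TYPES_TWO_SEX, names(cnt))],
             kin$ages, kin$years, kin$group, "two")
}

# totals over kin age: named list of focal-age x year matrices
kin_totals <- function(kin) {
  lapply(kin$counts, function(a) {
    m <- colSums(a)
    if (is.null(dim(m))) m <- matrix(m, ncol = length(kin$years))
    dimnames(m) <- list(kin$ages, kin$years)
    m
  })
}

#' Expected kin counts by type, focal age, and year
#'
#' Sums each kin type's age distribution over kin ages.
#'
#' @param kin A [kin_tensor()].
#' @param focal_ages Focal ages to report (default: full age axis).
#' @param years Years to report (default: all projected years).
#' @return Data frame with columns `group`, `sex`, `kin_type`, `focal_age`,
#'   `year`, `expected_count`.
#' @export
kin_count_table <- function(kin, focal_ages = kin$ages, years = kin$years) {
  stopifnot(inherits(kin, "kin_tensor"))
  if (!all(focal_ages %in% kin$ages))
    stop("requested focal ages outside the projected grid", call. = FALSE)
  if (!all(years %in% kin$years))
    stop("requested years outside the projected grid", call. = FALSE)
  tot <- kin_totals(kin)
  rows <- lapply(names(tot), function(tp) {
    m <- tot[[tp]][as.character(focal_ages), as.character(years), drop = FALSE]
    data.frame(group = kin$group, sex = kin$sex, kin_type = tp,
               focal_age = rep(focal_ages, times = length(years)),
               year = rep(years, each = length(focal_ages)),
               expected_count = as.vector(m))
  })
  do.call(rbind, rows)
}
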