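GENETIC_WEIGHTS <- c(
  children = 1, parents = 1, siblings = 1,
  grandchildren = 0.5, grandparents = 0.5, aunts_uncles = 0.5,
  nieces_nephews = 0.5,
  great_grandchildren = 0.25, great_grandparents = 0.25, cousins = 0.25
)

#' Kin-weighting schemes for aggregate dementia burden
#'
#' Returns the weight attached to each kin type when aggregating across the
#' network: `all_kin` weights every type 1; `parents_and_siblings` keeps only
#' parents and siblings (all children of the focal's parents, the focal
#' herself excluded); `genetic` weights types by genetic closeness -- 1 for
#' parents, children, and siblings (half their genes shared), 0.5 for
#' grandparents, grandchildren, aunts/uncles, and nieces/nephews (a quarter),
#' and 0.25 for great-grandparents, great-grandchildren, and cousins (an
#' eighth).
#'
#' @param scheme One of `"all_kin"`, `"parents_and_siblings"`, `"genetic"`.
#' @param kin_types Kin type labels (one-sex or two-sex) to weight.
#' @return Named numeric vector of weights over `kin_types`.
#' @export
kin_weight_scheme <- function(scheme = c("all_kin", "parents_and_siblings",
                                         "genetic"),
                              kin_types) {
  scheme <- match.arg(scheme)
  category <- ifelse(kin_types %in% names(ONE_TO_TWO_SEX),
                     ONE_TO_TWO_SEX[kin_types], kin_types)
  unknown <- setdiff(category, KIN_TYPES_TWO_SEX)
  if (length(unknown))
    stop("unknown kin types: ", paste(unknown, collapse = ", "), call. = FALSE)
  w <- switch(scheme,
    all_kin = rep(1, length(kin_types)),
    parents_and_siblings = as.numeric(category %in% c("parents", "siblings")),
    genetic = unname(GENETIC_WEIGHTS[category])
  )
  names(w) <- kin_types
  w
}

# validate that a prevalence matrix covers the tensor's ages and years,
# returning it with the tensor's column order
align_psi <- function(kin, psi) {
  if (!is.matrix(psi))
    stop("`psi` must be an age-by-year matrix", call. = FALSE)
  if (nrow(psi) != length(kin$ages) ||
      !identical(as.integer(rownames(psi)), kin$ages))
    stop("prevalence age axis does not match the kin tensor", call. = FALSE)
  miss <- setdiff(as.character(kin$years), colnames(psi))
  if (length(miss))
    stop("prevalence missing years: ", paste(miss, collapse = ", "),
         call. = FALSE)
  psi[, as.character(kin$years), drop = FALSE]
}

#' Expected number of kin with dementia
#'
#' Applies age-specific dementia prevalence to each kin type's age
#' distribution: \eqn{y_K(x,t) = \sum_a \Psi(a,t)\, k_K(a,x,t)}, and
#' aggregates across types with the weights of a kin-weighting scheme.
#'
#' @param kin A [kin_tensor()].
#' @param psi Prevalence matrix (rows = the tensor's age axis, columns named
#'   by year, covering the tensor's years).
#' @param scheme Kin-weighting scheme, see [kin_weight_scheme()].
#' @return Object of class `dementia_burden`: list with `by_type` (focal-age
#'   by year matrices), `total` (weighted aggregate), `weights`, `scheme`,
#'   `ages`, `years`, `group`.
#' @export
expected_kin_with_dementia <- function(kin, psi, scheme = "all_kin") {
  stopifnot(inherits(kin, "kin_tensor"))
  psi <- align_psi(kin, psi)
  w <- kin_weight_scheme(scheme, names(kin$counts))
  Ty <- length(kin$years)
  by_type <- lapply(kin$counts, function(a) {
    m <- vapply(seq_len(Ty),
                function(yi) colSums(psi[, yi] * a[, , yi]),
                numeric(length(kin$ages)))
    dimnames(m) <- list(kin$ages, kin$years)
    m
  })
  total <- Reduce(`+`, Map(`*`, by_type, as.list(w)))
  structure(list(by_type = by_type, total = total, weights = w,
                 scheme = scheme, ages = kin$ages, years = kin$years,
                 group = kin$group),
            class = "dementia_burden")
}

#' Probability of having at least one kin with dementia
#'
#' Under a Poisson approximation for the number of kin with dementia with
#' mean `y`, the probability of at least one is \eqn{1 - e^{-y}}.
#'
#' @param y Expected number of kin with dementia (non-negative scalar,
#'   vector, or matrix).
#' @return `1 - exp(-y)`, preserving the shape of `y`; values lie in \[0, 1)
#'   and never exceed `y`.
#' @export
prob_at_least_one <- function(y) {
  if (any(!is.finite(y)) || any(y < 0))
    stop("expected counts must be finite and non-negative", call. = FALSE)
  1 - exp(-y)
}

#' Age-specific Dementia Dependency Ratio
#'
#' The DDR of a focal individual aged `x` in year `t` is the expected number
#' of kin with dementia divided by the expected number of working-age
#' (default 16--64) kin without dementia:
#' \deqn{DDR(x,t) = y(x,t) / \sum_K w_K \sum_{a \in 16..64}
#'   (1 - \Psi(a,t)) k_K(a,x,t).}
#' Cells with a zero denominator are undefined and returned as `NA`, never as
#' zero.
#'
#' @inheritParams expected_kin_with_dementia
#' @param working_ages Integer ages treated as working-age (default 16:64).
#' @return Object of class `ddr_series`: list with `ddr`, `numerator`,
#'   `denominator` (focal-age by year matrices), `scheme`, `working_ages`,
#'   `ages`, `years`, `group`.
#' @export
ddr <- function(kin, psi, scheme = "all_kin", working_ages = 16:64) {
  stopifnot(inherits(kin, "kin_tensor"))
  psi <- align_psi(kin, psi)
  wa <- intersect(as.integer(working_ages), kin$ages)
  if (!length(wa)) stop("empty working-age window", call. = FALSE)
  burden <- expected_kin_with_dementia(kin, psi, scheme)
  w <- burden$weights
  wi <- match(wa, kin$ages)
  Ty <- length(kin$years)
  denom <- 0
  for (tp in names(kin$counts)) {
    a <- kin$counts[[tp]]
    d <- vapply(seq_len(Ty),
                function(yi) colSums((1 - psi[wi, yi]) * a[wi, , yi]),
                numeric(length(kin$ages)))
    denom <- denom + w[[tp]] * d
  }
  dimnames(denom) <- list(kin$ages, kin$years)
  ratio <- burden$total / denom
  ratio[denom == 0] <- NA_real_
  structure(list(ddr = ratio, numerator = burden$total, denominator = denom,
                 scheme = scheme, working_ages = wa, ages = kin$ages,
                 years = kin$years, group = kin$group),
            class = "ddr_series")
}

#' @export
print.ddr_series <- function(x, ...) {
  cat(sprintf("<ddr_series> group '%s', scheme '%s', working ages %d-%d, years %d-%d\n",
              x$group, x$scheme, min(x$working_ages), max(x$working_ages),
              min(x$years), max(x$years)))
  invisible(x)
}

#' Probability of at least one kin with dementia, by kin type
#'
#' Applies the prevalence overlay per kin type and converts the expected
#' count to an at-least-one probability under the Poisson approximation.
#'
#' @inheritParams expected_kin_with_dementia
#' @param kin_types Kin types to report (default: all types in the tensor).
#' @param focal_ages Focal ages to report (default 16:64).
#' @param years Years to report (default: all projected years).
#' @return Data frame with columns `group`, `kin_type`, `focal_age`, `year`,
#'   `expected_with_dementia`, `p_at_least_one`.
#' @export
prevalence_among_kin_table <- function(kin, psi, kin_types = names(kin$counts),
                                       focal_ages = 16:64, years = kin$years) {
  stopifnot(inherits(kin, "kin_tensor"))
  unknown <- setdiff(kin_types, names(kin$counts))
  if (length(unknown))
    stop("unknown kin types: ", paste(unknown, collapse = ", "), call. = FALSE)
  focal_ages <- intersect(as.integer(focal_ages), kin$ages)
  if (!all(years %in% kin$years))
    stop("requested years outside the projected grid", call. = FALSE)
  burden <- expected_kin_with_dementia(kin, psi, "all_kin")
  rows <- lapply(kin_types, function(tp) {
    y <- burden$by_type[[tp]][as.character(focal_ages), as.character(years),
                              drop = FALSE]
    data.frame(group = kin$group, kin_type = tp,
               focal_age = rep(focal_ages, times = length(years)),
               year = rep(years, each = length(focal_ages)),
               expected_with_dementia = as.vector(y),
               p_at_least_one = as.vector(prob_at_least_one(y)))
  })
  do.call(rbind, rows)
}
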