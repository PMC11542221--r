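# Small-world schedules (omega = 30, early fertility, heavy mortality) keep
# projection and microsimulation tests fast; the full axis (omega = 100) is
# used where prevalence above 65 matters.

small_world_spec <- function(label = "S", ...) {
  synth_group_spec(label = label, omega = 30L, tfr = 1.8, fert_mean = 13,
                   fert_sd = 3, fert_ages = c(8L, 20L), gompertz_a = 0.01,
                   gompertz_b = 0.12, makeham = 0.005, prev_mid = 24, ...)
}

small_world_rates <- function(years = 2000, ...) {
  synth_rates(small_world_spec(...), years)
}

full_world_rates <- function(years = 2016, ...) {
  synth_rates(synth_group_spec(...), years)
}

# manual rate set on the small-world axis from explicit hazard/fertility
manual_rates <- function(f, m, omega = 30L, years = 2000L,
                         population = NULL) {
  ages <- 0:omega
  A <- length(ages)
  Ty <- length(years)
  fm <- matrix(rep(f, Ty), A, Ty)
  sv <- mortality_to_survival(matrix(rep(m, Ty), A, Ty))
  if (is.null(population)) population <- sv$lx
  rate_set("manual", ages, years, fertility = fm, survival = sv$p,
           lx = sv$lx, population = population)
}

# total kin of one type by focal age for one year
type_totals <- function(kin, type, year = kin$years[1L]) {
  colSums(kin$counts[[type]][, , match(year, kin$years)])
}
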