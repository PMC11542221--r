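test_that("abridged survivorship interpolates linearly and reproduces knots", {
  lx <- interpolate_abridged_survivorship(c(0, 5, 10), c(1, 0.9, 0.8))
  expect_equal(unname(lx[c("0", "5", "10")]), c(1, 0.9, 0.8))
  expect_equal(unname(lx["2"]), 0.96)
  expect_equal(unname(lx["7"]), 0.86)

  # a complete single-age table passes through unchanged
  ages <- 0:20
  full <- exp(-0.05 * ages)
  full[1] <- 1
  expect_equal(unname(interpolate_abridged_survivorship(ages, full)), full)
})

test_that("interpolated survivorship is non-increasing for random monotone tables", {
  set.seed(42)
  for (i in 1:20) {
    knots <- c(0, sort(sample(1:99, 8)), 100)
    lx <- c(1, cumprod(runif(length(knots) - 1, 0.6, 1)))
    out <- interpolate_abridged_survivorship(knots, lx)
    expect_length(out, 101)
    # brute-force pointwise scan
    expect_true(all(diff(out) <= 1e-12))
  }
})

test_that("non-monotone abridged input is rejected with offending ages named", {
  expect_error(interpolate_abridged_survivorship(c(0, 5, 10), c(1, 0.8, 0.9)),
               "5-10")
  expect_error(interpolate_abridged_survivorship(c(0, 5, 5), c(1, 0.9, 0.8)),
               "increasing")
})

test_that("Kannisto fit recovers parameters exactly on noiseless hazards", {
  a <- 0.01
  b <- 0.1
  ages <- 0:85
  mu <- a * exp(b * ages) / (1 + a * exp(b * ages))
  fit <- kannisto_extrapolate(mu, ages)
  expect_lt(abs(fit$a - a) / a, 1e-6)
  expect_lt(abs(fit$b - b) / b, 1e-6)
  expect_equal(max(fit$ages), 100)
  # extension equals the generating logistic hazard
  ext <- a * exp(b * 86:100) / (1 + a * exp(b * 86:100))
  expect_equal(fit$hazard[fit$ages >= 86], ext, tolerance = 1e-9)
})

test_that("extrapolated hazards are strictly inside (0, 1)", {
  set.seed(7)
  for (i in 1:10) {
    a <- runif(1, 1e-4, 0.1)
    b <- runif(1, 0.05, 0.15)
    mu <- a * exp(b * 0:85) / (1 + a * exp(b * 0:85))
    fit <- kannisto_extrapolate(mu, 0:85)
    expect_true(all(fit$hazard > 0 & fit$hazard < 1))
  }
})

test_that("degenerate Kannisto fit falls back to a constant extension", {
  mu <- rep(0.2, 86)
  expect_warning(fit <- kannisto_extrapolate(mu, 0:85), "degenerate")
  expect_true(fit$fallback)
  expect_true(all(fit$hazard[fit$ages > 85] == 0.2))
  expect_error(kannisto_extrapolate(rep(0, 86), 0:85), "strictly in")
})

test_that("grouped rates expand constant-within-group and zero outside", {
  g <- data.frame(age_lo = c(15, 20, 25), age_hi = c(19, 24, 29),
                  value = c(0.05, 0.1, 0.08))
  f <- expand_grouped_rates(g)
  expect_equal(unname(f["21"]), 0.1)
  expect_equal(unname(f["23"]), 0.1)
  expect_equal(unname(f["15"]), 0.05)
  # beyond the observed range the rate is zero
  expect_true(all(f[as.character(c(0:14, 30:100))] == 0))
  expect_true(all(f[as.character(50:100)] == 0))
  # arithmetic identity: full 5-year groups sum to 5 x group-rate sum
  expect_equal(sum(f), 5 * sum(g$value))
})

test_that("grouped-rate expansion rejects overlap and is idempotent on single ages", {
  bad <- data.frame(age_lo = c(15, 18), age_hi = c(19, 24), value = c(1, 2))
  expect_error(expand_grouped_rates(bad), "overlap")
  single <- data.frame(age_lo = 10:20, age_hi = 10:20, value = runif(11))
  f <- expand_grouped_rates(single)
  expect_equal(unname(f[as.character(10:20)]), single$value)
})

test_that("prevalence surface is zero before 65 and interpolates at midpoints", {
  g <- expand.grid(year = 2000, lo = seq(65, 95, 5))
  g <- data.frame(year = g$year, age_lo = g$lo, age_hi = g$lo + 4,
                  value = seq(0.05, 0.4, length.out = 7))
  psi <- build_prevalence(g)
  expect_true(all(psi[as.character(0:64), ] == 0))
  # midpoint anchoring: value at a group midpoint equals the group value
  expect_equal(unname(psi["67", "2000"]), 0.05)
  expect_equal(unname(psi["97", "2000"]), 0.4)
})

test_that("prevalence interpolation lies on the line between adjacent midpoints", {
  g <- data.frame(year = 2000, age_lo = c(65, 70), age_hi = c(69, 74),
                  value = c(0.1, 0.2))
  psi <- build_prevalence(g)
  # midpoints 67 and 72; brute-force pointwise evaluation of the line
  for (a in 67:72) {
    expect_equal(unname(psi[as.character(a), "2000"]),
                 0.1 + (a - 67) * (0.2 - 0.1) / (72 - 67))
  }
  # clamped constant beyond the outermost midpoints
  expect_equal(unname(psi["65", "2000"]), 0.1)
  expect_equal(unname(psi["100", "2000"]), 0.2)
})

test_that("prevalence gap years carry the preceding year forward and project constant", {
  g <- data.frame(year = c(2000, 2002), age_lo = 65, age_hi = 69,
                  value = c(0.1, 0.3))
  psi <- build_prevalence(g, through_year = 2005)
  expect_equal(psi[, "2001"], psi[, "2000"])
  expect_equal(psi[, "2003"], psi[, "2002"])
  expect_equal(psi[, "2005"], psi[, "2002"])
  expect_error(build_prevalence(data.frame(year = 2000, age_lo = 65,
                                           age_hi = 69, value = 1.2)),
               "\\[0, 1\\]")
})

test_that("mortality-to-survival uses the constant-hazard convention", {
  z <- mortality_to_survival(rep(0, 10))
  expect_equal(z$p, rep(1, 10))
  expect_equal(z$lx, rep(1, 10))
  expect_equal(mortality_to_survival(0.693147)$p, 0.5, tolerance = 1e-6)
  set.seed(3)
  m <- runif(20, 0, 0.5)
  z <- mortality_to_survival(m)
  # cumulative-product oracle
  for (x in seq_along(m)) {
    expect_equal(z$lx[x], prod(exp(-m)[seq_len(x - 1)]))
  }
  expect_error(mortality_to_survival(c(0.1, -0.2)), "non-negative")
})

test_that("boundary extension copies edge years and fills the full grid", {
  mat <- matrix(1:6, 2, 3, dimnames = list(0:1, 2000:2002))
  ext <- extend_rates_boundary(mat, 1995:2005)
  expect_equal(colnames(ext), as.character(1995:2005))
  expect_equal(unname(ext[, "1995"]), unname(mat[, "2000"]))
  expect_equal(unname(ext[, "2005"]), unname(mat[, "2002"]))
  expect_equal(unname(ext[, "2001"]), unname(mat[, "2001"]))
  expect_false(anyNA(ext))
  expect_error(extend_rates_boundary(mat[, 0, drop = FALSE], 2000:2001),
               "empty")
})

test_that("regularize_rates assembles a valid rate set from raw tables", {
  ages <- 0:100
  # abridged survivorship to 85 (Kannisto extension needed)
  kn <- seq(0, 85, 5)
  lx <- exp(-(5e-4 * kn + 3e-5 / 0.095 * (exp(0.095 * kn) - 1)))
  lx[1] <- 1
  mort <- data.frame(year = 1980, age = kn, lx = lx)
  fert <- data.frame(year = 1980,
                     age_lo = seq(10, 45, 5), age_hi = seq(14, 49, 5),
                     value = c(0.01, 0.08, 0.12, 0.1, 0.06, 0.02, 0.005, 0.001))
  pop <- data.frame(year = 1980, age = ages, value = exp(-0.01 * ages))
  prev <- data.frame(year = 2000, age_lo = seq(65, 95, 5),
                     age_hi = seq(69, 99, 5),
                     value = seq(0.05, 0.35, length.out = 7))
  rs <- regularize_rates(fert, mort, pop, prev, group = "g",
                         analysis_years = 1970:2010)
  expect_s3_class(rs, "rate_set")
  expect_equal(rs$years, 1970:2010)
  expect_false(anyNA(rs$fertility) || anyNA(rs$survival) ||
                 anyNA(rs$prevalence) || anyNA(rs$population))
  expect_true(all(apply(rs$lx, 2, function(col) all(diff(col) <= 1e-12))))
  expect_true(all(rs$prevalence[ages < 65, ] == 0))
  # fertility zero beyond the observed window
  expect_true(all(rs$fertility[as.character(50:100), ] == 0))
})
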