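# worked-example tensor: place given counts at (kin age, focal age) cells
cell_tensor <- function(cells, type = "children", ages = 0:100, year = 2016,
                        sex = "two") {
  A <- length(ages)
  arr <- array(0, c(A, A, 1))
  for (cl in cells) arr[cl[1] + 1, cl[2] + 1, 1] <- cl[3]
  kin_tensor(stats::setNames(list(arr), type), ages, year, sex = sex)
}

psi_matrix <- function(values = numeric(0), ages = 0:100, year = 2016) {
  psi <- matrix(0, length(ages), 1, dimnames = list(ages, year))
  for (a in names(values)) psi[a, 1] <- values[[a]]
  psi
}

test_that("expected kin with dementia is the prevalence-weighted kin count", {
  # 2 kin aged 80 with prevalence 0.25 -> 0.5 expected
  kin <- cell_tensor(list(c(80, 40, 2)))
  psi <- psi_matrix(c("80" = 0.25))
  y <- expected_kin_with_dementia(kin, psi)
  expect_equal(unname(y$total["40", "2016"]), 0.5)
  # zero prevalence -> zero burden
  y0 <- expected_kin_with_dementia(kin, psi_matrix())
  expect_true(all(y0$total == 0))
})

test_that("burden matches a brute-force double loop on projected kin", {
  rs <- full_world_rates(2016)
  kin <- two_sex_scale(project_kin(rs))
  psi <- rs$prevalence
  y <- expected_kin_with_dementia(kin, psi, "all_kin")
  for (x in c(30, 60)) {
    acc <- 0
    for (tp in names(kin$counts)) {
      for (a in 0:100) acc <- acc + psi[a + 1, 1] * kin$counts[[tp]][a + 1, x + 1, 1]
    }
    expect_equal(unname(y$total[as.character(x), 1]), acc, tolerance = 1e-12)
  }
})

test_that("at-least-one probability follows the Poisson closed form", {
  expect_equal(prob_at_least_one(0), 0)
  expect_equal(prob_at_least_one(0.1), 1 - exp(-0.1))
  expect_lt(abs(prob_at_least_one(50) - 1), 1e-12)
  y <- seq(0, 10, by = 0.01)
  p <- prob_at_least_one(y)
  expect_true(all(p >= 0 & p < 1))
  expect_true(all(p <= y))             # Poisson bound, equality only at 0
  expect_true(all(diff(p) > 0))        # strictly increasing
  expect_error(prob_at_least_one(-0.1), "non-negative")
})

test_that("DDR reproduces the worked ratio and zero-prevalence identity", {
  # ten working-age kin without dementia, one expected kin with dementia
  kin <- cell_tensor(list(c(40, 60, 10), c(90, 60, 4)))
  psi <- psi_matrix(c("90" = 0.25))
  d <- ddr(kin, psi)
  expect_equal(unname(d$numerator["60", 1]), 1)
  expect_equal(unname(d$denominator["60", 1]), 10)
  expect_equal(unname(d$ddr["60", 1]), 0.1)
  # zero prevalence: DDR is zero wherever defined
  d0 <- ddr(kin, psi_matrix())
  expect_true(all(d0$ddr[!is.na(d0$ddr)] == 0))
  # zero denominator is undefined, not zero
  expect_true(is.na(d$ddr["20", 1]))
})

test_that("DDR equals the brute-force ratio of the two sums", {
  rs <- full_world_rates(2016)
  kin <- two_sex_scale(project_kin(rs))
  psi <- rs$prevalence
  d <- ddr(kin, psi, "genetic")
  w <- kin_weight_scheme("genetic", names(kin$counts))
  x <- 50
  num <- den <- 0
  for (tp in names(kin$counts)) {
    for (a in 0:100) {
      k <- kin$counts[[tp]][a + 1, x + 1, 1]
      num <- num + w[[tp]] * psi[a + 1, 1] * k
      if (a >= 16 && a <= 64) den <- den + w[[tp]] * (1 - psi[a + 1, 1]) * k
    }
  }
  expect_equal(unname(d$ddr[as.character(x), 1]), num / den, tolerance = 1e-12)
})

test_that("with onset-65 prevalence the denominator equals the working-age kin count", {
  rs <- full_world_rates(2016)
  kin <- two_sex_scale(project_kin(rs))
  d <- ddr(kin, rs$prevalence)
  plain <- 0
  for (tp in names(kin$counts))
    plain <- plain + colSums(kin$counts[[tp]][17:65, , 1])
  expect_equal(unname(d$denominator[, 1]), unname(plain), tolerance = 1e-12)
})

test_that("genetic weights never exceed the all-kin aggregate and DDR is scale-free", {
  rs <- full_world_rates(2016)
  kin <- two_sex_scale(project_kin(rs))
  psi <- rs$prevalence
  y_all <- expected_kin_with_dementia(kin, psi, "all_kin")$total
  y_gen <- expected_kin_with_dementia(kin, psi, "genetic")$total
  expect_true(all(y_gen <= y_all + 1e-12))
  # DDR invariant to uniform rescaling of all kin counts
  kin_scaled <- kin_tensor(lapply(kin$counts, function(a) a * 3.7),
                           kin$ages, kin$years, kin$group, "two")
  expect_equal(ddr(kin_scaled, psi)$ddr, ddr(kin, psi)$ddr,
               tolerance = 1e-12)
})

test_that("weighting schemes assign the documented weights", {
  w <- kin_weight_scheme("genetic", KIN_TYPES_TWO_SEX)
  expect_equal(unname(w[c("parents", "children", "siblings")]), rep(1, 3))
  expect_equal(unname(w[c("grandparents", "grandchildren", "aunts_uncles",
                          "nieces_nephews")]), rep(0.5, 4))
  expect_equal(unname(w[c("great_grandparents", "great_grandchildren",
                          "cousins")]), rep(0.25, 3))
  ws <- kin_weight_scheme("parents_and_siblings", KIN_TYPES_ONE_SEX)
  expect_equal(sum(ws), 3)  # mothers + older and younger sisters
  expect_equal(unname(ws[c("mothers", "older_sisters", "younger_sisters")]),
               rep(1, 3))
  expect_error(kin_weight_scheme("all_kin", "stepmothers"), "unknown kin")
})

test_that("per-type at-least-one probabilities behave at the boundaries", {
  # a type with no kin has probability zero
  kin <- cell_tensor(list(c(80, 30, 1)))
  psi1 <- psi_matrix(c("80" = 1))
  tab <- prevalence_among_kin_table(kin, psi1, focal_ages = 30)
  expect_equal(tab$expected_with_dementia, 1)
  expect_equal(tab$p_at_least_one, 1 - exp(-1))
  tab0 <- prevalence_among_kin_table(kin, psi1, focal_ages = 20)
  expect_equal(tab0$p_at_least_one, 0)
  expect_error(prevalence_among_kin_table(kin, psi1, kin_types = "uncles"),
               "unknown kin")
})

test_that("at-least-one probability is monotone in prevalence", {
  rs <- full_world_rates(2016)
  kin <- two_sex_scale(project_kin(rs))
  psi_lo <- rs$prevalence
  psi_hi <- pmin(psi_lo * 1.5, 1)
  t_lo <- prevalence_among_kin_table(kin, psi_lo)
  t_hi <- prevalence_among_kin_table(kin, psi_hi)
  expect_true(all(t_hi$p_at_least_one >= t_lo$p_at_least_one - 1e-12))
})
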