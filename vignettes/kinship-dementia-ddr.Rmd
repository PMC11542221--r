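---
title: "Projecting kinship networks and the Dementia Dependency Ratio"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Projecting kinship networks and the Dementia Dependency Ratio}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kinddr)
```

## The problem

Most care for older adults with dementia is provided by family.  How much
caregiving demand falls on a family therefore depends on two things that
demography determines jointly: how many living kin a person has at each age
(children, siblings, nieces and nephews, ...), and how many of those kin are
themselves old enough to have dementia.  Both quantities differ between
population groups whose fertility timing, mortality, and dementia prevalence
differ, and both evolve over calendar time as cohorts with different
demographic histories age.

`kinddr` makes this computable from standard vital-statistics inputs.  Given
age-specific fertility, survival, dementia prevalence, and population
structure for one or more groups, it projects the expected age distribution
of each kin type of a focal individual across focal ages and calendar years,
overlays prevalence on those distributions, and aggregates the result into a
single population-level index — the Dementia Dependency Ratio (DDR) — whose
between-group gap can be decomposed with counterfactual ingredient swaps.

## The kinship model

Each kin type of a focal individual (assumed female in the one-sex model,
and conditioned to be alive at every age considered) is treated as its own
age-structured population and projected with matrix population models under
time-varying rates.  Writing $k(a, x, t)$ for the expected number of kin of
a given type aged $a$ when the focal is aged $x$ in year $t$, one projection
step is

$$ k(\cdot, x+1, t+1) = U(t)\,k(\cdot, x, t) + \beta(x,t)\,e_1, $$

where $U(t)$ is the survival operator of year $t$ (subdiagonal entries
$p(a,t)$, survivors beyond age $\omega = 100$ dropped) and $\beta$ is the
type-specific recruitment of newborn kin at age 0:

* daughters are recruited by the focal's own fertility $f(x,t)$;
* granddaughters by fertility applied to the current daughter distribution,
  and great-granddaughters analogously from granddaughters;
* younger sisters by fertility applied to the mother distribution;
* nieces by fertility applied to the combined sister distribution;
* cousins by fertility applied to the aunt distribution;
* mothers, grandmothers, great-grandmothers, older sisters, and aunts
  receive no recruitment.

Boundary conditions at focal age 0 come from the mothers' age distribution
at the focal's birth, $\pi_x(t) = f(x,t)\,n(x,t) / \sum_y f(y,t)\,n(y,t)$:
the mother distribution is $\pi$ itself, and every other ancestor-side type
is the $\pi$-mixture of the corresponding grids of women already alive
(older sisters are the $\pi$-mixture of daughters-of-a-woman-aged-$i$, aunts
of her sisters, nieces of her granddaughters, cousins of her nieces,
grandmothers of her mothers, and so on).  These definitions are circular
across kin types but acyclic in dependency order, so the implementation
solves them topologically.

**Seeding.**  The first projection year needs fully formed grids for all
focal ages.  The grid is seeded with the stationary solution under constant
first-year rates, solved exactly column by column in topological order.
This is mathematically identical to an infinite burn-in under rates
boundary-extended backwards in time, which is also why the rate container
backfills years before the first data year with the first observed schedule:
kin of cohorts born before the data window can only ever see those copied
rates.  A test asserts the fixed-point property directly: under
time-invariant rates the projection step leaves the seeded grid unchanged to
machine precision.

**Two-sex scaling.**  The one-sex matrilineal counts are scaled by the
Goodman–Keyfitz–Pullum factors, which assume identical male and female
rates: 2 for children, parents, and siblings; 4 for grandchildren,
grandparents, nieces/nephews, and aunts/uncles; 8 for great-grandchildren,
great-grandparents, and cousins.  The scaling is exact arithmetic and is
guarded against double application.

**Deliberate simplifications.**  Aunts receive no recruitment after the
focal's birth: aunts born later are ignored, a small flow because
grandmothers are mostly post-reproductive by then.  Older and younger
sisters are projected separately (their boundary and recruitment structures
differ) and reported combined as siblings.  The focal's own survival is
never applied — all results condition on a living focal.  Kin aged past 100
are dropped, consistent with truncating the life table at 100.

## Schedule regularization

Published schedules rarely arrive on a complete single-year grid, so the
rate container applies a fixed set of preprocessing rules, each implemented
as an exported function with the convention stated in its help page:

* **Abridged survivorship** is linearly interpolated between published ages
  (`interpolate_abridged_survivorship`), reproducing knots exactly.
* **Old-age mortality** for tables that stop before 100 is extended with the
  Kannisto logistic hazard $\mu(x) = a e^{bx}/(1+a e^{bx})$
  (`kannisto_extrapolate`), with $(a, b)$ estimated by OLS on
  logit-transformed hazards over ages 70–85 by default (configurable); the
  estimator recovers the parameters of noiseless logistic hazards to better
  than $10^{-6}$ relative error.  A non-positive fitted slope triggers a
  warning and a constant-hazard extension instead.
* **Grouped fertility** (5-year groups) is expanded constant-within-group,
  with zero fertility outside the observed age window
  (`expand_grouped_rates`).
* **Mortality rates** convert to survival with the constant-hazard
  convention $p = e^{-m}$ (`mortality_to_survival`), which keeps $p$ in
  (0,1] for any non-negative rate.
* **Grouped prevalence** is anchored at group midpoints, linearly
  interpolated across single ages, clamped constant beyond the outermost
  midpoints, zero below 65, with gap estimate years carrying the preceding
  year forward and years beyond the last estimate held constant
  (`build_prevalence`).  Midpoint anchoring is the least-biased
  deterministic reading of "linear interpolation" over groups.
* **Boundary extension** copies the first/last observed year outward
  (`extend_rates_boundary`).

## The overlay and the DDR

With $\Psi(a,t)$ the prevalence of dementia at age $a$ (zero before 65), the
expected number of kin with dementia of a focal aged $x$ is the dot product
$y(x,t) = \Psi(t)^\top k(x,t)$, summed over kin types with scheme weights.
Under a Poisson approximation the probability of at least one such kin is
$1 - e^{-y}$.  The age-specific DDR divides the expected kin with dementia
by the expected working-age (16–64) kin without dementia:

$$ DDR(x,t) = \frac{y(x,t)}{\sum_K w_K \sum_{a=16}^{64}
   (1-\Psi(a,t))\,k_K(a,x,t)}. $$

Because prevalence is zero below 65 while working ages end at 64, the
denominator numerically equals the working-age kin count; the implementation
still computes the general $(1-\Psi)$ form, and a test confirms the equality
under onset-65 prevalence.  Cells with a zero denominator are undefined and
propagate as `NA`, never as zero.

Three kin-weighting schemes are provided: `all_kin` (every type weighted 1),
`parents_and_siblings` (only parents and all children of the focal's
parents; the focal is not counted as her own caregiver — her own dementia
status is outside $k$), and `genetic` (weights 1, 0.5, 0.25 mirroring shared
gene fractions of 1/2, 1/4, 1/8).

The population-level index weights the age-specific DDR by the population's
proportional age distribution, $DDR^{pop}(t) = \sum_x w_x(t) DDR(x,t)$, with
$w$ restricted to focal ages 16–64 — the ages at which the DDR is defined —
and renormalized there (also over any ages whose DDR is undefined).  This
makes $DDR^{pop}$ a convex combination of age-specific values, a property
asserted in the tests.  The restriction to 16–64 (rather than all ages) is a
design choice; both the working-age window and the averaging window are
arguments.

**Counterfactuals.**  `run_scenario` recomputes $DDR^{pop}$ with the three
ingredients — kinship structure (kin tensor), prevalence, and population
weights — drawn from possibly different groups.  Counterfactual 1 keeps a
group's own kinship and weights but swaps in the reference group's
prevalence; counterfactual 2 uses the reference group's kinship *and*
weights with the group's own prevalence (population structure is treated as
part of the kinship side of the swap, since it weights the same group's
focal individuals).  Identity and monotonicity checks (equal inputs give
identical series; pointwise-lower prevalence never raises the series) are
part of the test suite.

## The synthetic generator and what it does (not) emulate

`synth_group_spec`/`synth_rates` generate closed-form schedules with the
qualitative structure of the real inputs:

* fertility: a truncated-normal shape on ages 14–54 (default mean 28, sd 6)
  scaled so the age-sum equals the total fertility rate exactly (default
  1.9);
* mortality: Gompertz–Makeham hazards (defaults $a = 3\times10^{-5}$,
  $b = 0.095$, background $4\times10^{-4}$), giving survival near zero by
  age 100;
* prevalence: zero before 65, logistic rise (default midpoint 86, steepness
  0.13) to a plateau (default 0.35) approached by 100;
* population: the stationary population implied by the year's survivorship;
* optional linear secular trend multipliers per year.

`two_group_fixture` derives a stylized disadvantaged group from the
advantaged baseline: TFR +0.4, childbearing 3 years earlier, hazards scaled
by 1.5, prevalence plateau +0.10 with a 2-year-earlier rise — earlier
childbearing, higher fertility, higher mortality, and pointwise-higher
prevalence, the qualitative contrast the two-group analyses need.  These
defaults are round, demographically plausible magnitudes for a stylized
high/low-risk contrast; they are fixed constants of the fixture, not tuning
knobs.

The generator is deliberately smooth and trend-linear.  It does not emulate
period shocks (wars, pandemics, baby booms), cohort heaping, migration, or
any feedback of prevalence on mortality.  Tests passing on these schedules
therefore establish the correctness of the *mechanics* — projection,
overlay, aggregation — not the realism of any particular published estimate
derived from real vital statistics.

## The microsimulation oracle

`microsim_kinship` is an independent stochastic implementation of the same
matrilineal process, used to validate the matrix projections: mothers' ages
drawn from $\pi$, deaths drawn from the exact conditional death-age
distribution implied by $p$, births as Bernoulli events per living
woman-year with probability $\min(f, 1)$ (which matches the expectation
structure for the small per-age rates in use), and the same recruitment
timing convention (a birth at parent age $a$ enters at age 0 one year
later).  It simulates mothers, daughters, granddaughters, grandmothers,
older and younger sisters, aunts (those alive or born by the focal birth,
matching the projection's aunt boundary condition), and nieces;
great-granddaughters, great-grandmothers, and cousins are excluded and
listed as such in the result object.

The agreement test runs on a small world — $\omega = 30$, fertile ages 8–20,
heavy mortality — chosen so that 10,000 replicates complete in about a
second while exercising every recruitment and boundary pathway.  Matrix
expectations must agree with Monte-Carlo means within 3 standard errors at
every focal age for every simulated type (plus a small absolute floor of
$10^{-6}$ kin for cells whose sampling variance is zero).

## Numerical choices and degenerate inputs

* All grids are dense matrices/arrays; no iteration-to-convergence anywhere —
  the stationary seed is an exact topological solve, so results carry no
  tolerance beyond floating-point rounding.
* Undefined DDR cells are `NA` and excluded with weight renormalization; a
  year whose every weighted age is undefined is an error, not a silent zero.
* `mothers_age_distribution` rejects schedules with zero total births; for
  degenerate experiments (e.g. zero fertility) an explicit `mothers_dist`
  can be supplied to `project_kin` and `microsim_kinship`.
* Non-monotone survivorship, overlapping age groups, prevalence outside
  \[0,1\], and negative rates are rejected with diagnostics naming the
  offending values rather than silently repaired.
* Whether prevalence should be sex-specific is left to the caller: the rate
  set carries one prevalence surface per group, which may be female, male,
  or combined; the one-sex kinship model plus two-sex scaling implicitly
  applies it to kin of both sexes.

## Problem sizes

The default pipeline projects 101 ages over a 1940–2060 window in a few
seconds per group.  The test suite uses reduced windows (e.g. rate years
1950–2012 with kin years 2005–2012) and the $\omega = 30$ small world for
the microsimulation; these sizes were chosen as the smallest that exercise
every code path with comfortable margins, and the vignette's claims are all
re-derived by the suite at those sizes.

## Known limitations

Expectations only — the model carries no distributional information about
kin counts beyond the Poisson approximation used for the at-least-one
probability.  Stepkin and affinal kin are out of scope, as are within-group
heterogeneity, dementia severity staging, and actual caregiving hours.  The
aunt-recruitment simplification slightly undercounts aunts/uncles and hence
cousins at young focal ages.  The two-sex factors assume identical male and
female rates; where male mortality is materially higher, two-sex counts of
older kin are optimistic.
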