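Package: kinddr
Title: Kinship Networks, Dementia Prevalence Overlay, and the Dementia
    Dependency Ratio
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Projects the expected age distribution of eleven kin types of a
    focal individual from age-specific fertility and mortality schedules using
    time-varying matrix kinship models, with a Goodman-Keyfitz-Pullum two-sex
    scaling.  Overlays age-specific dementia prevalence on the projected kin
    age distributions to obtain expected numbers of kin with dementia,
    Poisson at-least-one-kin probabilities, and an age-specific Dementia
    Dependency Ratio (kin with dementia per working-age kin without dementia),
    aggregated into population-weighted series with counterfactual group
    swaps of prevalence and kinship structure.  Includes schedule
    regularization tools (abridged life-table interpolation, Kannisto old-age
    mortality extrapolation, grouped-rate expansion, prevalence
    interpolation), a deterministic synthetic rate-set generator, and a
    stochastic kinship microsimulation used as an independent check of the
    matrix projections.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
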