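#' Configuration for an end-to-end pipeline run
#'
#' @param groups Named list of group inputs: each element a [rate_set()] or a
#'   [synth_group_spec()] (generated over `years`).  `NULL` uses the default
#'   [two_group_fixture()].
#' @param years Year window the rate sets must cover (default 1940:2060).
#' @param kin_years Years retained in the kin tensors and the kin-level
#'   tables (default 2000:2060).
#' @param ddr_years Years of the population-DDR series (default 2010:2060).
#' @param scheme Kin-weighting scheme, see [kin_weight_scheme()].
#' @param working_ages DDR denominator ages (default 16:64).
#' @param focal_ages Focal ages of the population average (default 16:64).
#' @param reference_group Group supplying the swapped ingredient in the
#'   counterfactuals (default: first group).
#' @param out_dir Directory for CSV outputs, manifest, and log; `NULL` skips
#'   writing.
#' @param seed Integer seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return An object of class `run_config`.
#' @export
run_config <- function(groups = NULL, years = 1940:2060,
                       kin_years = 2000:2060, ddr_years = 2010:2060,
                       scheme = "all_kin", working_ages = 16:64,
                       focal_ages = 16:64, reference_group = NULL,
                       out_dir = NULL, seed = 1L) {
  structure(list(groups = groups, years = as.integer(years),
                 kin_years = as.integer(kin_years),
                 ddr_years = as.integer(ddr_years), scheme = scheme,
                 working_ages = as.integer(working_ages),
                 focal_ages = as.integer(focal_ages),
                 reference_group = reference_group,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' The file may set any [run_config()] field; `groups` entries are either
#' `synthetic:` blocks of [synth_group_spec()] parameters or `files:` blocks
#' with `fertility`, `mortality`, `population`, and optional `prevalence`
#' CSV paths (columns as in [regularize_rates()], read relative to the
#' configuration file).
#'
#' @param path Path to a YAML configuration file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(path)
  expand_years <- function(x, default) {
    if (is.null(x)) return(default)
    if (length(x) == 2L) x[1L]:x[2L] else as.integer(x)
  }
  years <- expand_years(cfg$years, 1940:2060)
  groups <- NULL
  if (!is.null(cfg$groups)) {
    groups <- lapply(names(cfg$groups), function(g) {
      spec <- cfg$groups[[g]]
      if (!is.null(spec$synthetic)) {
        do.call(synth_group_spec, c(list(label = g), spec$synthetic))
      } else if (!is.null(spec$files)) {
        rd <- function(p) utils::read.csv(file.path(base, p))
        regularize_rates(
          fertility = rd(spec$files$fertility),
          mortality = rd(spec$files$mortality),
          population = rd(spec$files$population),
          prevalence = if (!is.null(spec$files$prevalence))
            rd(spec$files$prevalence),
          group = g, analysis_years = years
        )
      } else {
        stop("group '", g, "' must declare `synthetic` or `files`",
             call. = FALSE)
      }
    })
    names(groups) <- names(cfg$groups)
  }
  run_config(
    groups = groups, years = years,
    kin_years = expand_years(cfg$kin_years, 2000:2060),
    ddr_years = expand_years(cfg$ddr_years, 2010:2060),
    scheme = if (is.null(cfg$scheme)) "all_kin" else cfg$scheme,
    working_ages = expand_years(cfg$working_ages, 16:64),
    focal_ages = expand_years(cfg$focal_ages, 16:64),
    reference_group = cfg$reference_group,
    out_dir = if (is.null(cfg$out_dir)) NULL else file.path(base, cfg$out_dir),
    seed = if (is.null(cfg$seed)) 1L else as.integer(cfg$seed)
  )
}

#' Run the full projection and overlay pipeline
#'
#' Executes the stages in order for every group -- schedule preparation, kin
#' projection with two-sex scaling, prevalence overlay, age-specific DDR, and
#' population-weighted DDR with the factual and both counterfactual
#' scenarios -- and returns (optionally writes) tidy tables: expected kin
#' counts, at-least-one-kin-with-dementia probabilities, age-specific DDR
#' with its numerator and denominator, population DDR per scenario, and
#' between-group gap series.  Counterfactual 1 keeps each group's own kinship
#' structure and population weights but swaps in the reference group's
#' prevalence; counterfactual 2 uses the reference group's kinship structure
#' and weights with each group's own prevalence.
#'
#' @param config A [run_config()].
#' @return (Invisibly) a list with `rates`, `kin_counts`, `kin_prevalence`,
#'   `ddr_age`, `ddr_pop`, `gaps`, and `manifest`.  With `out_dir` set, each
#'   table is also written as CSV together with `manifest.json` and a
#'   stage-level `pipeline.log`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  log_lines <- character(0)
  say <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    log_lines <<- c(log_lines, line)
    message(line)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  groups <- config$groups
  if (is.null(groups)) groups <- two_group_fixture(config$years)
  rates <- stage("vital_rates", {
    out <- lapply(names(groups), function(g) {
      x <- groups[[g]]
      rs <- if (inherits(x, "rate_set")) x else synth_rates(x, config$years)
      if (!all(config$years %in% rs$years))
        stop("rate set for group '", g, "' does not cover the year window")
      rs
    })
    names(out) <- names(groups)
    out
  })
  for (g in names(rates))
    say("vital_rates: group '%s' regularized (%d ages x %d years)", g,
        length(rates[[g]]$ages), length(rates[[g]]$years))
  ref <- if (is.null(config$reference_group)) names(rates)[1L] else
    config$reference_group
  if (!ref %in% names(rates))
    stop("reference group '", ref, "' not among groups", call. = FALSE)

  data <- stage("kinship_model", {
    lapply(rates, function(rs) {
      kin1 <- project_kin(rs, output_years = config$kin_years)
      list(kin = two_sex_scale(kin1), prevalence = rs$prevalence,
           population = rs$population)
    })
  })
  for (g in names(data))
    say("kinship_model: group '%s' projected, %d two-sex kin types, years %d-%d",
        g, length(data[[g]]$kin$counts), min(config$kin_years),
        max(config$kin_years))

  kin_counts <- stage("kin_counts", {
    do.call(rbind, lapply(names(data), function(g)
      kin_count_table(data[[g]]$kin)))
  })
  say("kin_counts: %d rows", nrow(kin_counts))

  kin_prevalence <- stage("dementia_overlay", {
    do.call(rbind, lapply(names(data), function(g)
      prevalence_among_kin_table(data[[g]]$kin, data[[g]]$prevalence,
                                 focal_ages = config$focal_ages)))
  })
  say("dementia_overlay: %d rows", nrow(kin_prevalence))

  ddr_age <- stage("ddr_age", {
    do.call(rbind, lapply(names(data), function(g) {
      dd <- ddr(data[[g]]$kin, data[[g]]$prevalence, config$scheme,
                config$working_ages)
      fa <- as.character(config$focal_ages)
      yy <- as.character(config$kin_years)
      data.frame(group = g, scheme = config$scheme,
                 focal_age = rep(config$focal_ages,
                                 times = length(config$kin_years)),
                 year = rep(config$kin_years, each = length(config$focal_ages)),
                 kin_with_dementia = as.vector(dd$numerator[fa, yy]),
                 working_age_kin_without = as.vector(dd$denominator[fa, yy]),
                 ddr = as.vector(dd$ddr[fa, yy]))
    }))
  })
  say("ddr_age: %d rows", nrow(ddr_age))

  ddr_pop <- stage("population_ddr", {
    rows <- list()
    for (g in names(data)) {
      sp <- function(kin_src, prev_src, w_src) {
        scenario_spec(kin_src, prev_src, w_src, config$scheme,
                      config$ddr_years, config$working_ages,
                      config$focal_ages)
      }
      add <- function(label, spec_obj) {
        s <- run_scenario(spec_obj, data)
        rows[[length(rows) + 1L]] <<-
          data.frame(scenario = label, group = g, year = s$year,
                     ddr_pop = s$ddr_pop)
      }
      add("factual", sp(g, g, g))
      if (g != ref) {
        add("cf1_reference_prevalence", sp(g, ref, g))
        add("cf2_reference_kinship", sp(ref, g, ref))
      }
    }
    do.call(rbind, rows)
  })
  say("population_ddr: %d rows (%d scenarios)", nrow(ddr_pop),
      length(unique(ddr_pop$scenario)))

  gaps <- stage("gap_series", {
    fact <- split(ddr_pop[ddr_pop$scenario == "factual", ],
                  ddr_pop$group[ddr_pop$scenario == "factual"])
    others <- setdiff(names(data), ref)
    if (!length(others)) NULL else do.call(rbind, lapply(others, function(g) {
      gg <- gap_series(fact[[g]], fact[[ref]])
      data.frame(group = g, reference = ref, year = gg$year, gap = gg$gap)
    }))
  })

  manifest <- list(
    package = "kinddr",
    version = as.character(utils::packageVersion("kinddr")),
    r_version = R.version.string,
    seed = config$seed,
    groups = names(rates),
    reference_group = ref,
    years = range(config$years),
    kin_years = range(config$kin_years),
    ddr_years = range(config$ddr_years),
    scheme = config$scheme,
    working_ages = range(config$working_ages),
    focal_ages = range(config$focal_ages)
  )

  result <- list(rates = rates, kin_counts = kin_counts,
                 kin_prevalence = kin_prevalence, ddr_age = ddr_age,
                 ddr_pop = ddr_pop, gaps = gaps, manifest = manifest)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    wr <- function(df, name) {
      if (is.null(df)) return(invisible())
      path <- file.path(config$out_dir, paste0(name, ".csv"))
      utils::write.csv(df, path, row.names = FALSE)
      say("wrote %s (%d rows)", path, nrow(df))
    }
    wr(do.call(rbind, lapply(rates, schedules_table)), "schedules")
    wr(kin_counts, "kin_counts")
    wr(kin_prevalence, "kin_prevalence")
    wr(ddr_age, "ddr_age")
    wr(ddr_pop, "ddr_pop")
    wr(gaps, "ddr_gaps")
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    writeLines(log_lines, file.path(config$out_dir, "pipeline.log"))
  }
  invisible(result)
}
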