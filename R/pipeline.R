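#' Fit the classification and cost models on synthetic estimation surveys
#'
#' Convenience wrapper reproducing the estimation stage of the pipeline on
#' generated fixtures: the cognitive survey for the multivariate probit, the
#' frailty survey for the logistic model, and the claims extract for the
#' health-care use regressions. Survey sizes default to study-like values
#' (the frailty survey has 1952 respondents).
#'
#' @param truth a [truth_parameters()] object
#' @param seed integer seed
#' @param n_cognitive,n_frailty,n_claims fixture sizes
#' @param config optional [generator_config()] for covariate draws
#' @return list of class `fitted_models`: `probit`, `frailty`, `cost_params`
#' @export
fit_pipeline_models <- function(truth = truth_parameters(), seed = 1L,
                                n_cognitive = 8000, n_frailty = 1952,
                                n_claims = 8000,
                                config = generator_config(seed = seed)) {
  cog <- generate_cognitive_survey(n_cognitive, truth, derive_seed(seed, 101L),
                                   config = config)
  fr <- generate_frailty_survey(n_frailty, truth, derive_seed(seed, 102L),
                                config = config)
  cl <- generate_utilization_claims(n_claims, truth, derive_seed(seed, 103L),
                                    config = config)
  structure(list(
    probit = fit_cognitive_probit(cog),
    frailty = fit_frailty_logit(fr),
    cost_params = cost_parameters(fit_healthcare_use(cl))
  ), class = "fitted_models")
}

#' Classify a population snapshot
#'
#' Applies the fitted probit and logistic models with the given thresholds:
#' sets `dementia_state` (normal/MCI/dementia), `frail` (FALSE below the
#' frailty threshold's minimum age) and the derived `dependency` tier on
#' alive persons; dead persons keep their last state.
#'
#' @param snapshot population `data.table`
#' @param models a [fit_pipeline_models()] list
#' @param thresholds list with `cognition` ([calibrate_thresholds()]) and
#'   `frailty` ([calibrate_frailty_threshold()])
#' @return the classified snapshot (a copy)
#' @export
classify_snapshot <- function(snapshot, models, thresholds) {
  snap <- data.table::copy(data.table::as.data.table(snapshot))
  if (!"dementia_state" %in% names(snap)) snap[, dementia_state := "normal"]
  if (!"frail" %in% names(snap)) snap[, frail := FALSE]
  alive_idx <- which(snap$alive)
  if (length(alive_idx)) {
    live <- snap[alive_idx]
    grp <- if (!is.null(thresholds$cognition$by_groups)) live$sex
    probs <- predict_impairment_probability(models$probit, live)
    snap[alive_idx, dementia_state := classify_cognition(probs, thresholds$cognition,
                                                         by = grp)]
    grp_f <- if (!is.null(thresholds$frailty$by_groups)) live$sex
    pfr <- predict_frailty_probability(models$frailty, live)
    snap[alive_idx, frail := classify_frailty(pfr, thresholds$frailty,
                                              age = live$age, by = grp_f)]
  }
  snap[, dependency := assign_dependency_level(snap)]
  snap[]
}

#' Calibrate thresholds on a baseline population
#'
#' @param population baseline population `data.table`
#' @param models a [fit_pipeline_models()] list
#' @param target a [generate_target_prevalence()] curve
#' @param granularity `"overall"` (default: one global threshold pair
#'   matched to the population-wide target) or `"sex"` (per-sex thresholds
#'   matched to each sex's own target)
#' @return list with `cognition` and `frailty` threshold objects and an
#'   `achieved_by_cell` validation table (achieved prevalence per age band
#'   and sex at the calibrated thresholds)
#' @export
calibrate_pipeline_thresholds <- function(population, models, target,
                                          granularity = c("overall", "sex")) {
  granularity <- match.arg(granularity)
  by <- if (granularity == "sex") population$sex
  probs <- predict_impairment_probability(models$probit, population)
  cognition <- calibrate_thresholds(probs, population, target, by = by)
  pfr <- predict_frailty_probability(models$frailty, population)
  frailty <- calibrate_frailty_threshold(pfr, population, target, by = by)

  labels <- classify_cognition(probs, cognition, by = by)
  frail <- classify_frailty(pfr, frailty, age = population$age, by = by)
  achieved <- data.table::data.table(
    sex = population$sex, age_band = age_band(population$age),
    dementia = labels == "dementia", mci = labels == "MCI", frail = frail
  )[, .(dementia = mean(dementia), mci = mean(mci), frailty = mean(frail),
        n = .N), by = .(sex, age_band)][order(sex, age_band)]
  list(cognition = cognition, frailty = frailty, achieved_by_cell = achieved)
}

#' Prevalence summary of a classified snapshot
#'
#' Counts and proportions of MCI, dementia, frailty and the
#' dementia-and-frailty intersection by sex and age group (>= 60, 60-74,
#' >= 75), optionally education-stratified, with counts also scaled by the
#' per-sex national weights.
#'
#' @param snapshot classified snapshot
#' @param year reporting year attached to the rows
#' @param weights named per-sex scaling factors (default 1)
#' @param by_education add an education-stratified block
#' @return `data.table` with columns `year`, `sex`, `education`, `age_group`,
#'   `condition`, `count`, `population`, `proportion`, `count_weighted`,
#'   `population_weighted`
#' @export
snapshot_prevalence <- function(snapshot, year, weights = c(female = 1, male = 1),
                                by_education = FALSE) {
  snap <- data.table::as.data.table(snapshot)
  live <- snap[alive == TRUE & age >= 60]
  live[, age_group := ifelse(age >= 75, "75+", "60-74")]
  live[, `:=`(
    is_mci = dementia_state == "MCI",
    is_dementia = dementia_state == "dementia",
    is_frail = !is.na(frail) & as.logical(frail)
  )]
  live[, is_both := is_dementia & is_frail]

  count_block <- function(d, edu_label) {
    blocks <- list()
    for (grp in list(c("60+", "60-74", "75+")[1], "60-74", "75+")) {
      sel <- if (grp == "60+") rep(TRUE, nrow(d)) else d$age_group == grp
      dd <- d[sel]
      agg <- dd[, .(
        mci = sum(is_mci), dementia = sum(is_dementia),
        frailty = sum(is_frail), dementia_and_frailty = sum(is_both),
        population = .N
      ), by = sex]
      agg <- data.table::melt(agg, id.vars = c("sex", "population"),
                              variable.name = "condition", value.name = "count",
                              variable.factor = FALSE)
      agg[, age_group := grp]
      blocks[[grp]] <- agg
    }
    out <- data.table::rbindlist(blocks)
    out[, education := edu_label]
    out
  }

  res <- count_block(live, "all")
  if (by_education) {
    edu <- data.table::rbindlist(lapply(EDUCATION_LEVELS, function(e) {
      count_block(live[education == e], e)
    }))
    res <- data.table::rbindlist(list(res, edu), use.names = TRUE)
  }
  res[, `:=`(
    year = year,
    proportion = ifelse(population > 0, count / population, NA_real_),
    count_weighted = count * weights[sex],
    population_weighted = population * weights[sex]
  )]
  data.table::setcolorder(res, c("year", "sex", "education", "age_group",
                                 "condition", "count", "population",
                                 "proportion"))
  res[]
}

#' Run one full projection of the pipeline
#'
#' A single end-to-end iteration: draw the stochastic baseline population,
#' simulate half-year transitions with annual entry cohorts over the
#' horizon, calibrate classification thresholds at baseline, classify every
#' reporting snapshot, and derive prevalence tables, Sullivan
#' life-expectancy partitions and cost tables at the presentation years.
#'
#' @param config a [generator_config()]; its `seed` is overridden by `seed`
#' @param models a [fit_pipeline_models()] list (estimated coefficients are
#'   held fixed across bootstrap iterations)
#' @param target a [generate_target_prevalence()] curve
#' @param horizon_years projection horizon (default 27, a 3-year grid)
#' @param present_years years for cost/life-expectancy outputs (default the
#'   9-year grid over the horizon)
#' @param seed iteration seed driving all simulation randomness
#' @param params optional pre-built [transition_parameters()]
#' @param le_terminal_age open-interval age for the period life tables
#' @param le_abridged use 5-year life-table intervals (default TRUE)
#' @param by_education education-stratified prevalence rows
#' @param threshold_granularity `"overall"` for one global threshold pair
#'   (default) or `"sex"` for per-sex calibration
#' @return list of class `projection_run`: `prevalence`, `life_expectancy`,
#'   `cost_totals`, `cost_headline`, `cost_per_capita`, `thresholds`,
#'   `weights`, `manifest`
#' @export
run_projection <- function(config, models, target = generate_target_prevalence(),
                           horizon_years = 27, present_years = NULL,
                           seed = config$seed, params = NULL,
                           le_terminal_age = 90, le_abridged = TRUE,
                           by_education = FALSE,
                           threshold_granularity = c("overall", "sex")) {
  threshold_granularity <- match.arg(threshold_granularity)
  cfg <- config
  cfg$seed <- derive_seed(seed, 7L)
  if (is.null(params)) {
    params <- generate_transition_parameters(cfg, horizon_years = horizon_years + 1)
  }
  pop <- generate_baseline_population(cfg)
  baseline <- population_state(pop, cfg$start_year)

  n_by_sex <- table(pop$sex)
  weights <- cfg$national_population[SEX_LEVELS] / as.numeric(n_by_sex[SEX_LEVELS])
  names(weights) <- SEX_LEVELS

  thresholds <- calibrate_pipeline_thresholds(pop, models, target,
                                              granularity = threshold_granularity)

  traj <- simulate_population(baseline, params, horizon_years,
                              report_interval = 3, seed = derive_seed(seed, 8L),
                              config = cfg)
  if (is.null(present_years)) {
    present_years <- seq(cfg$start_year, cfg$start_year + horizon_years, by = 9)
  }

  prev_list <- list()
  le_list <- list()
  cost_totals <- list()
  cost_headline <- list()
  cost_percap <- list()

  for (yr in traj$years) {
    snap <- classify_snapshot(traj$snapshots[[as.character(yr)]], models, thresholds)
    prev_list[[as.character(yr)]] <-
      snapshot_prevalence(snap, yr, weights = weights, by_education = by_education)

    if (yr %in% present_years) {
      # period mortality measured over the year ending at the reporting date
      exp_year <- if (yr == cfg$start_year) yr else yr - 1
      for (s in SEX_LEVELS) {
        lt <- build_period_life_table(traj, exp_year, sex = s,
                                      terminal_age = le_terminal_age,
                                      abridged = le_abridged)
        sp_dem <- sullivan_partition(lt, condition_prevalence(snap, lt, "dementia", sex = s))
        sp_fr <- sullivan_partition(lt, condition_prevalence(snap, lt, "frailty", sex = s))
        le_list[[paste(yr, s)]] <- data.table::data.table(
          year = yr, sex = s,
          measure = c("ex65", "with_dementia", "without_dementia",
                      "with_frailty", "without_frailty"),
          value = c(sp_dem$total_ex, sp_dem$years_with, sp_dem$years_without,
                    sp_fr$years_with, sp_fr$years_without)
        )
      }

      costs <- annual_cost(snap, models$cost_params, seed = derive_seed(seed, 9L + yr))
      w <- weights[snap$sex]
      agg <- aggregate_costs(snap, costs, weight = w)
      ct <- data.table::copy(agg$totals); ct[, year := yr]
      ch <- data.table::copy(agg$headline); ch[, year := yr]
      cp <- data.table::copy(agg$per_capita); cp[, year := yr]
      cost_totals[[as.character(yr)]] <- ct
      cost_headline[[as.character(yr)]] <- ch
      cost_percap[[as.character(yr)]] <- cp
    }
  }

  structure(list(
    prevalence = data.table::rbindlist(prev_list, use.names = TRUE),
    life_expectancy = data.table::rbindlist(le_list, use.names = TRUE),
    cost_totals = data.table::rbindlist(cost_totals, use.names = TRUE),
    cost_headline = data.table::rbindlist(cost_headline, use.names = TRUE),
    cost_per_capita = data.table::rbindlist(cost_percap, use.names = TRUE),
    thresholds = thresholds,
    weights = weights,
    manifest = list(seed = seed, horizon_years = horizon_years,
                    start_year = cfg$start_year,
                    population_size = cfg$population_size,
                    present_years = present_years)
  ), class = "projection_run")
}

# Flatten one projection run into (table, key, value) rows for ensembles.
flatten_run <- function(run) {
  pv <- run$prevalence
  rows <- list(
    data.table::data.table(
      table = "prevalence_count",
      cell = paste(pv$year, pv$sex, pv$education, pv$age_group, pv$condition, sep = "|"),
      value = pv$count_weighted
    ),
    data.table::data.table(
      table = "prevalence_proportion",
      cell = paste(pv$year, pv$sex, pv$education, pv$age_group, pv$condition, sep = "|"),
      value = pv$proportion
    ),
    data.table::data.table(
      table = "life_expectancy",
      cell = paste(run$life_expectancy$year, run$life_expectancy$sex,
                  run$life_expectancy$measure, sep = "|"),
      value = run$life_expectancy$value
    ),
    data.table::data.table(
      table = "cost_total",
      cell = paste(run$cost_totals$year, run$cost_totals$component,
                  run$cost_totals$group, sep = "|"),
      value = run$cost_totals$total
    ),
    data.table::data.table(
      table = "cost_headline",
      cell = paste(run$cost_headline$year, run$cost_headline$component,
                  run$cost_headline$condition, sep = "|"),
      value = run$cost_headline$total
    )
  )
  data.table::rbindlist(rows, use.names = TRUE)
}
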