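#' Transition parameter container
#'
#' Holds the half-year transition probabilities driving the microsimulation:
#' per-condition incidence and all-cause mortality, both indexed by 5-year
#' age band, sex and education; functional-decline probabilities; optional
#' per-condition log-hazard offsets that raise mortality multiplicatively
#' with comorbidity; and the annual entry-cohort schedule.
#'
#' @param incidence `data.table` with columns `condition`, `age_band`, `sex`,
#'   `education`, `p` (half-year probability)
#' @param mortality `data.table` with columns `age_band`, `sex`, `education`,
#'   `p` (half-year probability)
#' @param functional list as in [generator_config()]'s `functional` element
#' @param condition_loghr named numeric vector of log hazard ratios per
#'   condition applied to mortality (use zeros to disable)
#' @param entry_schedule `data.table` with columns `year`, `sex`, `count`,
#'   `share_lths`, `share_hs`, `share_college`
#' @param pre_entry_survival named vector: probability that a scheduled
#'   entrant survives attrition before reaching age 60, per education
#' @return object of class `transition_parameters`
#' @export
transition_parameters <- function(incidence, mortality,
                                  functional = default_functional_params(),
                                  condition_loghr = NULL,
                                  entry_schedule = NULL,
                                  pre_entry_survival = c(lths = 1, hs = 1, college = 1)) {
  incidence <- data.table::as.data.table(incidence)
  mortality <- data.table::as.data.table(mortality)
  check_prob(incidence$p, "incidence probabilities")
  check_prob(mortality$p, "mortality probabilities")
  if (is.null(condition_loghr)) {
    condition_loghr <- setNames(numeric(length(CONDITION_COLS)), CONDITION_COLS)
  }
  # fast lookup structures: one row per populated stratum cell
  mort_keys <- paste(mortality$age_band, mortality$sex, mortality$education,
                     sep = "|")
  if (anyDuplicated(mort_keys)) stop_data("duplicate mortality cells")
  mort_vec <- setNames(mortality$p, mort_keys)
  inc_keys <- unique(paste(incidence$age_band, incidence$sex,
                           incidence$education, sep = "|"))
  inc_mat <- matrix(NA_real_, length(inc_keys), length(CONDITION_COLS),
                    dimnames = list(inc_keys, CONDITION_COLS))
  ik <- paste(incidence$age_band, incidence$sex, incidence$education, sep = "|")
  inc_mat[cbind(match(ik, inc_keys), match(incidence$condition, CONDITION_COLS))] <-
    incidence$p

  obj <- list(
    incidence = data.table::setkeyv(incidence,
                                    c("condition", "age_band", "sex", "education")),
    mortality = data.table::setkeyv(mortality, c("age_band", "sex", "education")),
    functional = functional,
    condition_loghr = condition_loghr,
    entry_schedule = if (!is.null(entry_schedule)) data.table::as.data.table(entry_schedule),
    pre_entry_survival = pre_entry_survival,
    mort_vec = mort_vec, inc_mat = inc_mat
  )
  class(obj) <- "transition_parameters"
  obj
}

#' Population state container
#'
#' A population `data.table` plus calendar time (year + half-year phase).
#'
#' @param population person-level `data.table` as produced by
#'   [generate_baseline_population()]
#' @param calendar_time numeric year, advancing by 0.5 per cycle
#' @return object of class `population_state`
#' @export
population_state <- function(population, calendar_time) {
  population <- data.table::as.data.table(population)
  if (anyDuplicated(population$id)) stop_data("person ids must be unique")
  structure(list(population = population, calendar_time = calendar_time),
            class = "population_state")
}

# Common-random-numbers channels: one uniform per person, step and event so
# that raising a single probability cell can only move outcomes one way.
CRN_CHANNELS <- c("mortality", CONDITION_COLS, "iadl", "adl", "depression", "srh")

step_uniforms <- function(max_id, step_seed) {
  set.seed(step_seed)
  U <- matrix(runif(max_id * length(CRN_CHANNELS)), nrow = max_id)
  colnames(U) <- CRN_CHANNELS
  U
}

#' Advance the population by one half-year Markov cycle
#'
#' Event order per live individual: (1) mortality draw (Gompertz-style base
#' probability from the stratum cell, raised multiplicatively on the hazard
#' scale by current conditions); survivors then take (2) incidence draws for
#' each condition not yet present (conditions never revert), and (3)
#' functional-decline, depression-onset and self-reported-health moves.
#' Ages advance by 0.5 years; dead individuals are frozen.
#'
#' @param state a [population_state()]
#' @param params a [transition_parameters()]
#' @param rng_stream integer seed for this cycle's draws (common random
#'   numbers per person and event channel)
#' @return the advanced `population_state`
#' @export
step_half_year <- function(state, params, rng_stream) {
  pop <- data.table::copy(state$population)
  ai <- which(pop$alive)
  U <- step_uniforms(max(pop$id), rng_stream)

  if (length(ai)) {
    key <- paste(age_band(pop$age[ai]), pop$sex[ai], pop$education[ai], sep = "|")
    q0 <- params$mort_vec[key]
    if (anyNA(q0)) {
      stop_data("missing mortality parameter cell(s): ",
                paste(head(unique(key[is.na(q0)]), 5), collapse = "; "))
    }
    flags <- as.matrix(pop[ai, CONDITION_COLS, with = FALSE])
    lhr <- params$condition_loghr[CONDITION_COLS]
    lhr[is.na(lhr)] <- 0
    if (any(lhr != 0)) {
      h <- -log(pmax(1e-300, 1 - pmin(q0, 1 - 1e-15))) * exp(drop(flags %*% lhr))
      q <- 1 - exp(-h)
      q[q0 >= 1] <- 1
    } else {
      q <- unname(q0)
    }
    ids <- pop$id[ai]
    dies <- U[ids, "mortality"] < q
    if (any(dies)) {
      di <- ai[dies]
      data.table::set(pop, di, "alive", FALSE)
      data.table::set(pop, di, "death_age", pop$age[di] + 0.25)
      data.table::set(pop, di, "death_year", rep(state$calendar_time, length(di)))
    }

    sv <- ai[!dies]
    if (length(sv)) {
      sid <- ids[!dies]
      kidx <- match(key[!dies], rownames(params$inc_mat))
      P <- params$inc_mat[kidx, , drop = FALSE]
      absent <- flags[!dies, , drop = FALSE] == 0L
      if (any(absent & is.na(P))) {
        bad <- which(absent & is.na(P), arr.ind = TRUE)
        stop_data("missing incidence parameter cell(s): ",
                  paste(head(unique(paste(CONDITION_COLS[bad[, 2]],
                                          key[!dies][bad[, 1]])), 5),
                        collapse = "; "))
      }
      hit <- absent & !is.na(P) & (U[sid, CONDITION_COLS, drop = FALSE] < P)
      for (jc in seq_along(CONDITION_COLS)) {
        hj <- hit[, jc]
        if (any(hj)) data.table::set(pop, sv[hj], CONDITION_COLS[jc], 1L)
      }

      fp <- params$functional
      age_s <- pop$age[sv]
      p_iadl <- plogis(fp$iadl_increment[["intercept"]] +
                         fp$iadl_increment[["age_slope"]] * (age_s - 60))
      p_adl <- plogis(fp$adl_increment[["intercept"]] +
                        fp$adl_increment[["age_slope"]] * (age_s - 60))
      p_dep <- plogis(fp$depression_onset[["intercept"]] +
                        fp$depression_onset[["age_slope"]] * (age_s - 60))
      iadl_up <- U[sid, "iadl"] < p_iadl
      adl_up <- U[sid, "adl"] < p_adl
      dep_on <- U[sid, "depression"] < p_dep
      u_srh <- U[sid, "srh"]
      data.table::set(pop, sv, "iadl_limited",
                      pmin(7L, pop$iadl_limited[sv] + as.integer(iadl_up)))
      data.table::set(pop, sv, "adl_limited",
                      pmin(fp$adl_max, pop$adl_limited[sv] + as.integer(adl_up)))
      data.table::set(pop, sv, "depression",
                      pmax(pop$depression[sv], as.integer(dep_on)))
      data.table::set(pop, sv, "srh",
                      pmin(5L, pmax(1L, pop$srh[sv] +
                                      as.integer(u_srh < fp$srh_worsen) -
                                      as.integer(u_srh > 1 - fp$srh_improve))))
      data.table::set(pop, sv, "age", pmin(AGE_CAP, pop$age[sv] + 0.5))
    }
  }
  population_state(pop, state$calendar_time + 0.5)
}

#' Inject the annual entry cohort aged 60-62
#'
#' Appends new individuals for the current calendar year per the entry
#' schedule. Scheduled counts are thinned by pre-entry mortality attrition
#' (binomial with the configured cumulative survival per education stratum),
#' education is drawn from the schedule's shares, ages uniformly from
#' {60, 61, 62}; ids are fresh and unique.
#'
#' @param state a [population_state()]
#' @param params a [transition_parameters()] with an `entry_schedule`
#' @param rng_stream integer seed
#' @param config a [generator_config()] used to draw entrants' health state
#' @return the augmented `population_state`
#' @export
inject_entry_cohort <- function(state, params, rng_stream,
                                config = generator_config(seed = rng_stream)) {
  yr_now <- as.integer(floor(state$calendar_time))
  if (is.null(params$entry_schedule)) stop_data("no entry schedule configured")
  sched <- params$entry_schedule[list(yr_now), on = "year", nomatch = NULL]
  if (nrow(sched) == 0) {
    stop_data("entry schedule does not cover year ", yr_now)
  }
  if (sum(sched$count) == 0) return(state)

  set.seed(derive_seed(rng_stream, 51L))
  groups <- list()
  for (i in seq_len(nrow(sched))) {
    row <- sched[i]
    shares <- c(lths = row$share_lths, hs = row$share_hs, college = row$share_college)
    n_by_edu <- drop(stats::rmultinom(1, row$count, shares))
    for (e in EDUCATION_LEVELS) {
      n_real <- rbinom(1, n_by_edu[e], params$pre_entry_survival[e])
      if (n_real > 0) {
        groups[[length(groups) + 1L]] <- list(sex = row$sex, education = e, n = n_real)
      }
    }
  }
  if (!length(groups)) return(state)

  # health state at entry drawn per stratum so condition prevalences carry
  # the configured sex/education gradients
  entrant_list <- vector("list", length(groups))
  for (k in seq_along(groups)) {
    g <- groups[[k]]
    cfg <- config
    cfg$population_size <- g$n
    cfg$age_range <- c(60L, 62L)
    cfg$female_share <- if (g$sex == "female") 1 else 0
    pm <- setNames(as.numeric(EDUCATION_LEVELS == g$education), EDUCATION_LEVELS)
    cfg$education_shares <- list(female = pm, male = pm)
    cfg$seed <- derive_seed(rng_stream, 52L + k)
    entrant_list[[k]] <- generate_baseline_population(cfg)
  }
  entrants <- data.table::rbindlist(entrant_list, use.names = TRUE)
  max_id <- max(state$population$id)
  entrants[, id := max_id + .I]
  entrants[, entry_year := yr_now]

  pop <- data.table::rbindlist(list(state$population, entrants), use.names = TRUE)
  population_state(pop, state$calendar_time)
}

#' Run the microsimulation over a projection horizon
#'
#' Steps the population in half-year first-order Markov cycles (two per
#' calendar year) with an annual entry cohort, and records snapshots on a
#' reporting grid (default every 3 years). Also accumulates the single-year
#' age exposure (person-years) and death counts per calendar year, sex and
#' education needed for period life tables: each half-year lived contributes
#' 0.5 person-years; a death contributes 0.25 (mid-interval convention).
#'
#' @param baseline a [population_state()] at the start year
#' @param params a [transition_parameters()]
#' @param horizon_years projection horizon, divisible by `report_interval`
#' @param report_interval snapshot spacing in years (default 3)
#' @param seed integer master seed for all transition randomness
#' @param config [generator_config()] used for entry-cohort health states
#' @param inject_entries set `FALSE` for a closed-cohort run
#' @return object of class `trajectory`: list with `snapshots` (named list of
#'   population `data.table`s keyed by year), `exposure` (`data.table` of
#'   `year`, `age`, `sex`, `education`, `py`, `deaths`), `years`, `manifest`
#' @export
simulate_population <- function(baseline, params, horizon_years,
                                report_interval = 3, seed = 1L,
                                config = generator_config(seed = seed),
                                inject_entries = !is.null(params$entry_schedule)) {
  if (horizon_years %% report_interval != 0) {
    stop_config("horizon_years must be divisible by report_interval")
  }
  state <- baseline
  start_year <- floor(state$calendar_time)
  snap_years <- seq(start_year, start_year + horizon_years, by = report_interval)
  snapshots <- list()
  snapshots[[as.character(start_year)]] <- data.table::copy(state$population)
  exposure <- list()

  n_steps <- 2L * horizon_years
  for (step in seq_len(n_steps)) {
    phase_start <- (step %% 2L) == 1L           # first half of a calendar year
    if (phase_start && inject_entries) {
      state <- inject_entry_cohort(state, params, derive_seed(seed, 1000L + step),
                                   config = config)
    }
    before <- state$population
    state <- step_half_year(state, params, derive_seed(seed, 2000L + step))
    after <- state$population

    lived_rows <- which(before$alive)  # row order is preserved by the step
    lived <- before[lived_rows]
    died_now <- after[lived_rows][alive == FALSE]
    exp_dt <- lived[, .(py = 0.5 * .N), by = .(age = floor(age), sex, education)]
    exp_dt[, year := floor(state$calendar_time - 0.5)]
    d_dt <- died_now[, .(deaths = .N, py_adj = -0.25 * .N),
                     by = .(age = floor(age + 0.25), sex, education)]
    d_dt[, year := floor(state$calendar_time - 0.5)]
    exposure[[step]] <- merge(exp_dt, d_dt,
                              by = c("year", "age", "sex", "education"), all = TRUE)

    year_now <- state$calendar_time
    if (year_now %% 1 == 0 && (year_now %in% snap_years)) {
      snapshots[[as.character(year_now)]] <- data.table::copy(state$population)
    }
  }

  exp_all <- data.table::rbindlist(exposure, use.names = TRUE, fill = TRUE)
  if (nrow(exp_all) == 0) {
    exp_all <- data.table::data.table(year = numeric(), age = numeric(),
                                      sex = character(), education = character(),
                                      py = numeric(), deaths = numeric(),
                                      py_adj = numeric())
  }
  for (col in c("py", "deaths", "py_adj")) {
    data.table::set(exp_all, which(is.na(exp_all[[col]])), col, 0)
  }
  exp_all <- exp_all[, .(py = sum(py) + sum(py_adj), deaths = sum(deaths)),
                     by = .(year, age, sex, education)]

  structure(list(
    snapshots = snapshots,
    exposure = exp_all[order(year, age, sex, education)],
    years = snap_years,
    final_state = state,
    manifest = list(seed = seed, horizon_years = horizon_years,
                    report_interval = report_interval,
                    start_year = start_year,
                    n_baseline = nrow(baseline$population))
  ), class = "trajectory")
}
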