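test_that("null dynamics leave the population unchanged except time and age", {
  pop <- make_toy_population(200, age = 70)
  st <- population_state(pop, 2016)
  params <- make_flat_params(q_mort = 0, p_inc = 0)
  st2 <- step_half_year(st, params, rng_stream = 1L)
  expect_equal(st2$calendar_time, 2016.5)
  expect_true(all(st2$population$alive))
  expect_equal(st2$population$age, pop$age + 0.5)
  same_cols <- setdiff(names(pop), "age")
  expect_equal(st2$population[, same_cols, with = FALSE],
               pop[, same_cols, with = FALSE])
})

test_that("certain mortality absorbs everyone in one step", {
  pop <- make_toy_population(150)
  st <- population_state(pop, 2016)
  params <- make_flat_params(q_mort = 1)
  st2 <- step_half_year(st, params, rng_stream = 2L)
  expect_true(all(!st2$population$alive))
  expect_equal(st2$population$death_age, pop$age + 0.25)
  # dead individuals are frozen afterwards
  st3 <- step_half_year(st2, params, rng_stream = 3L)
  expect_equal(st3$population$age, st2$population$age)
})

test_that("survival under constant mortality matches the binomial closed form", {
  n <- 100000
  q <- 0.01
  pop <- make_toy_population(n, age = 70)
  st <- population_state(pop, 2016)
  params <- make_flat_params(q_mort = q)
  st <- step_half_year(st, params, rng_stream = 10L)
  st <- step_half_year(st, params, rng_stream = 11L)
  expected <- n * (1 - q)^2
  se <- sqrt(n * (1 - q)^2 * (1 - (1 - q)^2))
  expect_within(sum(st$population$alive), expected, 3 * se,
                info = "two-step survivors")
})

test_that("a missing stratum cell raises a named error", {
  pop <- make_toy_population(10, age = 70)
  params <- make_flat_params(q_mort = 0.1)
  params$mort_vec <- params$mort_vec[!grepl("70-74\\|female\\|hs",
                                            names(params$mort_vec))]
  st <- population_state(pop, 2016)
  expect_error(step_half_year(st, params, 1L), "70-74",
               class = "demfrailsim_data_error")
})

test_that("entry cohort obeys the schedule, including the empty one", {
  pop <- make_toy_population(50)
  st <- population_state(pop, 2016)
  sched0 <- data.table::data.table(year = 2016L, sex = "female", count = 0L,
                                   share_lths = 0, share_hs = 1, share_college = 0)
  p0 <- make_flat_params(entry_schedule = sched0)
  expect_identical(inject_entry_cohort(st, p0, 1L, config = small_config())$population,
                   st$population)
  expect_error(
    inject_entry_cohort(population_state(pop, 2030), p0, 1L,
                        config = small_config()),
    "2030", class = "demfrailsim_data_error"
  )

  sched1 <- data.table::data.table(year = 2016L, sex = "male", count = 500L,
                                   share_lths = 0, share_hs = 0, share_college = 1)
  p1 <- make_flat_params(entry_schedule = sched1)
  p1$pre_entry_survival[] <- 1
  st2 <- inject_entry_cohort(st, p1, 3L, config = small_config())
  entrants <- st2$population[entry_year == 2016 & id > 50]
  expect_equal(nrow(entrants), 500)
  expect_true(all(entrants$education == "college"))
  expect_true(all(entrants$sex == "male"))
  expect_true(all(entrants$age >= 60 & entrants$age <= 62))
  expect_false(anyDuplicated(st2$population$id) > 0)
})

test_that("pre-entry attrition thins the scheduled count binomially", {
  pop <- make_toy_population(10)
  st <- population_state(pop, 2016)
  s_surv <- 0.9
  sched <- data.table::data.table(year = 2016L, sex = "female", count = 10000L,
                                  share_lths = 1, share_hs = 0, share_college = 0)
  params <- make_flat_params(entry_schedule = sched)
  params$pre_entry_survival[] <- s_surv
  st2 <- inject_entry_cohort(st, params, 7L, config = small_config())
  realized <- nrow(st2$population) - nrow(pop)
  se <- sqrt(10000 * s_surv * (1 - s_surv))
  expect_within(realized, 10000 * s_surv, 3 * se, info = "thinned entrants")
})

test_that("trajectories conserve persons and report on the 3-year grid", {
  cfg <- small_config(1000, seed = 21)
  pop <- generate_baseline_population(cfg)
  params <- generate_transition_parameters(cfg, horizon_years = 10)
  st <- population_state(pop, 2016)
  traj <- simulate_population(st, params, horizon_years = 9, seed = 31, config = cfg)
  expect_equal(traj$years, c(2016, 2019, 2022, 2025))
  expect_named(traj$snapshots, c("2016", "2019", "2022", "2025"))
  for (yr in names(traj$snapshots)) {
    s <- traj$snapshots[[yr]]
    # conservation: every baseline person still present, entrants accounted
    expect_true(all(1:1000 %in% s$id))
    expect_equal(anyDuplicated(s$id), 0L)
    expect_equal(sum(s$alive) + sum(!s$alive), 1000 + sum(s$id > 1000))
  }
  expect_error(simulate_population(st, params, horizon_years = 10, seed = 1,
                                   config = cfg),
               class = "demfrailsim_config_error")
})

test_that("horizon zero returns only the baseline", {
  pop <- make_toy_population(20)
  st <- population_state(pop, 2016)
  params <- make_flat_params()
  traj <- simulate_population(st, params, horizon_years = 0, seed = 1,
                              inject_entries = FALSE)
  expect_equal(names(traj$snapshots), "2016")
  expect_equal(traj$snapshots[["2016"]], pop)
})

test_that("condition flags never revert while alive", {
  cfg <- small_config(800, seed = 22)
  pop <- generate_baseline_population(cfg)
  params <- generate_transition_parameters(cfg, horizon_years = 7)
  st <- population_state(pop, 2016)
  traj <- simulate_population(st, params, horizon_years = 6, seed = 32, config = cfg)
  snaps <- traj$snapshots
  for (i in seq_len(length(snaps) - 1)) {
    a <- snaps[[i]]; b <- snaps[[i + 1]]
    m <- merge(a[, c("id", cond_cols), with = FALSE],
               b[, c("id", cond_cols), with = FALSE], by = "id")
    for (cc in cond_cols) {
      expect_true(all(m[[paste0(cc, ".y")]] >= m[[paste0(cc, ".x")]]),
                  info = paste("non-reversibility of", cc))
    }
  }
})

test_that("raising mortality never increases later survivors (common random numbers)", {
  pop <- make_toy_population(4000, age = 75)
  st <- population_state(pop, 2016)
  run_alive <- function(q) {
    params <- make_flat_params(q_mort = q)
    s <- st
    out <- numeric(6)
    for (k in 1:6) {
      s <- step_half_year(s, params, rng_stream = 100L + k)
      out[k] <- sum(s$population$alive)
    }
    out
  }
  lo <- run_alive(0.02)
  hi <- run_alive(0.05)
  expect_true(all(hi <= lo))
})

test_that("identical seeds reproduce identical trajectories", {
  cfg <- small_config(800, seed = 23)
  pop <- generate_baseline_population(cfg)
  params <- generate_transition_parameters(cfg, horizon_years = 7)
  st <- population_state(pop, 2016)
  t1 <- simulate_population(st, params, horizon_years = 6, seed = 77, config = cfg)
  t2 <- simulate_population(st, params, horizon_years = 6, seed = 77, config = cfg)
  expect_identical(t1$snapshots, t2$snapshots)
  expect_identical(t1$exposure, t2$exposure)
  t3 <- simulate_population(st, params, horizon_years = 6, seed = 78, config = cfg)
  expect_false(identical(t1$snapshots[["2022"]], t3$snapshots[["2022"]]))
})

test_that("probability interval conversions are mutually inverse", {
  p3 <- c(0, 0.1, 0.5, 1)
  expect_equal(threeyr_prob_from_halfyear(halfyear_prob_from_3yr(p3)), p3)
  expect_equal(halfyear_prob_from_3yr(0.26), 1 - (1 - 0.26)^(1 / 6))
})
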