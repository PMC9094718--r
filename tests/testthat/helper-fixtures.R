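# Shared fixtures: tiny populations and flat parameter tables built in code.

cond_cols <- demfrailsim:::CONDITION_COLS

# A minimal population with every column the engine touches.
make_toy_population <- function(n, age = 70, sex = "female", education = "hs",
                                conditions = NULL) {
  pop <- data.table::data.table(
    id = seq_len(n), age = as.numeric(age), sex = sex, education = education
  )
  for (cc in cond_cols) {
    data.table::set(pop, j = cc, value = rep(0L, n))
  }
  if (!is.null(conditions)) {
    for (cc in names(conditions)) {
      data.table::set(pop, j = cc, value = as.integer(rep_len(conditions[[cc]], n)))
    }
  }
  pop[, `:=`(iadl_limited = 0L, adl_limited = 0L, depression = 0L, srh = 3L,
             alive = TRUE, entry_year = 2016, death_age = NA_real_,
             death_year = NA_real_)]
  pop[]
}

# Transition parameters with one flat probability everywhere.
make_flat_params <- function(q_mort = 0, p_inc = 0, loghr = NULL,
                             functional_off = TRUE, entry_schedule = NULL) {
  grid <- data.table::CJ(age_band = demfrailsim:::age_band_levels(),
                         sex = c("female", "male"),
                         education = c("lths", "hs", "college"))
  mortality <- data.table::copy(grid)[, p := q_mort]
  incidence <- data.table::rbindlist(lapply(cond_cols, function(cc) {
    data.table::copy(grid)[, `:=`(condition = cc, p = p_inc)]
  }))
  fp <- demfrailsim:::default_functional_params()
  if (functional_off) {
    fp$iadl_increment[] <- c(-Inf, 0)
    fp$adl_increment[] <- c(-Inf, 0)
    fp$depression_onset[] <- c(-Inf, 0)
    fp$srh_worsen <- 0
    fp$srh_improve <- 0
  }
  transition_parameters(incidence = incidence, mortality = mortality,
                        functional = fp, condition_loghr = loghr,
                        entry_schedule = entry_schedule)
}

# Small generator config used across tests.
small_config <- function(n = 2000, seed = 1) {
  generator_config(population_size = n, seed = seed)
}

# Fitted models are reused across test files; fit once per session.
.test_cache <- new.env(parent = emptyenv())
get_test_models <- function() {
  if (is.null(.test_cache$models)) {
    .test_cache$models <- fit_pipeline_models(truth_parameters(), seed = 2024,
                                              n_cognitive = 4000,
                                              n_frailty = 1952, n_claims = 4000)
  }
  .test_cache$models
}

expect_within <- function(object, expected, tol, info = NULL) {
  expect_true(abs(object - expected) <= tol,
              info = paste0(info, " (got ", object, ", expected ", expected,
                            " +- ", tol, ")"))
}
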