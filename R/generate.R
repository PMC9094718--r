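#' Generate the baseline simulated population
#'
#' Draws `population_size` persons aged within `age_range` with sex,
#' education, the eleven chronic-condition flags, ADL/IADL limitation
#' counts, depression and self-reported health, all from the configured
#' logistic models with age/sex/education gradients. Everyone starts alive.
#'
#' @param config a [generator_config()] object
#' @return a `data.table` with one row per person: `id`, `age` (years, may
#'   be half-integer after simulation), `sex`, `education`, the condition
#'   flags, `adl_limited`, `iadl_limited`, `depression`, `srh` (1 best - 5
#'   worst), `alive`, `entry_year`, `death_age`, `death_year`
#' @export
generate_baseline_population <- function(config) {
  validate_generator_config(config)
  n <- as.integer(config$population_size)
  set.seed(derive_seed(config$seed, 1L))

  ages <- config$age_range[1]:config$age_range[2]
  w <- exp(-0.032 * (ages - 60)) * ifelse(ages > 85, exp(-0.06 * (ages - 85)), 1)
  age <- sample(ages, n, replace = TRUE, prob = w / sum(w))
  sex <- ifelse(runif(n) < config$female_share, "female", "male")
  education <- character(n)
  for (s in SEX_LEVELS) {
    idx <- which(sex == s)
    sh <- config$education_shares[[s]]
    if (length(idx)) {
      education[idx] <- sample(EDUCATION_LEVELS, length(idx), replace = TRUE, prob = sh)
    }
  }

  pop <- data.table::data.table(
    id = seq_len(n), age = as.numeric(age), sex = sex, education = education
  )
  male <- as.numeric(sex == "male")
  edu_lths <- as.numeric(education == "lths")
  edu_college <- as.numeric(education == "college")

  cbl <- config$condition_baseline_logits
  for (cond in CONDITION_COLS) {
    b <- cbl[cond, ]
    eta <- b$intercept + b$age_slope * (age - 75) + b$male * male +
      b$lths * edu_lths + b$college * edu_college
    data.table::set(pop, j = cond, value = as.integer(runif(n) < plogis(eta)))
  }

  fp <- config$functional
  p_iadl <- plogis(fp$baseline_iadl_logit["intercept"] +
                     fp$baseline_iadl_logit["age_slope"] * (age - 60))
  p_adl <- plogis(fp$baseline_adl_logit["intercept"] +
                    fp$baseline_adl_logit["age_slope"] * (age - 60))
  pop[, `:=`(
    iadl_limited = rbinom(n, 7L, p_iadl),
    adl_limited = rbinom(n, fp$adl_max, p_adl),
    depression = as.integer(runif(n) < plogis(
      fp$baseline_depression_logit["intercept"] +
        fp$baseline_depression_logit["age_slope"] * (age - 60)
    ))
  )]
  ncond <- rowSums(as.matrix(pop[, CONDITION_COLS, with = FALSE]))
  pop[, srh := 1L + rbinom(n, 4L, pmin(0.9, 0.25 + 0.06 * ncond))]
  pop[, `:=`(alive = TRUE, entry_year = config$start_year,
             death_age = NA_real_, death_year = NA_real_)]
  data.table::setcolorder(pop, c("id", "age", "sex", "education", CONDITION_COLS))
  pop[]
}

#' Generate half-year transition parameter tables
#'
#' Produces the [transition_parameters()] object driving the simulation:
#' per-condition half-year incidence probabilities and half-year all-cause
#' mortality, indexed by 5-year age band, sex and education, plus
#' functional-decline probabilities and the annual 60-62 entry-cohort
#' schedule. Incidence and mortality are monotonically non-decreasing in
#' age; mortality decreases with higher educational attainment. Mortality
#' follows a Gompertz hazard, `q = 1 - exp(-exp(a + b * age) * 0.5)` per
#' cell, evaluated at band midpoints.
#'
#' @param config a [generator_config()] object
#' @param horizon_years number of calendar years the entry schedule must
#'   cover (default 30)
#' @return a `transition_parameters` object (see [transition_parameters()])
#' @export
generate_transition_parameters <- function(config, horizon_years = 30) {
  validate_generator_config(config)
  bands <- age_band_levels()
  grid <- data.table::CJ(age_band = bands, sex = SEX_LEVELS,
                         education = EDUCATION_LEVELS)
  mid <- age_band_mid(grid$age_band)
  male <- as.numeric(grid$sex == "male")
  edu_lths <- as.numeric(grid$education == "lths")
  edu_college <- as.numeric(grid$education == "college")

  inc_list <- vector("list", length(CONDITION_COLS))
  il <- config$incidence_logits
  for (i in seq_along(CONDITION_COLS)) {
    cond <- CONDITION_COLS[i]
    b <- il[cond, ]
    eta <- b$intercept + b$age_slope * (mid - 75) + b$male * male +
      b$lths * edu_lths + b$college * edu_college
    inc_list[[i]] <- data.table::data.table(
      condition = cond, grid, p = plogis(eta)
    )
  }
  incidence <- data.table::rbindlist(inc_list)

  mp <- config$mortality
  loghaz <- mp$intercept[ifelse(grid$sex == "male", "male", "female")] +
    mp$slope * mid + mp$education[grid$education]
  mortality <- data.table::data.table(grid, p = 1 - exp(-exp(loghaz) * 0.5))

  ep <- config$entry
  years <- config$start_year + seq_len(horizon_years) - 1L
  sched <- list()
  n0 <- config$population_size *
    c(female = config$female_share, male = 1 - config$female_share)
  for (s in SEX_LEVELS) {
    college <- pmin(ep$college_max,
                    ep$college_base + ep$college_trend * (years - config$start_year) +
                      ep$college_sex_offset[s])
    lths <- pmax(ep$lths_min,
                 ep$lths_base + ep$lths_trend * (years - config$start_year))
    hs <- 1 - college - lths
    count <- round(n0[s] * ep$rate * (1 - ep$annual_decline)^(years - config$start_year))
    sched[[s]] <- data.table::data.table(
      year = years, sex = s,
      count = as.integer(count),
      share_lths = lths, share_hs = hs, share_college = college
    )
  }
  entry_schedule <- data.table::rbindlist(sched)

  transition_parameters(
    incidence = incidence, mortality = mortality,
    functional = config$functional,
    condition_loghr = mp$condition_loghr,
    entry_schedule = entry_schedule,
    pre_entry_survival = ep$pre_entry_survival
  )
}

# Shared covariate builders -------------------------------------------------

# Draw survey covariates (age, sex, education, the 11 conditions) from the
# config's baseline models; used by the cognitive/frailty/claims generators.
draw_survey_covariates <- function(n, config, min_age = 60) {
  cfg <- config
  cfg$population_size <- n
  cfg$age_range <- c(max(60L, as.integer(min_age)), cfg$age_range[2])
  generate_baseline_population(cfg)
}

probit_design_matrix <- function(df) {
  ncond <- rowSums(as.matrix(df[, CONDITION_COLS, with = FALSE]))
  cbind(
    intercept = 1, age10 = (df$age - 75) / 10,
    male = as.numeric(df$sex == "male"),
    edu_hs = as.numeric(df$education == "hs"),
    edu_college = as.numeric(df$education == "college"),
    stroke = df$stroke, diabetes = df$diabetes, chd = df$chd,
    ncond = ncond
  )
}

frailty_design_matrix <- function(df) {
  cbind(
    intercept = 1, age10 = (df$age - 75) / 10,
    male = as.numeric(df$sex == "male"),
    edu_hs = as.numeric(df$education == "hs"),
    edu_college = as.numeric(df$education == "college"),
    diabetes = df$diabetes, chd = df$chd, stroke = df$stroke,
    hypertension = df$hypertension, hyperlipidaemia = df$hyperlipidaemia,
    cancer = df$cancer, kidney = df$kidney, depression = df$depression,
    impaired_mobility = impaired_mobility(df)
  )
}

cost_design_matrix <- function(df, count_column = "multimorbidity") {
  ncond <- rowSums(as.matrix(df[, CONDITION_COLS, with = FALSE]))
  count_col <- switch(count_column,
    multimorbidity = as.numeric(ncond >= 3),
    ncond = ncond,
    stop_config("unknown count_column: ", count_column)
  )
  X <- cbind(
    intercept = 1, age10 = (df$age - 75) / 10,
    male = as.numeric(df$sex == "male"),
    as.matrix(df[, CONDITION_COLS, with = FALSE]),
    count_col
  )
  colnames(X)[ncol(X)] <- count_column
  X
}

#' Impaired mobility in daily living
#'
#' Maps the simulated functional state to the binary "impaired mobility"
#' covariate of the frailty model: any basic-ADL limitation, or at least two
#' IADL difficulties.
#'
#' @param df population or survey table with `adl_limited` and `iadl_limited`
#' @param adl_min,iadl_min configurable cutoffs
#' @return 0/1 numeric vector
#' @export
impaired_mobility <- function(df, adl_min = 1L, iadl_min = 2L) {
  as.numeric(df$adl_limited >= adl_min | df$iadl_limited >= iadl_min)
}

#' Generate the cognitive-test survey fixture
#'
#' Emulates a cognitive-function survey: covariates plus ten correlated
#' binary outcomes -- failure on three cognitive tests (immediate recall,
#' delayed recall, serial sevens) and difficulty with seven instrumental
#' activities of daily living -- drawn by thresholding a latent multivariate
#' normal at the per-outcome probit linear predictors.
#'
#' @param n number of respondents
#' @param truth a [truth_parameters()] object
#' @param seed integer seed
#' @param config optional [generator_config()] controlling covariate draws
#' @return `data.table` of covariates plus the ten 0/1 outcome columns
#' @export
generate_cognitive_survey <- function(n, truth, seed,
                                      config = generator_config(seed = seed)) {
  if (n <= 0) stop_config("n must be positive")
  validate_truth_parameters(truth)
  cfg <- config
  cfg$seed <- derive_seed(seed, 21L)
  df <- draw_survey_covariates(n, cfg, min_age = 60)
  X <- probit_design_matrix(df)
  eta <- X %*% t(truth$probit_coefficients)

  R <- truth$probit_correlation
  ch <- tryCatch(chol(R), error = function(e) {
    stop_data("probit_correlation is not positive definite")
  })
  set.seed(derive_seed(seed, 22L))
  Z <- matrix(rnorm(n * nrow(truth$probit_coefficients)), nrow = n) %*% ch
  Y <- (Z <= eta) * 1L
  colnames(Y) <- PROBIT_OUTCOMES
  cbind(df[, c("id", "age", "sex", "education", CONDITION_COLS,
               "adl_limited", "iadl_limited", "depression"), with = FALSE],
        data.table::as.data.table(Y))
}

#' Generate the frailty survey fixture
#'
#' Emulates a community frailty-phenotype survey of people aged 65 and
#' older (default size 1952 respondents): covariates plus a binary frailty
#' phenotype drawn from the logistic truth model over age, sex, education,
#' seven comorbid conditions, depression and impaired mobility.
#'
#' @param n number of respondents (default 1952)
#' @param truth a [truth_parameters()] object
#' @param seed integer seed
#' @param config optional [generator_config()] controlling covariate draws
#' @return `data.table` with covariates, `impaired_mobility`, and 0/1 `frail`
#' @export
generate_frailty_survey <- function(n = 1952, truth = truth_parameters(), seed,
                                    config = generator_config(seed = seed)) {
  if (n <= 0) stop_config("n must be positive")
  validate_truth_parameters(truth)
  cfg <- config
  cfg$seed <- derive_seed(seed, 31L)
  df <- draw_survey_covariates(n, cfg, min_age = 65)
  X <- frailty_design_matrix(df)
  eta <- drop(X %*% truth$frailty_logit_coefficients)
  set.seed(derive_seed(seed, 32L))
  df[, impaired_mobility := X[, "impaired_mobility"]]
  df[, frail := as.integer(runif(n) < plogis(eta))]
  df[]
}

#' Generate the monthly utilization claims fixture
#'
#' Emulates claims extracts with monthly use (in cost units) per person and
#' service type (inpatient vs outpatient + prescription). Expected use is
#' linear in age, sex, the eleven comorbidity flags and a multimorbidity
#' indicator per the truth coefficients, with additive Gaussian noise and a
#' floor at zero; expected use increases with comorbidity burden whenever
#' the truth slopes are positive.
#'
#' @param n number of persons
#' @param truth a [truth_parameters()] object
#' @param seed integer seed
#' @param config optional [generator_config()] controlling covariate draws
#' @return `data.table` with covariates and columns `monthly_inpatient`,
#'   `monthly_outpatient_rx`
#' @export
generate_utilization_claims <- function(n, truth, seed,
                                        config = generator_config(seed = seed)) {
  if (n <= 0) stop_config("n must be positive")
  validate_truth_parameters(truth)
  cfg <- config
  cfg$seed <- derive_seed(seed, 41L)
  df <- draw_survey_covariates(n, cfg, min_age = 60)
  X <- cost_design_matrix(df)
  set.seed(derive_seed(seed, 42L))
  for (svc in c("inpatient", "outpatient_rx")) {
    mu <- drop(X %*% truth$cost_coefficients[[svc]])
    y <- pmax(0, mu + rnorm(n, 0, truth$cost_coefficients$sigma[svc]))
    data.table::set(df, j = paste0("monthly_", svc), value = y)
  }
  df[]
}

#' Build a calibration-target prevalence object
#'
#' Age-band and sex specific target prevalence curves for dementia, MCI and
#' frailty, used by the threshold-calibration step. The default curves are
#' logistic in age, anchored so that the overall 2016-style prevalences in
#' a 60+ population are near 8% (men) / 15% (women) for dementia, around
#' 10% for MCI, and 7% / 11% for frailty, with dementia and frailty rising
#' steeply in age and MCI forming a mid-age plateau.
#'
#' @param curve_params optional `data.table`/`data.frame` with columns
#'   `condition` ("dementia", "mci", "frailty"), `sex`, `age_band`,
#'   `prevalence`; if `NULL` the default curves are tabulated
#' @return object of class `calibration_target`: a `data.table` of the same
#'   four columns, validated to lie in `[0, 1]`
#' @export
generate_target_prevalence <- function(curve_params = NULL) {
  if (is.null(curve_params)) {
    bands <- age_band_levels()
    mid <- age_band_mid(bands)
    grid <- data.table::CJ(sex = SEX_LEVELS, age_band = bands, sorted = FALSE)
    gm <- age_band_mid(grid$age_band)
    male <- grid$sex == "male"
    # intercepts anchor the overall 60+ prevalence, under the default
    # baseline age composition, near the 2016 values observed for Japan:
    # dementia 14.6% women / 8.1% men, MCI ~10.4% / 10.8%, frailty 11.4% /
    # 7.2%; slopes give the steep age rise of dementia and frailty and the
    # flatter mid-age MCI profile
    dementia <- plogis(ifelse(male, -3.06, -2.23) + 0.13 * (gm - 75))
    mci <- plogis(ifelse(male, -2.00, -1.92) + 0.05 * (gm - 75)) *
      (1 - dementia)
    frailty <- plogis(ifelse(male, -3.02, -2.44) + 0.11 * (gm - 75))
    curve_params <- data.table::rbindlist(list(
      data.table::data.table(condition = "dementia", grid, prevalence = dementia),
      data.table::data.table(condition = "mci", grid, prevalence = mci),
      data.table::data.table(condition = "frailty", grid, prevalence = frailty)
    ))
  }
  tgt <- data.table::as.data.table(curve_params)
  need <- c("condition", "sex", "age_band", "prevalence")
  if (!all(need %in% names(tgt))) {
    stop_data("calibration target needs columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(tgt$prevalence)) || any(tgt$prevalence < 0) ||
      any(tgt$prevalence > 1)) {
    stop_data("target prevalence values must lie in [0, 1]")
  }
  structure(tgt[, need, with = FALSE], class = c("calibration_target",
                                                 class(tgt)))
}

#' Population-weighted overall target prevalence
#'
#' Collapses an age-sex target curve to the overall proportion implied for a
#' given population's age-sex composition.
#'
#' @param target a [generate_target_prevalence()] object
#' @param population population `data.table` (alive rows are used)
#' @param condition one of "dementia", "mci", "frailty"
#' @param min_age persons younger than this are treated as unaffected
#' @return single proportion in `[0, 1]`
#' @export
overall_target_prevalence <- function(target, population, condition,
                                      min_age = 60) {
  pop <- population[population$alive & population$age >= 60, ]
  cells <- pop[, .(n = .N), by = .(sex, age_band = age_band(age))]
  cond <- condition
  tt <- data.table::as.data.table(target)[list(cond), on = "condition"]
  m <- merge(cells, tt, by = c("sex", "age_band"), all.x = TRUE)
  if (anyNA(m$prevalence)) {
    miss <- m[is.na(prevalence), paste(sex, age_band, collapse = "; ")]
    stop_data("target curve missing cells: ", miss)
  }
  m[age_band_mid(age_band) < min_age, prevalence := 0]
  sum(m$n * m$prevalence) / sum(m$n)
}
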