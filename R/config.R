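#' Generator configuration
#'
#' Bundles everything the synthetic-data generator needs: the size and
#' age/sex/education composition of the baseline population, per-condition
#' baseline prevalence models, incidence and mortality (Gompertz) parameters,
#' entry-cohort schedule settings, and the RNG seed. Defaults emulate the
#' population of Japan aged 60 and older as of 2016: education shares and
#' age structure follow the census-era composition, Gompertz mortality is
#' calibrated so that period life expectancy at age 65 is about 23.7 years
#' for women and 18.7 for men, and entry cohorts carry a rising share of
#' college education across calendar time.
#'
#' @param population_size number of simulated persons at baseline
#' @param start_year first simulated calendar year
#' @param age_range integer baseline age range, minimum at least 60
#' @param education_shares named list with one numeric vector of three
#'   proportions (lths, hs, college) per sex; each must sum to 1
#' @param female_share proportion of women at baseline
#' @param condition_baseline_logits data.frame of per-condition baseline
#'   prevalence models (intercept at age 75, per-year age slope, male and
#'   education offsets on the log-odds scale)
#' @param incidence_logits data.frame of per-condition half-year incidence
#'   models on the log-odds scale
#' @param mortality list with Gompertz `intercept` per sex (log hazard at age
#'   0), `slope` per year, education offsets, and per-condition log-hazard
#'   offsets applied multiplicatively
#' @param functional list of functional-decline transition parameters
#' @param entry list controlling the annual 60-62 entry cohorts
#' @param national_population named total population represented per sex,
#'   used when scaling per-person results to national totals
#' @param seed integer RNG seed for the run
#' @return an object of class `gen_config`
#' @export
generator_config <- function(population_size = 10000,
                             start_year = 2016,
                             age_range = c(60L, 100L),
                             education_shares = list(
                               female = c(lths = 0.35, hs = 0.50, college = 0.15),
                               male   = c(lths = 0.30, hs = 0.45, college = 0.25)
                             ),
                             female_share = 0.554,
                             condition_baseline_logits = default_condition_baseline(),
                             incidence_logits = default_incidence_logits(),
                             mortality = default_mortality_params(),
                             functional = default_functional_params(),
                             entry = default_entry_params(),
                             national_population = c(female = 24105400, male = 19388180),
                             seed = 1L) {
  cfg <- list(
    population_size = population_size, start_year = start_year,
    age_range = as.integer(age_range), education_shares = education_shares,
    female_share = female_share,
    condition_baseline_logits = condition_baseline_logits,
    incidence_logits = incidence_logits, mortality = mortality,
    functional = functional, entry = entry,
    national_population = national_population, seed = as.integer(seed)
  )
  class(cfg) <- "gen_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (!is.numeric(cfg$population_size) || length(cfg$population_size) != 1 ||
      is.na(cfg$population_size) || cfg$population_size <= 0) {
    stop_config("population_size must be a positive count")
  }
  if (length(cfg$age_range) != 2 || cfg$age_range[1] > cfg$age_range[2]) {
    stop_config("age_range must be an ordered [min, max] pair")
  }
  if (cfg$age_range[1] < 60) stop_config("baseline minimum age must be >= 60")
  for (s in SEX_LEVELS) {
    sh <- cfg$education_shares[[s]]
    if (is.null(sh) || length(sh) != 3 || any(sh < 0)) {
      stop_config("education_shares[['", s, "']] must be three non-negative proportions")
    }
    if (abs(sum(sh) - 1) > 1e-9) {
      stop_config("education_shares for ", s, " must sum to 1 (got ", sum(sh), ")")
    }
  }
  if (cfg$female_share < 0 || cfg$female_share > 1) {
    stop_config("female_share must lie in [0, 1]")
  }
  cbl <- cfg$condition_baseline_logits
  if (!all(CONDITION_COLS %in% rownames(cbl))) {
    stop_config("condition_baseline_logits must have one row per condition")
  }
  invisible(cfg)
}

default_condition_baseline <- function() {
  # Log-odds of carrying each condition at baseline; intercept at age 75,
  # slope per year of age. Magnitudes give a mean comorbidity count near 1.5
  # at the population's mean age, in line with observed multimorbidity.
  m <- rbind(
    diabetes        = c(-1.55, 0.030,  0.30),
    chd             = c(-2.20, 0.040,  0.40),
    stroke          = c(-2.90, 0.055,  0.40),
    hypertension    = c(-0.20, 0.045,  0.00),
    hyperlipidaemia = c(-1.30, 0.000, -0.20),
    cancer          = c(-2.50, 0.035,  0.30),
    respiratory     = c(-2.60, 0.030,  0.20),
    joint_condition = c(-1.70, 0.035, -0.40),
    eye_problem     = c(-1.90, 0.050, -0.10),
    kidney          = c(-3.20, 0.045,  0.30),
    other_dx        = c(-1.50, 0.010,  0.00)
  )
  out <- as.data.frame(m)
  names(out) <- c("intercept", "age_slope", "male")
  out$lths <- 0.12
  out$college <- -0.12
  out
}

default_incidence_logits <- function() {
  # Half-year incidence on the log-odds scale, intercept at age 75. Levels
  # are set consistent with the baseline cross-sectional prevalence curves
  # (incidence hazard ~ age-slope x prevalence), so condition prevalence by
  # age stays near the configured cross-section as the simulation runs.
  m <- rbind(
    diabetes        = c(-5.94, 0.030, 0.20),
    chd             = c(-6.22, 0.040, 0.20),
    stroke          = c(-6.55, 0.055, 0.20),
    hypertension    = c(-4.58, 0.045, 0.00),
    hyperlipidaemia = c(-6.20, 0.010, -0.10),
    cancer          = c(-6.62, 0.035, 0.20),
    respiratory     = c(-6.87, 0.030, 0.10),
    joint_condition = c(-5.91, 0.035, -0.20),
    eye_problem     = c(-5.73, 0.050, 0.00),
    kidney          = c(-7.03, 0.045, 0.20),
    other_dx        = c(-7.00, 0.010, 0.00)
  )
  out <- as.data.frame(m)
  names(out) <- c("intercept", "age_slope", "male")
  out$lths <- 0.10
  out$college <- -0.10
  out
}

default_mortality_params <- function() {
  # Gompertz all-cause baseline (condition-free reference person, education
  # "hs"): log h(age) = intercept + slope * age. Intercepts solved so that
  # population-level period life expectancy at 65 is close to 23.7 years for
  # women and 18.7 for men once typical comorbidity loads are carried.
  list(
    intercept = c(female = -12.28, male = -11.72),
    slope = 0.105,
    education = c(lths = 0.25, hs = 0, college = -0.25),
    condition_loghr = c(
      diabetes = 0.25, chd = 0.35, stroke = 0.45, hypertension = 0.05,
      hyperlipidaemia = 0.00, cancer = 0.55, respiratory = 0.25,
      joint_condition = 0.00, eye_problem = 0.00, kidney = 0.35,
      other_dx = 0.10
    )
  )
}

default_functional_params <- function() {
  list(
    # half-year probability of gaining one more limitation / onset
    iadl_increment = c(intercept = -5.8, age_slope = 0.075), # at age 60
    adl_increment  = c(intercept = -6.8, age_slope = 0.085),
    depression_onset = c(intercept = -5.5, age_slope = 0.010),
    srh_worsen = 0.04, srh_improve = 0.03,
    # baseline cross-sectional draws
    baseline_iadl_logit = c(intercept = -4.5, age_slope = 0.080),
    baseline_adl_logit  = c(intercept = -5.5, age_slope = 0.090),
    baseline_depression_logit = c(intercept = -2.2, age_slope = 0.010),
    adl_max = 5L
  )
}

default_entry_params <- function() {
  list(
    rate = 0.040,           # annual entrants as a share of the baseline sex total
    annual_decline = 0.005, # cohort shrinkage per calendar year
    # education shares of entrants drift towards higher attainment
    college_base = 0.25, college_trend = 0.009, college_max = 0.60,
    lths_base = 0.12, lths_trend = -0.003, lths_min = 0.03,
    college_sex_offset = c(female = -0.03, male = 0.03),
    pre_entry_survival = c(lths = 0.955, hs = 0.965, college = 0.975)
  )
}

#' Ground-truth model parameters for the synthetic surveys
#'
#' Houses the "true" analogues of the estimated classification and cost
#' models: per-outcome probit coefficient vectors for the three cognitive
#' test failures and seven IADL difficulties, the latent outcome correlation
#' matrix (default exchangeable with rho 0.3), the logistic frailty model,
#' and the per-service cost regression coefficients. Survey generators draw
#' from these models, so refitting the models on generated data must recover
#' these values -- the package's parameter-recovery contract.
#'
#' @param probit_coefficients numeric matrix, one row per latent outcome,
#'   columns `r paste(PROBIT_COVARIATES, collapse = ", ")`
#' @param probit_correlation symmetric positive-definite correlation matrix
#'   across the ten binary outcomes
#' @param frailty_logit_coefficients named numeric vector over
#'   `r paste(FRAILTY_COVARIATES, collapse = ", ")`
#' @param cost_coefficients list with one named coefficient vector per
#'   service type (`inpatient`, `outpatient_rx`) over
#'   `r paste(COST_COVARIATES, collapse = ", ")`, plus `sigma` residual sds
#' @return object of class `truth_params`
#' @export
truth_parameters <- function(probit_coefficients = default_probit_truth(),
                             probit_correlation = exchangeable_correlation(10, 0.3),
                             frailty_logit_coefficients = default_frailty_truth(),
                             cost_coefficients = default_cost_truth()) {
  tp <- list(
    probit_coefficients = probit_coefficients,
    probit_correlation = probit_correlation,
    frailty_logit_coefficients = frailty_logit_coefficients,
    cost_coefficients = cost_coefficients
  )
  class(tp) <- "truth_params"
  validate_truth_parameters(tp)
  tp
}

validate_truth_parameters <- function(tp) {
  pc <- tp$probit_coefficients
  if (!identical(colnames(pc), PROBIT_COVARIATES)) {
    stop_config("probit_coefficients columns must be: ",
                paste(PROBIT_COVARIATES, collapse = ", "))
  }
  if (nrow(pc) != length(PROBIT_OUTCOMES)) {
    stop_config("probit_coefficients needs one row per outcome (",
                length(PROBIT_OUTCOMES), ")")
  }
  R <- tp$probit_correlation
  if (!isSymmetric(unname(R)) || any(abs(diag(R) - 1) > 1e-12)) {
    stop_config("probit_correlation must be symmetric with unit diagonal")
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 1e-10) {
    stop_config("probit_correlation must be positive definite")
  }
  if (!identical(names(tp$frailty_logit_coefficients), FRAILTY_COVARIATES)) {
    stop_config("frailty_logit_coefficients must be named: ",
                paste(FRAILTY_COVARIATES, collapse = ", "))
  }
  for (svc in c("inpatient", "outpatient_rx")) {
    b <- tp$cost_coefficients[[svc]]
    if (!identical(names(b), COST_COVARIATES)) {
      stop_config("cost_coefficients$", svc, " must be named: ",
                  paste(COST_COVARIATES, collapse = ", "))
    }
  }
  invisible(tp)
}

# Covariate orderings shared by generators and fitters. age10 is
# (age - 75) / 10 so intercepts refer to a 75-year-old woman with less than
# high-school education and no comorbidities.
PROBIT_COVARIATES <- c("intercept", "age10", "male", "edu_hs", "edu_college",
                       "stroke", "diabetes", "chd", "ncond")
PROBIT_OUTCOMES <- c("test_recall_immediate", "test_recall_delayed",
                     "test_serial7",
                     "iadl_transport", "iadl_shopping", "iadl_meals",
                     "iadl_bills", "iadl_banking", "iadl_phone",
                     "iadl_medication")
FRAILTY_COVARIATES <- c("intercept", "age10", "male", "edu_hs", "edu_college",
                        "diabetes", "chd", "stroke", "hypertension",
                        "hyperlipidaemia", "cancer", "kidney", "depression",
                        "impaired_mobility")
COST_COVARIATES <- c("intercept", "age10", "male", CONDITION_COLS, "multimorbidity")

#' Exchangeable correlation matrix
#'
#' @param d dimension
#' @param rho common off-diagonal correlation
#' @return d x d correlation matrix
#' @export
exchangeable_correlation <- function(d, rho) {
  if (rho <= -1 / (d - 1) || rho >= 1) {
    stop_config("exchangeable rho must lie in (-1/(d-1), 1) for positive definiteness")
  }
  R <- matrix(rho, d, d)
  diag(R) <- 1
  R
}

default_probit_truth <- function() {
  tests <- rbind(
    test_recall_immediate = c(-0.90, 0.55, 0.10, -0.25, -0.50, 0.35, 0.12, 0.08, 0.05),
    test_recall_delayed   = c(-0.80, 0.60, 0.10, -0.25, -0.50, 0.35, 0.12, 0.08, 0.05),
    test_serial7          = c(-1.00, 0.50, 0.05, -0.30, -0.55, 0.30, 0.10, 0.08, 0.05)
  )
  iadl_names <- PROBIT_OUTCOMES[4:10]
  iadl <- matrix(rep(c(-1.70, 0.70, -0.05, -0.15, -0.30, 0.40, 0.10, 0.10, 0.06),
                     each = length(iadl_names)),
                 nrow = length(iadl_names), dimnames = list(iadl_names, NULL))
  # mild heterogeneity across the seven IADL items
  iadl[, 1] <- iadl[, 1] + seq(-0.15, 0.15, length.out = length(iadl_names))
  out <- rbind(tests, iadl)
  colnames(out) <- PROBIT_COVARIATES
  out
}

default_frailty_truth <- function() {
  c(intercept = -2.60, age10 = 0.90, male = -0.30, edu_hs = -0.15,
    edu_college = -0.30, diabetes = 0.30, chd = 0.30, stroke = 0.50,
    hypertension = 0.10, hyperlipidaemia = 0.05, cancer = 0.20,
    kidney = 0.30, depression = 0.60, impaired_mobility = 1.30)
}

default_cost_truth <- function() {
  inpatient <- c(intercept = 80, age10 = 15, male = 5,
                 diabetes = 25, chd = 45, stroke = 60, hypertension = 10,
                 hyperlipidaemia = 5, cancer = 60, respiratory = 30,
                 joint_condition = 15, eye_problem = 5, kidney = 45,
                 other_dx = 10, multimorbidity = 40)
  outpatient_rx <- c(intercept = 120, age10 = 15, male = -5,
                     diabetes = 40, chd = 35, stroke = 30, hypertension = 25,
                     hyperlipidaemia = 20, cancer = 45, respiratory = 25,
                     joint_condition = 20, eye_problem = 15, kidney = 50,
                     other_dx = 15, multimorbidity = 30)
  list(inpatient = inpatient, outpatient_rx = outpatient_rx,
       sigma = c(inpatient = 18, outpatient_rx = 22))
}
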