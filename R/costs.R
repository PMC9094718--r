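#' Fit the health-care use regressions
#'
#' Least-squares fit of monthly use per service type (inpatient vs
#' outpatient + prescription) on age, sex, the eleven comorbidity flags and
#' a comorbidity-burden term. With `count_column = "ncond"` the raw
#' comorbidity count is used, which is an exact linear combination of the
#' eleven flags and raises the rank-deficiency error naming the collinear
#' column; the default multimorbidity indicator (count >= 3) is not
#' collinear.
#'
#' @param claims claims table from [generate_utilization_claims()]
#' @param count_column `"multimorbidity"` (default) or `"ncond"`
#' @return object of class `healthcare_model`: per-service `coefficients`
#'   and `se`, `sigma`, `n`, `count_column`
#' @export
fit_healthcare_use <- function(claims, count_column = "multimorbidity") {
  claims <- data.table::as.data.table(claims)
  X <- cost_design_matrix(claims, count_column)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_data("rank-deficient cost design; collinear column(s): ",
              paste(dropped, collapse = ", "))
  }
  out <- list()
  for (svc in c("inpatient", "outpatient_rx")) {
    ycol <- paste0("monthly_", svc)
    if (!ycol %in% names(claims)) stop_data("claims lack column ", ycol)
    y <- claims[[ycol]]
    fit <- lm.fit(X, y)
    rss <- sum(fit$residuals^2)
    dfres <- nrow(X) - ncol(X)
    sigma2 <- rss / dfres
    covb <- chol2inv(qr.R(qr_x)) * sigma2
    out[[svc]] <- list(coefficients = setNames(fit$coefficients, colnames(X)),
                       se = setNames(sqrt(diag(covb)), colnames(X)),
                       sigma = sqrt(sigma2))
  }
  structure(list(inpatient = out$inpatient, outpatient_rx = out$outpatient_rx,
                 n = nrow(claims), count_column = count_column),
            class = "healthcare_model")
}

#' Cost parameter bundle
#'
#' Combines the fitted health-care use model with the long-term-care (LTC)
#' monthly-use table by age band, sex, dependency tier and care setting, the
#' care-home residence probability model, and the informal-care constants:
#' 25 hours/week for high dependency, 10 for mild, valued at $11/hour, in
#' constant 2016 dollars.
#'
#' @param healthcare a [fit_healthcare_use()] model (or compatible list)
#' @param ltc_monthly_use `data.table` with columns `age_band`, `sex`,
#'   `dependency` ("mild"/"high"), `setting` ("home_community"/"care_home"),
#'   `monthly_cost`
#' @param residence_logit list with per-tier intercept and age slope for the
#'   log-odds of care-home residence
#' @param informal_hours named vector, hours/week by tier
#' @param informal_wage hourly wage
#' @param weeks_per_year weeks used for annualising informal care
#' @param currency_year reporting currency year
#' @return object of class `cost_parameters`
#' @export
cost_parameters <- function(healthcare,
                            ltc_monthly_use = default_ltc_monthly_use(),
                            residence_logit = list(
                              high = c(intercept = -3.0, age_slope = 0.05),
                              mild = c(intercept = -4.5, age_slope = 0.04)
                            ),
                            informal_hours = c(high = 25, mild = 10),
                            informal_wage = 11,
                            weeks_per_year = 52,
                            currency_year = 2016) {
  ltc <- data.table::as.data.table(ltc_monthly_use)
  if (any(ltc$monthly_cost < 0)) stop_config("ltc monthly costs must be >= 0")
  if (any(informal_hours <= 0) || informal_wage <= 0) {
    stop_config("informal-care constants must be positive")
  }
  structure(list(healthcare = healthcare,
                 ltc_monthly_use = data.table::setkeyv(
                   ltc, c("age_band", "sex", "dependency", "setting")),
                 residence_logit = residence_logit,
                 informal_hours = informal_hours,
                 informal_wage = informal_wage,
                 weeks_per_year = weeks_per_year,
                 currency_year = currency_year),
            class = "cost_parameters")
}

default_ltc_monthly_use <- function() {
  bands <- age_band_levels()
  grid <- data.table::CJ(age_band = bands, sex = SEX_LEVELS,
                         dependency = c("mild", "high"),
                         setting = c("home_community", "care_home"))
  base <- c(mild.home_community = 420, mild.care_home = 1300,
            high.home_community = 1500, high.care_home = 3100)
  key <- paste(grid$dependency, grid$setting, sep = ".")
  idx <- match(grid$age_band, bands) - 1
  grid$monthly_cost <- base[key] * (1 + 0.015 * idx)
  grid
}

#' Assign the LTC dependency tier
#'
#' Deterministic collapse of functional state to the two costing tiers of
#' the seven-level LTC eligibility scale: `high` with any basic-ADL
#' limitation, `mild` with IADL limitation or frailty but intact ADLs,
#' `none` otherwise.
#'
#' @param persons population rows with `adl_limited`, `iadl_limited` and
#'   (optionally) `frail`
#' @return character vector in `c("none", "mild", "high")`
#' @export
assign_dependency_level <- function(persons) {
  persons <- data.table::as.data.table(persons)
  frail <- if ("frail" %in% names(persons)) {
    f <- persons$frail
    !is.na(f) & as.logical(f)
  } else rep(FALSE, nrow(persons))
  ifelse(persons$adl_limited >= 1, "high",
         ifelse(persons$iadl_limited >= 1 | frail, "mild", "none"))
}

#' Annual per-person cost breakdown
#'
#' Health-care costs are 12 times the predicted monthly use per service
#' type (floored at zero). Formal LTC is 12 times the tier- and
#' stratum-specific monthly mean, split between home/community and
#' care-home settings by a stochastic residence draw. Informal care is
#' hours/week x 52 x wage for home-based persons by tier; zero for tier
#' `none` and for care-home residents.
#'
#' @param persons classified population rows (alive persons are costed;
#'   dead rows get zero costs)
#' @param params a [cost_parameters()] object
#' @param seed integer seed for the residence draw
#' @return `data.table` keyed by `id` with columns `inpatient`,
#'   `outpatient_rx`, `ltc_home_community`, `ltc_care_home`, `informal`,
#'   `dependency`, `care_home`, `total`
#' @export
annual_cost <- function(persons, params, seed = 1L) {
  persons <- data.table::as.data.table(persons)
  n <- nrow(persons)
  X <- cost_design_matrix(persons, params$healthcare$count_column %||% "multimorbidity")
  inp <- pmax(0, drop(X %*% params$healthcare$inpatient$coefficients)) * 12
  outp <- pmax(0, drop(X %*% params$healthcare$outpatient_rx$coefficients)) * 12

  dep <- assign_dependency_level(persons)
  set.seed(seed)
  u <- runif(n)
  p_ch <- numeric(n)
  for (tier in c("mild", "high")) {
    b <- params$residence_logit[[tier]]
    sel <- dep == tier
    p_ch[sel] <- plogis(b["intercept"] + b["age_slope"] * (persons$age[sel] - 65))
  }
  care_home <- dep != "none" & u < p_ch

  keys <- data.table::data.table(
    age_band = age_band(persons$age), sex = persons$sex, dependency = dep,
    setting = ifelse(care_home, "care_home", "home_community")
  )
  mc <- params$ltc_monthly_use[keys, monthly_cost,
                               on = c("age_band", "sex", "dependency", "setting")]
  has_tier <- dep != "none"
  if (any(has_tier & is.na(mc))) {
    bad <- unique(keys[has_tier & is.na(mc)])
    stop_data("missing LTC monthly-use cell(s): ",
              paste(apply(head(bad, 5), 1, paste, collapse = "/"), collapse = "; "))
  }
  ltc_annual <- ifelse(has_tier, mc * 12, 0)
  ltc_home <- ifelse(has_tier & !care_home, ltc_annual, 0)
  ltc_ch <- ifelse(has_tier & care_home, ltc_annual, 0)

  hours <- setNames(rep(0, 3), c("none", "mild", "high"))
  hours[names(params$informal_hours)] <- params$informal_hours
  informal <- ifelse(has_tier & !care_home,
                     hours[dep] * params$weeks_per_year * params$informal_wage, 0)

  alive <- if ("alive" %in% names(persons)) persons$alive else rep(TRUE, n)
  out <- data.table::data.table(
    id = persons$id,
    inpatient = ifelse(alive, inp, 0),
    outpatient_rx = ifelse(alive, outp, 0),
    ltc_home_community = ifelse(alive, ltc_home, 0),
    ltc_care_home = ifelse(alive, ltc_ch, 0),
    informal = ifelse(alive, informal, 0),
    dependency = ifelse(alive, dep, "none"),
    care_home = alive & care_home
  )
  out[, total := inpatient + outpatient_rx + ltc_home_community +
        ltc_care_home + informal]
  out[]
}

COST_COMPONENTS <- c("inpatient", "outpatient_rx", "ltc_home_community",
                     "ltc_care_home", "informal")

#' Condition group of each person
#'
#' Partition by the joint dementia/frailty state: `"both"`,
#' `"dementia_only"`, `"frailty_only"`, `"neither"`. The four groups are
#' disjoint and exhaustive over classified persons.
#'
#' @param persons classified population rows
#' @return character vector
#' @export
condition_group <- function(persons) {
  dem <- persons$dementia_state == "dementia"
  fr <- !is.na(persons$frail) & as.logical(persons$frail)
  dem[is.na(dem)] <- FALSE
  ifelse(dem & fr, "both",
         ifelse(dem, "dementia_only", ifelse(fr, "frailty_only", "neither")))
}

#' Aggregate individual costs to population tables
#'
#' National annual totals by component and condition group (headline
#' dementia/frailty totals count the overlap group in both, with the
#' overlap also reported separately), plus per-capita means and mean
#' comorbidity counts by sex, education and with/without condition group.
#'
#' @param persons classified population rows (alive persons enter the
#'   denominators)
#' @param costs matching [annual_cost()] table
#' @param weight scalar or per-person weights scaling simulated persons to
#'   the population represented (default 1)
#' @return list of class `cost_tables`: `totals` (component x group),
#'   `headline` (overlapping condition attribution), `per_capita`,
#'   `components`, `n_costed`
#' @export
aggregate_costs <- function(persons, costs, weight = 1) {
  persons <- data.table::as.data.table(persons)
  stopifnot(nrow(persons) == nrow(costs))
  w <- rep_len(weight, nrow(persons))
  alive <- persons$alive
  grp <- condition_group(persons)

  dt <- cbind(costs[, COST_COMPONENTS, with = FALSE],
              data.table::data.table(
                w = w, alive = alive, group = grp, sex = persons$sex,
                education = persons$education,
                ncond = rowSums(as.matrix(persons[, CONDITION_COLS, with = FALSE]))
              ))
  dt <- dt[alive == TRUE]

  long <- data.table::melt(dt, id.vars = c("w", "group", "sex", "education", "ncond"),
                           measure.vars = COST_COMPONENTS,
                           variable.name = "component", value.name = "cost",
                           variable.factor = FALSE)
  totals <- long[, .(total = sum(w * cost)), by = .(component, group)]
  grand <- long[, .(group = "all", total = sum(w * cost)), by = component]
  totals <- data.table::rbindlist(list(totals, grand), use.names = TRUE)

  head_groups <- list(
    dementia = c("dementia_only", "both"),
    frailty = c("frailty_only", "both"),
    both_overlap = "both",
    neither = "neither"
  )
  headline <- data.table::rbindlist(lapply(names(head_groups), function(g) {
    long[group %in% head_groups[[g]],
         .(condition = g, total = sum(w * cost)), by = component]
  }))

  dt[, group2 := ifelse(group == "neither", "without_dementia_or_frailty",
                        "with_dementia_or_frailty")]
  percap_grp <- dt[, .(
    healthcare = sum(w * (inpatient + outpatient_rx)) / sum(w),
    formal_ltc = sum(w * (ltc_home_community + ltc_care_home)) / sum(w),
    informal = sum(w * informal) / sum(w),
    mean_comorbidities = sum(w * ncond) / sum(w),
    headcount = sum(w)
  ), by = .(sex, education, group = group2)]
  percap_all <- dt[, .(
    healthcare = sum(w * (inpatient + outpatient_rx)) / sum(w),
    formal_ltc = sum(w * (ltc_home_community + ltc_care_home)) / sum(w),
    informal = sum(w * informal) / sum(w),
    mean_comorbidities = sum(w * ncond) / sum(w),
    headcount = sum(w), group = "total_population"
  ), by = .(sex, education)]
  per_capita <- data.table::rbindlist(list(percap_all, percap_grp),
                                      use.names = TRUE)

  structure(list(totals = totals, headline = headline,
                 per_capita = per_capita[order(sex, education, group)],
                 components = COST_COMPONENTS,
                 n_costed = nrow(dt)),
            class = "cost_tables")
}

#' Household-substitution sensitivity analysis
#'
#' Scales informal-care volume down by the projected decline in household
#' care capacity and formal community-based home care up by the substitution
#' rate, and reports the adjusted combined formal + informal total.
#'
#' @param tables a [aggregate_costs()] result
#' @param household_capacity_decline proportion in `[0, 1]` (default 0.20)
#' @param substitution_rate proportion in `[0, 1]` (default 0.13)
#' @return list: adjusted `totals`, `combined_total` (all components,
#'   group "all"), `baseline_combined_total`
#' @export
substitution_sensitivity <- function(tables, household_capacity_decline = 0.20,
                                     substitution_rate = 0.13) {
  if (household_capacity_decline < 0 || household_capacity_decline > 1 ||
      substitution_rate < 0 || substitution_rate > 1) {
    stop_config("sensitivity rates must lie in [0, 1]")
  }
  tot <- data.table::copy(tables$totals)
  tot[component == "informal", total := total * (1 - household_capacity_decline)]
  tot[component == "ltc_home_community", total := total * (1 + substitution_rate)]
  list(totals = tot,
       combined_total = tot[group == "all", sum(total)],
       baseline_combined_total = tables$totals[group == "all", sum(total)])
}
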