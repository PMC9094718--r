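zero_probit_truth <- function(rho = 0) {
  truth_parameters(
    probit_coefficients = matrix(0, 10, 9,
      dimnames = list(demfrailsim:::PROBIT_OUTCOMES,
                      demfrailsim:::PROBIT_COVARIATES)),
    probit_correlation = if (rho == 0) diag(10) else
      exchangeable_correlation(10, rho)
  )
}

test_that("probit slopes fitted on null truth are within 3 se of zero", {
  svy <- generate_cognitive_survey(5000, zero_probit_truth(0.3), seed = 41)
  fit <- fit_cognitive_probit(svy, estimate_correlation = "none")
  slopes <- fit$coefficients[, -1]
  ses <- fit$se[, -1]
  expect_true(mean(abs(slopes) <= 3 * ses) > 0.95)
})

test_that("duplicating every record keeps estimates and shrinks se by sqrt(2)", {
  svy <- generate_cognitive_survey(1500, truth_parameters(), seed = 42)
  dup <- data.table::rbindlist(list(svy, svy))
  f1 <- fit_cognitive_probit(svy, estimate_correlation = "none")
  f2 <- fit_cognitive_probit(dup, estimate_correlation = "none")
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-8)
  expect_equal(f2$se, f1$se / sqrt(2), tolerance = 1e-6)
})

test_that("degenerate outcomes raise a fit error naming the outcome", {
  svy <- generate_cognitive_survey(500, truth_parameters(), seed = 43)
  svy[, test_serial7 := 0L]
  expect_error(fit_cognitive_probit(svy), "test_serial7",
               class = "demfrailsim_data_error")
})

test_that("null model with independence matches battery-rule enumeration", {
  # each outcome has probability 1/2; failing >= 2 of 3 tests enumerates to
  # 4/8, and >= 1 of 7 IADLs to 1 - (1/2)^7
  truth <- zero_probit_truth(0)
  model <- structure(list(coefficients = truth$probit_coefficients,
                          correlation = truth$probit_correlation,
                          battery_k = 2L),
                     class = "probit_model")
  person <- make_toy_population(1, age = 75, education = "lths")
  pr_q <- predict_impairment_probability(model, person, method = "quadrature")
  pr_mc <- predict_impairment_probability(model, person, method = "montecarlo")
  expect_equal(pr_q$p_fail, 0.5, tolerance = 1e-6)
  expect_equal(pr_q$p_joint, 0.5 * (1 - 0.5^7), tolerance = 1e-6)
  expect_equal(pr_mc$p_fail, 0.5, tolerance = 0.03)
  expect_equal(pr_mc$p_joint, 0.5 * (1 - 0.5^7), tolerance = 0.03)
})

test_that("quadrature and Monte Carlo orthant probabilities agree", {
  truth <- truth_parameters()
  model <- structure(list(coefficients = truth$probit_coefficients,
                          correlation = truth$probit_correlation,
                          battery_k = 2L),
                     class = "probit_model")
  set.seed(44)
  persons <- generate_baseline_population(small_config(40, seed = 44))
  pq <- predict_impairment_probability(model, persons, method = "quadrature")
  pm <- predict_impairment_probability(model, persons, method = "montecarlo",
                                       n_draws = 20000)
  expect_lt(max(abs(pq$p_fail - pm$p_fail)), 0.02)
  expect_lt(max(abs(pq$p_joint - pm$p_joint)), 0.02)
})

test_that("an overwhelming age effect drives probabilities to one", {
  truth <- zero_probit_truth(0.3)
  truth$probit_coefficients[, "age10"] <- 25
  model <- structure(list(coefficients = truth$probit_coefficients,
                          correlation = truth$probit_correlation,
                          battery_k = 2L),
                     class = "probit_model")
  old <- make_toy_population(1, age = 100)
  pr <- predict_impairment_probability(model, old)
  expect_gt(pr$p_fail, 0.999)
  expect_gt(pr$p_joint, 0.999)
})

test_that("joint probability never exceeds the marginal failure probability", {
  truth <- truth_parameters()
  model <- structure(list(coefficients = truth$probit_coefficients,
                          correlation = truth$probit_correlation,
                          battery_k = 2L),
                     class = "probit_model")
  persons <- generate_baseline_population(small_config(500, seed = 45))
  pr <- predict_impairment_probability(model, persons)
  expect_true(all(pr$p_joint <= pr$p_fail + 1e-12))
  expect_true(all(pr$p_fail >= 0 & pr$p_fail <= 1))
})

test_that("threshold calibration matches the order-statistic oracle", {
  set.seed(46)
  n <- 1000
  probs <- data.table::data.table(p_fail = runif(n), p_joint = runif(n))
  probs[, p_joint := pmin(p_fail, p_joint)]
  th <- calibrate_thresholds(probs, target = c(dementia = 0.10, mci = 0.15))
  # sort-based oracle: the 100th largest joint probability is labelled
  oracle_theta <- sort(probs$p_joint, decreasing = TRUE)[100]
  labels <- classify_cognition(probs, th)
  expect_equal(sum(labels == "dementia"), 100)
  expect_gte(oracle_theta, th$theta_dementia - 1e-9)
  expect_equal(th$achieved_dementia, 0.10, tolerance = 1e-9)
  expect_equal(sum(labels == "MCI"), round(0.15 * n))
})

test_that("calibration handles boundary targets and reports unreachable ones", {
  probs <- data.table::data.table(p_fail = c(0.2, 0.4, 0.6, 0.8),
                                  p_joint = c(0.1, 0.2, 0.3, 0.4))
  th0 <- calibrate_thresholds(probs, target = c(dementia = 0, mci = 0))
  expect_equal(th0$achieved_dementia, 0)
  expect_equal(sum(classify_cognition(probs, th0) != "normal"), 0)
  th1 <- calibrate_thresholds(probs, target = c(dementia = 1, mci = 0))
  expect_equal(th1$achieved_dementia, 1)
  expect_lte(th1$theta_dementia, min(probs$p_joint))
  expect_error(
    demfrailsim:::calibrate_threshold_single(c(0.5, 0.5, 0.5, 0.5), 0.5),
    class = "demfrailsim_calibration_error"
  )
})

test_that("modelled prevalence is monotone in the threshold", {
  set.seed(47)
  p <- runif(400)
  thetas <- seq(0, 1, by = 0.05)
  prev <- vapply(thetas, function(t) mean(p >= t), numeric(1))
  expect_true(all(diff(prev) <= 0))
})

test_that("classification reproduces the calibrated prevalence exactly", {
  set.seed(48)
  n <- 2000
  probs <- data.table::data.table(p_fail = runif(n))
  probs[, p_joint := p_fail * runif(n)]
  th <- calibrate_thresholds(probs, target = c(dementia = 0.12, mci = 0.08))
  labels <- classify_cognition(probs, th)
  expect_equal(mean(labels == "dementia"), th$achieved_dementia)
  expect_equal(mean(labels == "MCI"), th$achieved_mci)
  expect_equal(mean(labels == "dementia"), 0.12, tolerance = 1e-3)
})

test_that("per-group calibration matches each group's own target", {
  set.seed(50)
  n <- 4000
  probs <- data.table::data.table(p_fail = runif(n))
  probs[, p_joint := p_fail * runif(n)]
  sexes <- rep(c("female", "male"), n / 2)
  th <- calibrate_thresholds(probs, target = c(dementia = 0.15, mci = 0.10),
                             by = sexes)
  expect_equal(th$by_groups, c("female", "male"))
  labels <- classify_cognition(probs, th, by = sexes)
  for (s in c("female", "male")) {
    expect_equal(mean(labels[sexes == s] == "dementia"), 0.15, tolerance = 1e-3)
  }
  expect_error(classify_cognition(probs, th), class = "demfrailsim_config_error")

  p <- runif(n)
  thf <- calibrate_frailty_threshold(p, population = NULL, target = 0.2,
                                     by = sexes)
  fl <- classify_frailty(p, thf, by = sexes)
  expect_equal(mean(fl[sexes == "male"]), 0.2, tolerance = 1e-3)
})

test_that("probit model serialization round-trips through JSON", {
  svy <- generate_cognitive_survey(800, truth_parameters(), seed = 49)
  fit <- fit_cognitive_probit(svy, estimate_correlation = "exchangeable")
  f <- tempfile(fileext = ".json")
  write_model_json(fit, f)
  back <- read_model_json(f)
  expect_equal(back$coefficients, fit$coefficients, tolerance = 1e-12)
  expect_equal(back$correlation, fit$correlation, tolerance = 1e-12)
  p1 <- predict_impairment_probability(fit, make_toy_population(3, age = 80))
  p2 <- predict_impairment_probability(back, make_toy_population(3, age = 80))
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("bivariate normal probability matches independent and comonotone cases", {
  a <- c(-1, 0, 0.5); b <- c(0.3, 0, -0.2)
  expect_equal(pbinorm(a, b, 0), pnorm(a) * pnorm(b), tolerance = 1e-12)
  # closed form at equal zero limits: 1/4 + asin(rho)/(2 pi), for any rho
  for (r in c(-0.8, 0.3, 0.5, 0.999)) {
    expect_equal(pbinorm(0, 0, r), 0.25 + asin(r) / (2 * pi), tolerance = 1e-8)
  }
  # comonotone-ish case away from the diagonal reaches the sharp limit
  expect_equal(pbinorm(c(-1, 0.5), c(0.3, -0.2), 0.999),
               pnorm(pmin(c(-1, 0.5), c(0.3, -0.2))), tolerance = 1e-6)
})
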