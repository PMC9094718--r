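#' Fit the logistic frailty model
#'
#' Maximum-likelihood logistic regression of the binary frailty phenotype on
#' age, sex, education, seven comorbid conditions (diabetes, heart disease,
#' stroke, hypertension, hyperlipidaemia, cancer, chronic renal failure),
#' depression and impaired mobility in daily living.
#'
#' @param survey frailty survey table from [generate_frailty_survey()]
#' @return object of class `frailty_model`: `coefficients`, `se`, `loglik`,
#'   `n`, `converged`
#' @export
fit_frailty_logit <- function(survey) {
  survey <- data.table::as.data.table(survey)
  if (nrow(survey) < 200) stop_data("frailty survey needs at least 200 records")
  y <- survey$frail
  if (length(unique(y)) < 2) stop_data("both frail and non-frail classes required")
  X <- frailty_design_matrix(survey)
  fit <- suppressWarnings(
    glm.fit(X, y, family = binomial(), control = list(maxit = 100))
  )
  if (!fit$converged || any(abs(fit$coefficients) > 25)) {
    stop_data("frailty logistic fit failed (possible separation)")
  }
  cov_u <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
  mu <- plogis(drop(X %*% fit$coefficients))
  ll <- sum(y * log(pmax(mu, 1e-12)) + (1 - y) * log(pmax(1 - mu, 1e-12)))
  structure(list(coefficients = setNames(fit$coefficients, colnames(X)),
                 se = setNames(sqrt(diag(cov_u)), colnames(X)),
                 loglik = ll, n = nrow(survey), converged = fit$converged),
            class = "frailty_model")
}

#' Predict frailty probability
#'
#' Inverse-logit of the fitted linear predictor; impaired mobility is mapped
#' from the simulated ADL/IADL state via [impaired_mobility()].
#'
#' @param model a [fit_frailty_logit()] model
#' @param persons population rows with the covariate columns
#' @return numeric vector of probabilities in (0, 1)
#' @export
predict_frailty_probability <- function(model, persons) {
  persons <- data.table::as.data.table(persons)
  X <- frailty_design_matrix(persons)
  plogis(drop(X %*% model$coefficients[colnames(X)]))
}

#' Calibrate the frailty classification threshold
#'
#' Bisection threshold on the predicted probabilities so the achieved
#' overall prevalence matches the target within tolerance (or the nearest
#' person-granularity share). Persons younger than `min_age` are outside the
#' frailty survey's support and are excluded from calibration (and later
#' labelled not frail).
#'
#' @param probabilities predicted frailty probabilities
#' @param population matching population table (for target-curve collapsing
#'   and the age restriction); may be `NULL` with a numeric target and no
#'   age restriction
#' @param target a single proportion or a [generate_target_prevalence()]
#'   curve
#' @param min_age minimum age with survey support (default 65)
#' @param tolerance calibration tolerance
#' @param by optional grouping vector (e.g. `population$sex`) for per-group
#'   thresholds matched to group-specific targets
#' @return object of class `frailty_threshold`: `theta_frail`,
#'   `achieved_prevalence`, `target`, `min_age` (vectors when `by` is used),
#'   plus `by_groups`
#' @export
calibrate_frailty_threshold <- function(probabilities, population = NULL,
                                        target, min_age = 65, tolerance = 1e-4,
                                        by = NULL) {
  if (!is.null(by)) {
    stopifnot(length(by) == length(probabilities))
    groups <- sort(unique(by))
    parts <- lapply(groups, function(g) {
      calibrate_frailty_threshold(probabilities[by == g],
                                  if (!is.null(population)) population[by == g],
                                  target, min_age = min_age,
                                  tolerance = tolerance)
    })
    return(structure(list(
      theta_frail = setNames(vapply(parts, `[[`, 0, "theta_frail"), groups),
      achieved_prevalence = setNames(vapply(parts, `[[`, 0, "achieved_prevalence"),
                                     groups),
      target = setNames(vapply(parts, `[[`, 0, "target"), groups),
      min_age = min_age, by_groups = groups
    ), class = "frailty_threshold"))
  }
  if (inherits(target, "calibration_target")) {
    if (is.null(population)) stop_config("population needed to collapse a target curve")
    target <- overall_target_prevalence(target, population, "frailty",
                                        min_age = min_age)
  }
  target <- as.numeric(target)
  p <- probabilities
  if (!is.null(population)) {
    p <- ifelse(population$age >= min_age, p, -Inf)
  }
  res <- calibrate_threshold_single(p, target, tolerance = tolerance,
                                    what = "frailty")
  structure(list(theta_frail = res$theta, achieved_prevalence = res$achieved,
                 target = target, min_age = min_age, by_groups = NULL),
            class = "frailty_threshold")
}

#' Classify frailty
#'
#' Frail iff the predicted probability reaches `theta_frail`; persons below
#' the threshold's `min_age` are never labelled frail.
#'
#' @param probabilities predicted frailty probabilities
#' @param threshold a [calibrate_frailty_threshold()] object
#' @param age optional ages enforcing the survey-support restriction
#' @param by grouping vector matching the one used at calibration, when the
#'   threshold was calibrated per group
#' @return logical vector
#' @export
classify_frailty <- function(probabilities, threshold, age = NULL, by = NULL) {
  check_prob(threshold$theta_frail, "theta_frail")
  th <- if (!is.null(threshold$by_groups)) {
    if (is.null(by)) stop_config("this threshold was calibrated per group; supply `by`")
    threshold$theta_frail[by]
  } else {
    threshold$theta_frail
  }
  out <- probabilities >= th
  if (!is.null(age)) out <- out & age >= threshold$min_age
  out
}
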