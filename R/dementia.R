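#' Fit the multivariate probit model of cognitive failure and IADL difficulty
#'
#' Estimates, by maximum likelihood, one probit regression per binary outcome
#' (three cognitive-test failures, seven IADL difficulties) on age, sex,
#' education and comorbidity, then estimates the latent outcome correlation
#' matrix pairwise by moment-matching each pair's joint success rate through
#' the bivariate normal (a composite-likelihood estimator).
#'
#' @param survey cognitive survey table from [generate_cognitive_survey()]
#'   (needs the covariate columns and the ten outcome columns)
#' @param estimate_correlation `"pairwise"` (default), `"exchangeable"`
#'   (pairwise estimates averaged), or `"none"` (identity)
#' @param battery_k how many of the three tests must be failed to count as
#'   overall cognitive failure (default 2)
#' @return object of class `probit_model`: `coefficients` and `se` matrices
#'   (outcome x covariate), `correlation`, `loglik`, `n`, `outcomes`,
#'   `battery_k`
#' @export
fit_cognitive_probit <- function(survey,
                                 estimate_correlation = c("pairwise", "exchangeable", "none"),
                                 battery_k = 2L) {
  estimate_correlation <- match.arg(estimate_correlation)
  survey <- data.table::as.data.table(survey)
  if (nrow(survey) < 200) stop_data("cognitive survey needs at least 200 records")
  miss <- setdiff(PROBIT_OUTCOMES, names(survey))
  if (length(miss)) stop_data("survey lacks outcome columns: ", paste(miss, collapse = ", "))
  X <- probit_design_matrix(survey)

  k <- ncol(X)
  coefs <- se <- matrix(NA_real_, length(PROBIT_OUTCOMES), k,
                        dimnames = list(PROBIT_OUTCOMES, colnames(X)))
  loglik <- 0
  for (j in PROBIT_OUTCOMES) {
    y <- survey[[j]]
    if (length(unique(y)) < 2) {
      stop_data("degenerate outcome (single class): ", j)
    }
    fit <- suppressWarnings(
      glm.fit(X, y, family = binomial(link = "probit"),
              control = list(maxit = 100))
    )
    if (!fit$converged || any(abs(fit$coefficients) > 25)) {
      stop_data("probit fit failed (possible separation) for outcome: ", j)
    }
    coefs[j, ] <- fit$coefficients
    # observed-information standard errors from the weighted least-squares form
    cov_u <- chol2inv(chol(crossprod(X * sqrt(fit$weights))))
    se[j, ] <- sqrt(diag(cov_u))
    mu <- pnorm(drop(X %*% fit$coefficients))
    loglik <- loglik + sum(y * log(pmax(mu, 1e-12)) +
                             (1 - y) * log(pmax(1 - mu, 1e-12)))
  }

  d <- length(PROBIT_OUTCOMES)
  R <- diag(d)
  dimnames(R) <- list(PROBIT_OUTCOMES, PROBIT_OUTCOMES)
  if (estimate_correlation != "none") {
    eta <- X %*% t(coefs)
    for (j1 in 1:(d - 1)) {
      for (j2 in (j1 + 1):d) {
        y12 <- survey[[PROBIT_OUTCOMES[j1]]] * survey[[PROBIT_OUTCOMES[j2]]]
        m_obs <- mean(y12)
        a <- eta[, j1]; b <- eta[, j2]
        f <- function(r) mean(pbinorm(a, b, r)) - m_obs
        lo <- -0.9; hi <- 0.9
        flo <- f(lo); fhi <- f(hi)
        r_hat <- if (flo > 0) lo else if (fhi < 0) hi else {
          uniroot(f, c(lo, hi), f.lower = flo, f.upper = fhi, tol = 1e-4)$root
        }
        R[j1, j2] <- R[j2, j1] <- r_hat
      }
    }
    if (estimate_correlation == "exchangeable") {
      rho <- mean(R[upper.tri(R)])
      R <- exchangeable_correlation(d, rho)
      dimnames(R) <- list(PROBIT_OUTCOMES, PROBIT_OUTCOMES)
    }
  }

  structure(list(coefficients = coefs, se = se, correlation = R,
                 loglik = loglik, n = nrow(survey),
                 outcomes = PROBIT_OUTCOMES, battery_k = as.integer(battery_k)),
            class = "probit_model")
}

#' Predict cognitive-impairment probabilities
#'
#' For each person, the model-implied probability of failing the cognitive
#' test battery (at least `battery_k` of the three tests below cutoff) and
#' the joint probability of battery failure together with difficulty in at
#' least one of the seven IADLs, both computed from the latent-normal model.
#'
#' With an (approximately) exchangeable correlation the joint orthant
#' probabilities reduce to a one-dimensional latent-factor integral,
#' evaluated by Gauss-Hermite quadrature (`method = "quadrature"`); for a
#' general correlation matrix they are estimated by Monte Carlo with a fixed
#' internal seed (`method = "montecarlo"`). `"auto"` picks quadrature when
#' the off-diagonal spread is below 0.1.
#'
#' @param model a [fit_cognitive_probit()] model (or a `truth_params`-style
#'   coefficient matrix wrapped by the caller)
#' @param persons population table rows with the covariate columns
#' @param method `"auto"`, `"quadrature"` or `"montecarlo"`
#' @param n_nodes Gauss-Hermite nodes (quadrature)
#' @param n_draws Monte Carlo draws
#' @return `data.table` with columns `p_fail`, `p_joint`, `p_joint <= p_fail`
#'   guaranteed
#' @export
predict_impairment_probability <- function(model, persons,
                                           method = c("auto", "quadrature", "montecarlo"),
                                           n_nodes = 40, n_draws = 8000) {
  method <- match.arg(method)
  persons <- data.table::as.data.table(persons)
  X <- probit_design_matrix(persons)
  eta <- X %*% t(model$coefficients)
  R <- model$correlation
  off <- R[upper.tri(R)]
  rho_bar <- mean(off)
  if (method == "auto") {
    method <- if (length(off) == 0 || (max(abs(off - rho_bar)) < 0.1 && rho_bar >= 0 && rho_bar < 1))
      "quadrature" else "montecarlo"
  }
  k <- model$battery_k %||% 2L
  test_idx <- 1:3
  iadl_idx <- 4:10

  if (method == "quadrature") {
    if (rho_bar < 0 || rho_bar >= 1) {
      stop_data("one-factor quadrature needs exchangeable rho in [0, 1)")
    }
    gh <- gauss_hermite_normal(n_nodes)
    n <- nrow(eta)
    p_fail <- p_joint <- numeric(n)
    s <- sqrt(rho_bar); t <- sqrt(1 - rho_bar)
    for (q in seq_len(n_nodes)) {
      pc <- pnorm((eta - s * gh$nodes[q]) / t)   # n x 10 conditional probs
      pf <- prob_at_least_k(pc[, test_idx, drop = FALSE], k)
      pi1 <- 1 - apply(1 - pc[, iadl_idx, drop = FALSE], 1, prod)
      p_fail <- p_fail + gh$weights[q] * pf
      p_joint <- p_joint + gh$weights[q] * pf * pi1
    }
  } else {
    set.seed(20160601L)  # fixed scramble seed: predictions are deterministic
    d <- ncol(eta)
    Z <- matrix(rnorm(n_draws * d), nrow = n_draws) %*% chol(R)
    n <- nrow(eta)
    p_fail <- p_joint <- numeric(n)
    chunk <- 256L
    for (i0 in seq(1, n, by = chunk)) {
      i1 <- min(n, i0 + chunk - 1L)
      for (i in i0:i1) {
        hit <- sweep(Z, 2, eta[i, ], "<=")
        fail <- rowSums(hit[, test_idx, drop = FALSE]) >= k
        anyi <- rowSums(hit[, iadl_idx, drop = FALSE]) >= 1
        p_fail[i] <- mean(fail)
        p_joint[i] <- mean(fail & anyi)
      }
    }
  }
  data.table::data.table(p_fail = pmin(1, pmax(0, p_fail)),
                         p_joint = pmin(p_fail, pmax(0, p_joint)))
}

# P(at least k of the independent Bernoulli(p) in each row succeed);
# p is an n x m matrix with small m (here m = 3).
prob_at_least_k <- function(p, k) {
  m <- ncol(p)
  n <- nrow(p)
  # distribution of the count by sequential convolution
  dist <- matrix(0, n, m + 1)
  dist[, 1] <- 1
  for (j in seq_len(m)) {
    pj <- p[, j]
    new <- matrix(0, n, m + 1)
    new[, 1] <- dist[, 1] * (1 - pj)
    for (c in 1:j) {
      new[, c + 1] <- dist[, c + 1] * (1 - pj) + dist[, c] * pj
    }
    dist <- new
  }
  rowSums(dist[, (k + 1):(m + 1), drop = FALSE])
}

#' Calibrate classification thresholds to target prevalences
#'
#' Finds, by bisection on the empirical prevalence step function, the
#' probability cutoffs such that the modelled prevalence of dementia (joint
#' probability at or above `theta_dementia`) and of MCI (battery-failure
#' probability at or above `theta_mci` among persons not labelled dementia)
#' match the target overall prevalences. Targets are matched within 1e-4
#' where the person-level granularity of the population permits; otherwise
#' to the nearest attainable share (one-person granularity, identical to the
#' order-statistic rule).
#'
#' @param probabilities `data.table` from [predict_impairment_probability()]
#' @param population population table the probabilities belong to (used for
#'   collapsing an age-sex target curve); may be `NULL` when `target` is
#'   already a pair of overall proportions
#' @param target either a named numeric vector/list with elements `dementia`
#'   and `mci`, or a [generate_target_prevalence()] curve (collapsed against
#'   `population`)
#' @param tolerance calibration tolerance on the absolute proportion
#' @param by optional grouping vector (e.g. `population$sex`): thresholds
#'   are then calibrated per group against the group-specific targets,
#'   instead of the default single global pair
#' @return object of class `cognition_thresholds`: `theta_dementia`,
#'   `theta_mci`, `achieved_dementia`, `achieved_mci`, `target` (each a
#'   named vector when `by` is used), plus `by_groups`
#' @export
calibrate_thresholds <- function(probabilities, population = NULL, target,
                                 tolerance = 1e-4, by = NULL) {
  if (!is.null(by)) {
    stopifnot(length(by) == nrow(probabilities))
    groups <- sort(unique(by))
    parts <- lapply(groups, function(g) {
      calibrate_thresholds(probabilities[by == g],
                           if (!is.null(population)) population[by == g],
                           target, tolerance = tolerance)
    })
    return(structure(list(
      theta_dementia = setNames(vapply(parts, `[[`, 0, "theta_dementia"), groups),
      theta_mci = setNames(vapply(parts, `[[`, 0, "theta_mci"), groups),
      achieved_dementia = setNames(vapply(parts, `[[`, 0, "achieved_dementia"), groups),
      achieved_mci = setNames(vapply(parts, `[[`, 0, "achieved_mci"), groups),
      target = lapply(setNames(parts, groups), `[[`, "target"),
      by_groups = groups
    ), class = "cognition_thresholds"))
  }
  if (inherits(target, "calibration_target")) {
    if (is.null(population)) stop_config("population needed to collapse a target curve")
    target <- c(
      dementia = overall_target_prevalence(target, population, "dementia"),
      mci = overall_target_prevalence(target, population, "mci")
    )
  }
  target <- unlist(target)[c("dementia", "mci")]
  check_prob(target, "target prevalences")

  dem <- calibrate_threshold_single(probabilities$p_joint, target[["dementia"]],
                                    tolerance = tolerance, what = "dementia")
  keep <- probabilities$p_joint < dem$theta
  # MCI share is counted over the whole population but only non-dementia
  # persons are eligible for the label
  p_mci <- ifelse(keep, probabilities$p_fail, -Inf)
  mci <- calibrate_threshold_single(p_mci, target[["mci"]],
                                    tolerance = tolerance, what = "MCI")
  structure(list(theta_dementia = dem$theta, theta_mci = mci$theta,
                 achieved_dementia = dem$achieved, achieved_mci = mci$achieved,
                 target = target, by_groups = NULL),
            class = "cognition_thresholds")
}

# Bisection on the decreasing step function g(theta) = mean(p >= theta).
calibrate_threshold_single <- function(p, target, tolerance = 1e-4,
                                       what = "condition") {
  check_prob(target, paste(what, "target"))
  n <- length(p)
  g <- function(theta) mean(p >= theta)
  if (target == 0) {
    theta <- 1
    if (g(theta) > 0) theta <- 1 + 1e-12  # all-probability-one corner
    return(list(theta = min(theta, 1), achieved = g(min(theta, 1)),
                target = target))
  }
  if (g(0) < target - tolerance) {
    stop_calibration(what, " target ", target, " unreachable; attainable range [0, ",
                     g(0), "]")
  }
  lo <- 0; hi <- 1 + 1e-9
  for (it in 1:80) {
    mid <- (lo + hi) / 2
    if (g(mid) >= target) lo <- mid else hi <- mid
  }
  g_lo <- g(lo); g_hi <- g(hi)
  cands <- unique(c(lo, hi, 1))
  ach <- vapply(cands, g, numeric(1))
  best <- which.min(abs(ach - target))
  theta <- min(cands[best], 1)
  achieved <- g(theta)
  # discreteness allowance: tied predictions make prevalence move in jumps of
  # the boundary tie-group share; accept the nearest attainable share up to
  # half that jump (capped at one percentage point -- beyond that the target
  # is effectively unattainable and silently mislabelling would be worse)
  allowed <- max(tolerance, 1.5 / n, min((g_lo - g_hi) / 2, 0.01))
  if (abs(achieved - target) > allowed) {
    stop_calibration(what, " target ", target,
                     " not attainable at person granularity; nearest achievable ",
                     achieved)
  }
  list(theta = theta, achieved = achieved, target = target)
}

#' Classify cognition into normal / MCI / dementia
#'
#' Dementia if the joint probability reaches `theta_dementia`; otherwise MCI
#' if the battery-failure probability reaches `theta_mci`; otherwise normal.
#' Deterministic given inputs.
#'
#' @param probabilities `data.table` from [predict_impairment_probability()]
#' @param thresholds a [calibrate_thresholds()] object
#' @param by grouping vector matching the one used at calibration, when the
#'   thresholds were calibrated per group
#' @return character vector in `c("normal", "MCI", "dementia")`
#' @export
classify_cognition <- function(probabilities, thresholds, by = NULL) {
  check_prob(c(thresholds$theta_dementia, thresholds$theta_mci), "thresholds")
  if (!is.null(thresholds$by_groups)) {
    if (is.null(by)) stop_config("these thresholds were calibrated per group; supply `by`")
    th_d <- thresholds$theta_dementia[by]
    th_m <- thresholds$theta_mci[by]
  } else {
    th_d <- thresholds$theta_dementia
    th_m <- thresholds$theta_mci
  }
  dem <- probabilities$p_joint >= th_d
  mci <- !dem & probabilities$p_fail >= th_m
  out <- rep("normal", nrow(probabilities))
  out[mci] <- "MCI"
  out[dem] <- "dementia"
  out
}
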