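#' @importFrom stats plogis qlogis pnorm qnorm dnorm glm glm.fit lm lm.fit
#'   rbinom rnorm runif rmultinom binomial coef vcov sd quantile setNames
#'   uniroot
#' @importFrom utils head tail
#' @import data.table
NULL

# The eleven chronic-condition flags carried by every simulated person.
CONDITION_COLS <- c(
  "diabetes", "chd", "stroke", "hypertension", "hyperlipidaemia",
  "cancer", "respiratory", "joint_condition", "eye_problem",
  "kidney", "other_dx"
)

EDUCATION_LEVELS <- c("lths", "hs", "college")
SEX_LEVELS <- c("female", "male")

AGE_CAP <- 105L

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Five-year age band label for parameter tables
#'
#' Bands run 60-64, 65-69, ..., 95-99 with an open 100+ band; ages are
#' floored to integers first. Ages above the simulation cap reuse the 100+
#' cell.
#'
#' @param age numeric vector of ages in years (>= 60)
#' @return character vector of band labels, e.g. "60-64", "100+"
#' @export
age_band <- function(age) {
  a <- pmin(floor(age), AGE_CAP)
  lo <- pmin(100, (a %/% 5L) * 5L)
  ifelse(lo >= 100, "100+", sprintf("%d-%d", lo, lo + 4L))
}

age_band_levels <- function() c(sprintf("%d-%d", seq(60, 95, 5), seq(64, 99, 5)), "100+")

# Midpoint age of a band label, used when evaluating age curves per band.
age_band_mid <- function(band) {
  lo <- suppressWarnings(as.numeric(sub("[-+].*", "", band)))
  ifelse(band == "100+", 102, lo + 2)
}

#' Convert between 3-year and half-year transition probabilities
#'
#' Assumes a constant hazard within the interval, so
#' `p_half = 1 - (1 - p3)^(1/6)` and conversely `p3 = 1 - (1 - p_half)^6`.
#'
#' @param p3 probability over a 3-year interval
#' @return half-year probability
#' @export
halfyear_prob_from_3yr <- function(p3) {
  stopifnot(all(p3 >= 0 & p3 <= 1))
  1 - (1 - p3)^(1 / 6)
}

#' @rdname halfyear_prob_from_3yr
#' @param p_half probability over a half-year interval
#' @export
threeyr_prob_from_halfyear <- function(p_half) {
  stopifnot(all(p_half >= 0 & p_half <= 1))
  1 - (1 - p_half)^6
}

# Deterministic sub-stream seeds: one global seed per run, modules draw from
# offsets so each can be regenerated independently. Kept below 2^31.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + 11 * offset) %% 2147483647)
}

stop_config <- function(...) {
  stop(structure(
    class = c("demfrailsim_config_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_data <- function(...) {
  stop(structure(
    class = c("demfrailsim_data_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_calibration <- function(...) {
  stop(structure(
    class = c("demfrailsim_calibration_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

check_prob <- function(x, what) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop_data(what, " must lie in [0, 1]")
  }
  invisible(x)
}
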