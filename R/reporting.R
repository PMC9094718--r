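#' Prevalence proportion in percent
#'
#' @param count non-negative count of cases
#' @param population positive population size, at least `count`
#' @param digits decimals reported (default 2)
#' @return `100 * count / population`, rounded
#' @export
proportion <- function(count, population, digits = 2) {
  if (any(population <= 0)) stop_data("population must be positive")
  if (any(count < 0) || any(count > population)) {
    stop_data("count must lie in [0, population]")
  }
  round(100 * count / population, digits)
}

#' Growth ratio and percent change between two values
#'
#' @param value_t1 later value
#' @param value_t0 earlier (baseline) value, positive
#' @return list with `ratio`, `percent_change`, and presentation roundings
#'   `ratio_1dp` (one decimal) and `percent_int` (nearest integer)
#' @export
change_ratio <- function(value_t1, value_t0) {
  if (any(value_t0 <= 0)) stop_data("baseline value must be positive")
  ratio <- value_t1 / value_t0
  list(ratio = ratio, percent_change = 100 * (ratio - 1),
       ratio_1dp = round(ratio, 1), percent_int = round(100 * (ratio - 1)))
}

fmt_interval <- function(mean, lo, hi, digits = 0) {
  sprintf("%s (%s-%s)",
          formatC(round(mean, digits), format = "f", digits = digits, big.mark = " "),
          formatC(round(lo, digits), format = "f", digits = digits, big.mark = " "),
          formatC(round(hi, digits), format = "f", digits = digits, big.mark = " "))
}

#' Projected-prevalence presentation table
#'
#' Reshapes a bootstrap ensemble's prevalence cells into the presentation
#' layout: rows by year, sex, age group (>= 60, 60-74, >= 75) and condition
#' (MCI, dementia, frailty, dementia-and-frailty), with weighted counts and
#' proportions as point estimates plus nearest-rank percentile intervals and
#' formatted "count (p5-p95)" strings.
#'
#' @param ensemble a [bootstrap_run()] result
#' @param years presentation years (must be covered by the runs)
#' @return `data.table` (class `prevalence_table`)
#' @export
build_prevalence_table <- function(ensemble, years) {
  sm <- ensemble$summary
  parse_key <- function(d) {
    parts <- data.table::tstrsplit(d$cell, "|", fixed = TRUE)
    d[, `:=`(year = as.numeric(parts[[1]]), sex = parts[[2]],
             education = parts[[3]], age_group = parts[[4]],
             condition = parts[[5]])]
    d
  }
  cnt <- parse_key(sm[table == "prevalence_count"])
  prp <- parse_key(sm[table == "prevalence_proportion"])
  missing_years <- setdiff(years, unique(cnt$year))
  if (length(missing_years)) {
    stop_data("ensemble lacks requested year(s): ",
              paste(missing_years, collapse = ", "))
  }
  cnt <- cnt[year %in% years]
  prp <- prp[year %in% years]
  out <- merge(
    cnt[, .(year, sex, education, age_group, condition,
            count = mean, count_p5 = p_lower, count_p95 = p_upper)],
    prp[, .(year, sex, education, age_group, condition,
            proportion = mean, proportion_p5 = p_lower, proportion_p95 = p_upper)],
    by = c("year", "sex", "education", "age_group", "condition")
  )
  out[, `:=`(
    count_formatted = fmt_interval(count, count_p5, count_p95, 0),
    proportion_formatted = fmt_interval(100 * proportion, 100 * proportion_p5,
                                        100 * proportion_p95, 2)
  )]
  check <- out[condition %in% c("dementia", "frailty", "dementia_and_frailty")]
  wide <- data.table::dcast(check, year + sex + education + age_group ~ condition,
                            value.var = "count")
  bad <- wide[dementia_and_frailty > pmin(dementia, frailty) + 1e-9]
  if (nrow(bad)) stop_data("intersection count exceeds a marginal count")
  structure(out[order(year, sex, education, age_group, condition)],
            class = c("prevalence_table", class(out)))
}

#' Backward-validation comparison
#'
#' Compares a projected summary against an observed table on matching
#' stratum keys: absolute and relative differences per cell, flagging cells
#' whose relative difference exceeds the tolerance.
#'
#' @param projected `data.table` with key columns and a `value` column
#' @param observed same layout with the observed values
#' @param keys character vector of key column names
#' @param tolerance relative-difference flag threshold (default 0.05)
#' @return `data.table` with per-cell `projected`, `observed`,
#'   `abs_diff`, `rel_diff`, `flagged`
#' @export
backward_validate <- function(projected, observed,
                              keys = setdiff(names(projected), "value"),
                              tolerance = 0.05) {
  pr <- data.table::as.data.table(projected)
  ob <- data.table::as.data.table(observed)
  m <- merge(pr[, c(keys, "value"), with = FALSE],
             ob[, c(keys, "value"), with = FALSE],
             by = keys, suffixes = c("_projected", "_observed"), all = TRUE)
  unmatched <- m[is.na(value_projected) | is.na(value_observed)]
  if (nrow(unmatched)) {
    stop_data("unmatched strata: ",
              paste(apply(unmatched[, keys, with = FALSE], 1, paste,
                          collapse = "/"), collapse = "; "))
  }
  m[, `:=`(
    projected = value_projected, observed = value_observed,
    abs_diff = value_projected - value_observed,
    rel_diff = ifelse(value_observed != 0,
                      (value_projected - value_observed) / value_observed,
                      ifelse(value_projected == 0, 0, Inf))
  )]
  m[, flagged := abs(rel_diff) > tolerance]
  m[, c(keys, "projected", "observed", "abs_diff", "rel_diff", "flagged"),
    with = FALSE]
}
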