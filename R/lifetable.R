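#' Period life table from age-specific mortality rates
#'
#' Standard period life-table recursion from occurrence/exposure rates.
#' Within each closed interval of width `n` the mid-interval convention
#' `a = n/2` gives `q = n m / (1 + (n - a) m)`; the final row is an open
#' interval with `q = 1` and `L = l / m`. Life expectancy is `e = T / l`.
#' The radix is 1, so `lx` is a survival proportion.
#'
#' @param ages starting age of each interval (increasing; last is open)
#' @param mx age-specific mortality rates (deaths per person-year)
#' @param widths interval widths for the closed intervals (length
#'   `length(ages) - 1` or a scalar, default 1)
#' @param stratum optional named list of labels attached as columns
#' @return `data.table` with columns `age`, `width`, `mx`, `qx`, `lx`, `Lx`,
#'   `Tx`, `ex` (class `life_table`)
#' @export
life_table <- function(ages, mx, widths = 1, stratum = NULL) {
  k <- length(ages)
  if (length(mx) != k) stop_data("ages and mx must have equal length")
  if (any(!is.finite(mx)) || any(mx < 0)) stop_data("mx must be finite and >= 0")
  if (is.unsorted(ages, strictly = TRUE)) stop_data("ages must be increasing")
  w <- rep_len(widths, k - 1)
  if (k > 1 && !all(abs(diff(ages) - w) < 1e-9)) {
    w <- diff(ages)  # trust the age grid when widths disagree
  }
  qx <- numeric(k)
  if (k > 1) {
    a <- w / 2
    qx[1:(k - 1)] <- pmin(1, w * mx[1:(k - 1)] / (1 + (w - a) * mx[1:(k - 1)]))
  }
  qx[k] <- 1
  lx <- cumprod(c(1, 1 - qx[-k]))
  Lx <- numeric(k)
  if (k > 1) {
    dx <- lx[1:(k - 1)] * qx[1:(k - 1)]
    Lx[1:(k - 1)] <- w * (lx[2:k] + 0.5 * dx)
  }
  if (mx[k] > 0) {
    Lx[k] <- lx[k] / mx[k]
  } else if (lx[k] > 0) {
    stop_data("open-interval mortality rate is zero with survivors remaining")
  }
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)
  out <- data.table::data.table(age = ages, width = c(w, NA_real_), mx = mx,
                                qx = qx, lx = lx, Lx = Lx, Tx = Tx, ex = ex)
  if (!is.null(stratum)) {
    for (nm in names(stratum)) data.table::set(out, j = nm, value = stratum[[nm]])
  }
  structure(out, class = c("life_table", class(out)))
}

#' Build a period life table from a simulated trajectory
#'
#' Aggregates the trajectory's recorded person-years and deaths for one
#' calendar year (and optional sex/education stratum) into
#' occurrence/exposure rates from `start_age`, then applies [life_table()].
#' Ages at and above `terminal_age` are pooled into the open interval.
#' A closed age cell with no exposure is an error naming the cell.
#'
#' @param trajectory a [simulate_population()] result
#' @param year calendar year of exposure; `NULL` pools the whole run (useful
#'   for closed-cohort runs with constant rates)
#' @param sex,education optional stratum filters
#' @param start_age life-table starting age (default 65)
#' @param terminal_age open-interval starting age (default 100)
#' @param abridged use 5-year age intervals instead of single years
#' @return a [life_table()] with stratum labels
#' @export
build_period_life_table <- function(trajectory, year, sex = NULL,
                                    education = NULL, start_age = 65,
                                    terminal_age = 100, abridged = FALSE) {
  ex <- trajectory$exposure
  sel <- if (is.null(year)) rep(TRUE, nrow(ex)) else ex$year == year
  if (!is.null(sex)) sel <- sel & ex$sex %in% sex
  if (!is.null(education)) sel <- sel & ex$education %in% education
  ex <- ex[sel & ex$age >= start_age]
  if (nrow(ex) == 0) {
    stop_data("no exposure recorded for year ",
              if (is.null(year)) "(all)" else year, " in the requested stratum")
  }
  if (abridged) {
    grp <- pmin(terminal_age, (ex$age %/% 5) * 5)
    grp <- pmax(grp, start_age)
  } else {
    grp <- pmin(terminal_age, ex$age)
  }
  agg <- data.table::data.table(age = grp, py = ex$py, deaths = ex$deaths)
  agg <- agg[, .(py = sum(py), deaths = sum(deaths)), by = age][order(age)]
  step <- if (abridged) 5 else 1
  full_ages <- c(seq(start_age, terminal_age - step, by = step), terminal_age)
  agg <- agg[data.table::data.table(age = full_ages), on = "age"]
  agg[is.na(py), `:=`(py = 0, deaths = 0)]
  zero <- agg$py <= 0
  if (any(zero)) {
    stop_data("zero exposure in age cell(s): ",
              paste(agg$age[zero], collapse = ", "),
              " (year ", year,
              if (!is.null(sex)) paste0(", sex ", paste(sex, collapse = "/")) else "",
              ")")
  }
  life_table(agg$age, agg$deaths / agg$py,
             widths = if (abridged) 5 else 1,
             stratum = list(year = if (is.null(year)) NA_real_ else year,
                            sex = if (is.null(sex)) "all" else paste(sex, collapse = "+"),
                            education = if (is.null(education)) "all" else
                              paste(education, collapse = "+")))
}

#' Sullivan partition of life expectancy
#'
#' Splits period life expectancy at the table's starting age into years
#' lived with and without a condition using age-specific prevalence:
#' `years_with = sum(prevalence * Lx) / l(start)`, `years_without = ex -
#' years_with`. The partition identity holds to machine precision.
#'
#' @param table a [life_table()]
#' @param prevalence age-specific proportion with the condition, one value
#'   per table row, each in `[0, 1]`
#' @return list with `total_ex`, `years_with`, `years_without`
#' @export
sullivan_partition <- function(table, prevalence) {
  if (length(prevalence) != nrow(table)) {
    stop_data("prevalence must have one value per life-table age")
  }
  check_prob(prevalence, "prevalence")
  years_with <- sum(prevalence * table$Lx) / table$lx[1]
  total <- table$ex[1]
  list(total_ex = total, years_with = years_with,
       years_without = total - years_with)
}

#' Age-specific condition prevalence aligned to a life table
#'
#' Computes, from a classified population snapshot, the proportion with the
#' condition in each life-table age interval. Empty intervals inherit the
#' nearest younger interval's value (documented smoothing for small runs).
#'
#' @param snapshot classified population `data.table` (alive rows are used)
#' @param table a [life_table()] giving the age grid
#' @param condition `"dementia"` (dementia_state == "dementia"), `"frailty"`,
#'   or a column name of 0/1 values
#' @param sex optional sex filter
#' @return numeric prevalence vector, one per table row
#' @export
condition_prevalence <- function(snapshot, table, condition, sex = NULL) {
  snap <- data.table::as.data.table(snapshot)
  snap <- snap[snap$alive]
  if (!is.null(sex)) snap <- snap[snap$sex %in% sex]
  flag <- switch(condition,
    dementia = snap$dementia_state == "dementia",
    frailty = as.logical(snap$frail),
    as.logical(snap[[condition]])
  )
  ages <- table$age
  k <- length(ages)
  upper <- c(ages[-1], Inf)
  prev <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    inb <- snap$age >= ages[i] & snap$age < upper[i]
    if (any(inb)) prev[i] <- mean(flag[inb])
  }
  for (i in seq_len(k)) {
    if (is.na(prev[i])) prev[i] <- if (i > 1) prev[i - 1] else 0
  }
  prev
}
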