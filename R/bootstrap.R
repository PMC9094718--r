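#' Bootstrap the full projection pipeline
#'
#' Runs [run_projection()] `n_iterations` times (default 50) with
#' independent seeds derived deterministically from the master seed. Each
#' iteration redraws the stochastic baseline population, the entry cohorts
#' and all transition randomness; estimated model coefficients are held
#' fixed. Iterations run sequentially; any failure aborts with the
#' iteration id and seed for replay.
#'
#' @param config a [generator_config()]
#' @param models a [fit_pipeline_models()] list
#' @param n_iterations bootstrap iterations (default 50)
#' @param master_seed master seed for the seed stream
#' @param ... further arguments passed to [run_projection()]
#' @return object of class `result_ensemble`: `draws` (long `data.table`
#'   with `iteration`, `seed`, `table`, `key`, `value`), `summary` (from
#'   [percentile_interval()]), `n_iterations`, `master_seed`, `runs`
#'   (the per-iteration `projection_run` manifests)
#' @export
bootstrap_run <- function(config, models, n_iterations = 50, master_seed = 1L,
                          ...) {
  if (n_iterations < 1) stop_config("n_iterations must be >= 1")
  set.seed(master_seed)
  iter_seeds <- sample.int(2147483646L, n_iterations)
  draws <- vector("list", n_iterations)
  manifests <- vector("list", n_iterations)
  for (i in seq_len(n_iterations)) {
    run <- tryCatch(
      run_projection(config, models, seed = iter_seeds[i], ...),
      error = function(e) {
        stop_data("bootstrap iteration ", i, " (seed ", iter_seeds[i],
                  ") failed: ", conditionMessage(e))
      }
    )
    flat <- flatten_run(run)
    flat[, `:=`(iteration = i, seed = iter_seeds[i])]
    draws[[i]] <- flat
    manifests[[i]] <- run$manifest
  }
  draws <- data.table::rbindlist(draws, use.names = TRUE)
  ens <- structure(list(draws = draws, n_iterations = n_iterations,
                        master_seed = master_seed, runs = manifests),
                   class = "result_ensemble")
  ens$summary <- percentile_interval(ens)
  ens
}

#' Nearest-rank empirical percentile
#'
#' @param x numeric vector
#' @param p percentile in (0, 100]
#' @return the `ceiling(p/100 * n)`-th smallest value
#' @export
nearest_rank_percentile <- function(x, p) {
  n <- length(x)
  if (n == 0) return(NA_real_)
  r <- min(n, max(1L, as.integer(ceiling(p / 100 * n))))
  sort(x, partial = r)[r]
}

#' Percentile-interval summary of a bootstrap ensemble
#'
#' Per result cell: mean across iterations, nearest-rank lower/upper
#' percentiles (default 5th and 95th) and the Monte-Carlo standard error
#' `sd / sqrt(n_iterations)`. Invariant to iteration order.
#'
#' @param ensemble a [bootstrap_run()] result (or its `draws` table)
#' @param lower,upper percentile bounds
#' @return `data.table` with `table`, `key`, `mean`, `p_lower`, `p_upper`,
#'   `mc_se`, `n`
#' @export
percentile_interval <- function(ensemble, lower = 5, upper = 95) {
  draws <- if (inherits(ensemble, "result_ensemble")) ensemble$draws else
    data.table::as.data.table(ensemble)
  draws[, .(
    mean = mean(value),
    p_lower = nearest_rank_percentile(value, lower),
    p_upper = nearest_rank_percentile(value, upper),
    mc_se = if (.N > 1) sd(value) / sqrt(.N) else 0,
    n = .N
  ), by = .(table, cell)]
}
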