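#' Read and write pipeline tables as CSV
#'
#' Thin wrappers over [data.table::fwrite()]/[data.table::fread()] fixing
#' the conventions (header row, period decimal separator, UTF-8) so that
#' every writer round-trips losslessly through its reader.
#'
#' @param x a `data.table`/`data.frame`
#' @param path file path
#' @return `read_table_csv` returns a `data.table`
#' @export
write_table_csv <- function(x, path) {
  data.table::fwrite(data.table::as.data.table(x), path)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  data.table::fread(path)
}

#' Read and write configuration files
#'
#' Configurations are stored as YAML key-value files.
#'
#' @param config a list-like configuration object
#' @param path file path
#' @return `read_config_yaml` returns a list
#' @export
write_config_yaml <- function(config, path) {
  cfg <- unclass(config)
  cfg <- rapply(cfg, function(x) {
    if (is.data.frame(x)) as.list(as.data.frame(x)) else x
  }, classes = "data.frame", how = "replace")
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' @rdname write_config_yaml
#' @export
read_config_yaml <- function(path) {
  yaml::read_yaml(path)
}

#' Serialize a fitted classification model to JSON
#'
#' Coefficients, standard errors, correlation matrix (probit), labels and
#' fit diagnostics, written so that [read_model_json()] reconstructs an
#' object usable for prediction.
#'
#' @param model a `probit_model` or `frailty_model`
#' @param path file path
#' @return `read_model_json` returns the model object
#' @export
write_model_json <- function(model, path) {
  obj <- list(class = class(model)[1])
  if (inherits(model, "probit_model")) {
    obj$coefficients <- model$coefficients
    obj$se <- model$se
    obj$correlation <- model$correlation
    obj$outcomes <- model$outcomes
    obj$battery_k <- model$battery_k
    obj$loglik <- model$loglik
    obj$n <- model$n
  } else if (inherits(model, "frailty_model")) {
    obj$coefficients <- as.list(model$coefficients)
    obj$se <- as.list(model$se)
    obj$loglik <- model$loglik
    obj$n <- model$n
  } else {
    stop_config("unsupported model class: ", class(model)[1])
  }
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (obj$class == "probit_model") {
    coefs <- as.matrix(obj$coefficients)
    dimnames(coefs) <- list(obj$outcomes, PROBIT_COVARIATES)
    se <- as.matrix(obj$se)
    dimnames(se) <- dimnames(coefs)
    R <- as.matrix(obj$correlation)
    dimnames(R) <- list(obj$outcomes, obj$outcomes)
    structure(list(coefficients = coefs, se = se, correlation = R,
                   loglik = obj$loglik, n = obj$n, outcomes = obj$outcomes,
                   battery_k = obj$battery_k),
              class = "probit_model")
  } else if (obj$class == "frailty_model") {
    structure(list(coefficients = unlist(obj$coefficients),
                   se = unlist(obj$se),
                   loglik = obj$loglik, n = obj$n, converged = TRUE),
              class = "frailty_model")
  } else {
    stop_data("unknown model class in ", path)
  }
}

#' Write a run manifest
#'
#' Records the seed, configuration fingerprint, horizon and calibrated
#' thresholds of a projection run as JSON.
#'
#' @param run a [run_projection()] result
#' @param path file path
#' @return the path, invisibly
#' @export
write_run_manifest <- function(run, path) {
  man <- run$manifest
  man$thresholds <- list(
    theta_dementia = run$thresholds$cognition$theta_dementia,
    theta_mci = run$thresholds$cognition$theta_mci,
    theta_frail = run$thresholds$frailty$theta_frail
  )
  man$weights <- as.list(run$weights)
  jsonlite::write_json(man, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}
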