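#' Write a JSON summary of a fit
#'
#' Serialises the parameter table (name, median, sd, ci_low, ci_high, rhat,
#' ess) plus model/MCMC settings to JSON.
#'
#' @param fit an `nma_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_summary <- function(fit, path) {
  stopifnot(inherits(fit, "nma_fit"))
  s <- fit$summary
  obj <- list(
    model = fit$spec$model,
    effects = fit$spec$effects,
    reference = fit$reference,
    treatments = fit$treatments,
    chains = fit$mcmc$chains,
    iterations = fit$mcmc$iterations,
    burn_in = fit$mcmc$burn_in,
    seed = fit$mcmc$seed,
    convergence_flag = fit$convergence_flag,
    parameters = data.frame(name = s$parameter, median = s$median,
                            sd = s$sd, ci_low = s$lower, ci_high = s$upper,
                            rhat = s$rhat, ess = s$ess)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' Write retained posterior draws as a flat CSV
#'
#' One column per parameter, one row per retained draw, with a leading
#' `chain` column.
#'
#' @param fit an `nma_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path) {
  stopifnot(inherits(fit, "nma_fit"))
  df <- data.frame(chain = fit$chain, fit$draws, check.names = FALSE)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# plain-text key=value config file; '#' starts a comment
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) != 2
  if (any(bad)) {
    stop_validation("malformed config line(s): ",
                    paste(lines[bad], collapse = "; "))
  }
  setNames(lapply(kv, function(x) trimws(x[2])),
           vapply(kv, function(x) trimws(x[1]), character(1)))
}
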