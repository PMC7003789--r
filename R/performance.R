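#' Expected familywise false-positive rate of independent tests
#'
#' In a star network with known heterogeneity and all effects truly zero, the
#' `T - 1` basic-parameter estimates are independent, so the chance that at
#' least one is "significant" at level `alpha` is
#' `1 - (1 - alpha)^(T - 1)` -- e.g. 62% for 20 treatments at the 5% level.
#'
#' @param n_treatments number of treatments `T` (>= 2).
#' @param alpha per-comparison significance level in (0, 1); 0 is allowed and
#'   returns 0.
#' @return probability of at least one false positive among the basic
#'   parameters.
#' @examples
#' expected_familywise_rate(20, 0.05)
#' @export
expected_familywise_rate <- function(n_treatments, alpha = 0.05) {
  stopifnot(n_treatments >= 2, alpha >= 0, alpha < 1)
  1 - (1 - alpha)^(n_treatments - 1)
}

#' Evaluate one fit against the simulation truth
#'
#' Computes, for a single fitted dataset: signed errors of the
#' basic-parameter posterior medians (effects versus the truth's first
#' treatment); per-contrast credible-interval exclusion and reversal flags
#' (interval excludes zero but the median has the wrong sign); and the
#' SUCRA-selected best and worst treatments with the posterior median and SD
#' of their contrast and of best versus reference.
#'
#' @param fit an `nma_fit`.
#' @param truth a [truth_table()] over the same treatments.
#' @param sucra_values optional precomputed [sucra()] vector.
#' @param direction ranking direction, see [rank_probabilities()].
#' @param level credible level for exclusion flags.
#' @return a list of class `fit_evaluation`.
#' @export
evaluate_fit <- function(fit, truth, sucra_values = NULL,
                         direction = "higher", level = 0.95) {
  stopifnot(inherits(fit, "nma_fit"), inherits(truth, "truth_table"))
  if (!setequal(fit$treatments, names(truth$psi))) {
    stop_validation("fit and truth cover different treatments")
  }
  eff <- effect_draws(fit)
  ref <- names(truth$psi)[1]

  basic <- setdiff(names(truth$psi), ref)
  med_basic <- vapply(basic,
                      function(t) median(eff[, t] - eff[, ref]), numeric(1))
  err_basic <- med_basic - unname(truth$psi[basic])

  ct <- contrast_summaries(fit, level = level)
  key <- function(a, b) paste(a, b, sep = "\r")
  tc <- truth$contrasts
  m <- match(key(ct$t1, ct$t2), key(tc$t1, tc$t2))
  ct$true <- tc$true_effect[m]
  ct$truly_zero <- tc$truly_zero[m]
  ct$reversal <- ct$excludes_zero & !ct$truly_zero &
    sign(ct$median) != sign(ct$true)

  if (is.null(sucra_values)) {
    sucra_values <- sucra(rank_probabilities(fit, direction))
  }
  bw <- select_best_worst(sucra_values)
  bw_draws <- contrast_draws(fit, bw$worst, bw$best)
  br_draws <- contrast_draws(fit, ref, bw$best)
  structure(list(
    err_basic = err_basic,
    contrasts = ct,
    sucra = sucra_values,
    best = bw$best, worst = bw$worst,
    best_vs_worst_median = median(bw_draws),
    best_vs_worst_sd = sd(bw_draws),
    best_vs_ref_median = median(br_draws),
    best_vs_ref_sd = sd(br_draws),
    convergence_flag = fit$convergence_flag
  ), class = "fit_evaluation")
}

#' Aggregate per-dataset evaluations into one metrics row
#'
#' Averages per-dataset results into the summary used throughout the
#' simulation study: mean absolute error and mean bias of the basic
#' parameters (averaged over datasets and parameters); the mean posterior
#' median and mean posterior SD of the SUCRA-best versus SUCRA-worst
#' contrast, and of best versus reference; the percentage of datasets in
#' which at least one truly-zero contrast's credible interval excludes zero
#' (confident-nonzero rate, among datasets that have truly-zero contrasts);
#' power as the percentage of truly-nonzero contrasts with interval excluding
#' zero, pooled over datasets; the reversal rate over all estimated
#' contrasts; and the mean (with range) of the per-dataset maximum and
#' minimum SUCRA.
#'
#' @param records list of [evaluate_fit()] results.
#' @param scenario,model labels copied into the output row.
#' @return one-row data frame of class `simulation_metrics`.
#' @export
aggregate_metrics <- function(records, scenario = NA_character_,
                              model = NA_character_) {
  stopifnot(length(records) >= 1)
  g <- function(f) vapply(records, f, numeric(1))
  mae <- g(function(r) mean(abs(r$err_basic)))
  bias <- g(function(r) mean(r$err_basic))

  has_zero <- vapply(records, function(r) any(r$contrasts$truly_zero),
                     logical(1))
  conf_nonzero <- if (any(has_zero)) {
    hits <- vapply(records[has_zero], function(r) {
      any(r$contrasts$excludes_zero & r$contrasts$truly_zero)
    }, logical(1))
    100 * mean(hits)
  } else NA_real_

  nz_flags <- unlist(lapply(records, function(r) {
    r$contrasts$excludes_zero[!r$contrasts$truly_zero]
  }))
  power <- if (length(nz_flags) > 0) 100 * mean(nz_flags) else NA_real_

  rev_flags <- unlist(lapply(records, function(r) r$contrasts$reversal))
  reversal <- 100 * mean(rev_flags)

  smax <- g(function(r) max(r$sucra))
  smin <- g(function(r) min(r$sucra))

  out <- data.frame(
    scenario = scenario, model = model,
    n_datasets = length(records),
    mae_basic = mean(mae), bias_basic = mean(bias),
    best_vs_worst_mean = mean(g(function(r) r$best_vs_worst_median)),
    best_vs_worst_sd = mean(g(function(r) r$best_vs_worst_sd)),
    best_vs_ref_mean = mean(g(function(r) r$best_vs_ref_median)),
    best_vs_ref_sd = mean(g(function(r) r$best_vs_ref_sd)),
    confident_nonzero_rate = conf_nonzero,
    power = power,
    reversal_rate = reversal,
    sucra_max_mean = mean(smax),
    sucra_max_low = min(smax), sucra_max_high = max(smax),
    sucra_min_mean = mean(smin),
    sucra_min_low = min(smin), sucra_min_high = max(smin),
    n_convergence_flags = sum(g(function(r) as.numeric(r$convergence_flag))),
    stringsAsFactors = FALSE)
  class(out) <- c("simulation_metrics", class(out))
  out
}

#' Model specification by simulation-protocol label
#'
#' Maps the labels used in the simulation study to full [model_spec()]
#' objects: `"I-flat"` (flat priors, SD 100), `"I-inf"` (informative,
#' SD 1), `"II"` (control = treatment 1), `"III"`, `"IV"` (classes 2-5 and
#' 6-10, control 1) and `"V"` (classes 1-5 and 6-10). Random-effects
#' versions are used for the scenarios whose generator has study-level
#' random effects (family B); all other scenarios are analysed with the
#' common-effect versions.
#'
#' @param label one of `"I-flat"`, `"I-inf"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param config the [make_scenario()] configuration being analysed.
#' @return a [model_spec()].
#' @export
paper_model_spec <- function(label, config) {
  stopifnot(inherits(config, "scenario_config"))
  trt <- names(config$truth$psi)
  effects <- if (config$random_effects) "random" else "common"
  if (label %in% c("IV", "V") && config$n_treatments != 10) {
    stop_validation("Model ", label,
                    " presets require the 10-treatment scenarios")
  }
  switch(label,
    "I-flat" = model_spec("I", effects, priors = prior_spec(d_sd = 100)),
    "I-inf"  = model_spec("I", effects, priors = prior_spec(d_sd = 1)),
    "II"  = model_spec("II", effects, control = trt[1]),
    "III" = model_spec("III", effects),
    "IV"  = model_spec("IV", effects, control = trt[1],
                       classes = class_map(setNames(
                         rep(c("c1", "c2"), c(4, 5)), trt[2:10]),
                         control = trt[1])),
    "V"   = model_spec("V", effects,
                       classes = class_map(setNames(
                         rep(c("c1", "c2"), c(5, 5)), trt))),
    stop_validation("unknown model label '", label, "'"))
}

#' Run a simulation study
#'
#' For each scenario: generates `n_datasets` datasets from per-dataset seed
#' substreams, fits every requested model to the same datasets (so model
#' comparisons are paired), evaluates each fit against the scenario truth and
#' aggregates. Per-dataset fit failures are caught, logged and excluded; a
#' failure rate above 5% for any model aborts the run.
#'
#' @param scenarios character vector of scenario names ([make_scenario()]).
#' @param models character vector of model labels ([paper_model_spec()]) or
#'   a named list of [model_spec()] objects.
#' @param n_datasets datasets per scenario.
#' @param mcmc an [mcmc_settings()]; its seed is replaced by per-fit
#'   substream seeds derived from `base_seed`.
#' @param base_seed integer seed governing the whole study.
#' @param direction ranking direction.
#' @param keep_records also return the per-dataset [evaluate_fit()] records.
#' @param progress print progress messages.
#' @return a data frame with one [aggregate_metrics()] row per
#'   (scenario, model); attributes `records` (if requested), `failures`, and
#'   `manifest` (seeds and settings).
#' @export
run_study <- function(scenarios, models, n_datasets,
                      mcmc = mcmc_settings(chains = 2, iterations = 4000,
                                           burn_in = 1000),
                      base_seed = 1L, direction = "higher",
                      keep_records = FALSE, progress = FALSE) {
  stopifnot(n_datasets >= 1)
  rows <- list()
  records_all <- list()
  failures <- list()
  for (si in seq_along(scenarios)) {
    sc_name <- scenarios[si]
    config <- make_scenario(sc_name)
    seed_sc <- substream_seed(base_seed, si, stream = 777L)
    datasets <- simulate_datasets(config, n_datasets, seed_sc)

    model_list <- if (is.list(models)) models else {
      setNames(lapply(models, paper_model_spec, config = config), models)
    }
    for (mi in seq_along(model_list)) {
      m_name <- names(model_list)[mi]
      spec <- model_list[[mi]]
      recs <- list()
      fails <- character()
      for (i in seq_len(n_datasets)) {
        fit_seed <- substream_seed(seed_sc, i, stream = 100L + mi)
        res <- tryCatch({
          fit <- fit_nma(datasets[[i]], spec,
                         mcmc = modifyList(mcmc, list(seed = fit_seed)))
          evaluate_fit(fit, config$truth, direction = direction)
        }, error = function(e) e)
        if (inherits(res, "error")) {
          fails <- c(fails, sprintf("dataset %d: %s", i,
                                    conditionMessage(res)))
        } else {
          recs[[length(recs) + 1]] <- res
        }
        if (progress && i %% 25 == 0) {
          message(sprintf("[%s / %s] %d/%d datasets", sc_name, m_name, i,
                          n_datasets))
        }
      }
      if (length(fails) > 0.05 * n_datasets) {
        stop("more than 5% of fits failed for ", sc_name, " / ", m_name,
             "; first error: ", fails[1])
      }
      rows[[length(rows) + 1]] <- aggregate_metrics(recs, sc_name, m_name)
      if (keep_records) records_all[[paste(sc_name, m_name)]] <- recs
      if (length(fails) > 0) failures[[paste(sc_name, m_name)]] <- fails
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "failures") <- failures
  attr(out, "manifest") <- list(
    scenarios = scenarios,
    models = if (is.list(models)) names(models) else models,
    n_datasets = n_datasets, base_seed = base_seed,
    mcmc = unclass(mcmc)[c("chains", "iterations", "burn_in", "thin")],
    direction = direction,
    seed_rule = "scenario seed = substream_seed(base_seed, scenario_index, 777); dataset i seed = substream_seed(scenario_seed, i); fit seed = substream_seed(scenario_seed, i, 100 + model_index); chain c adds c")
  if (keep_records) attr(out, "records") <- records_all
  out
}
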