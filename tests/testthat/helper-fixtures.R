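# Shared fixtures and small helpers for the test suite.

# three treatments, one study per edge, unit SEs; GLS solution d_B=1, d_C=2
triangle_data <- function() {
  contrast_data(data.frame(study = c("s1", "s2", "s3"),
                           t1 = c("A", "B", "A"),
                           t2 = c("B", "C", "C"),
                           y = c(1, 1, 2), se = 1))
}

quick_mcmc <- function(seed = 1, iterations = 3000, burn_in = 500) {
  mcmc_settings(chains = 2, iterations = iterations, burn_in = burn_in,
                seed = seed)
}

# Monte Carlo standard error of a posterior median estimated from draws
mcse_median <- function(x, ess = length(x)) {
  1.2533 * stats::sd(x) / sqrt(ess)
}

# minimal nma_fit carrying given effect draws (symmetric layout so
# effect_draws() returns them unchanged); enough for ranking/evaluation code
fake_fit <- function(eff, convergence_flag = FALSE) {
  trt <- colnames(eff)
  colnames(eff) <- paste0("d[", trt, "]")
  structure(list(draws = eff, chain = rep(1L, nrow(eff)),
                 components = trt, symmetric = TRUE,
                 treatments = trt, reference = trt[1],
                 spec = model_spec("III"),
                 mcmc = mcmc_settings(1, 10, 0),
                 summary = NULL, convergence_flag = convergence_flag),
            class = "nma_fit")
}

write_temp_csv <- function(text) {
  path <- tempfile(fileext = ".csv")
  writeLines(text, path)
  path
}
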