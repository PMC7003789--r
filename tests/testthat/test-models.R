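test_that("Model I common-effect with flat priors matches the GLS oracle", {
  cd <- triangle_data()
  g <- fit_fixed_effect_gls(cd)
  fit <- fit_nma(cd, model_spec("I"), quick_mcmc(seed = 11,
                                                 iterations = 6000,
                                                 burn_in = 1000))
  for (k in c("B", "C")) {
    x <- contrast_draws(fit, "A", k)
    expect_lt(abs(mean(x) - g$estimate[k]), 3 * mcse_median(x))
    expect_lt(abs(sd(x) - g$se[k]) / g$se[k], 0.05)
  }
  # contrast B-C has GLS value d_C - d_B = 1
  bc <- contrast_draws(fit, "B", "C")
  expect_lt(abs(median(bc) - 1), 3 * mcse_median(bc))
})

test_that("contrasts are consistent by construction in every draw", {
  fit <- fit_nma(triangle_data(), model_spec("III"), quick_mcmc(seed = 2))
  ab <- contrast_draws(fit, "A", "B")
  bc <- contrast_draws(fit, "B", "C")
  ac <- contrast_draws(fit, "A", "C")
  expect_equal(ab + bc, ac, tolerance = 1e-12)
  # sign symmetry of summaries
  expect_equal(median(contrast_draws(fit, "C", "B")), -median(bc))
})

test_that("contrast table enumerates all pairs", {
  cd <- simulate_dataset(make_scenario("A.1"), seed = 3)
  fit <- fit_nma(cd, model_spec("I"), quick_mcmc(seed = 3,
                                                 iterations = 1500,
                                                 burn_in = 500))
  ct <- contrast_summaries(fit)
  expect_equal(nrow(ct), 45)
  expect_true(all(ct$lower <= ct$median & ct$median <= ct$upper))
})

test_that("conditional Model II posterior is the precision-weighted mean", {
  # one study, hyperparameters fixed: the d posterior is exactly
  # N((y/s^2 + m/t^2)/(1/s^2 + 1/t^2), ...) -- check mean and the two
  # pooling limits tau_d -> 0 (extreme pooling) and tau_d -> inf (none)
  cd <- contrast_data(data.frame(study = "s1", t1 = "A", t2 = "B",
                                 y = 1, se = 0.5))
  fit_at <- function(td, m = 0.2) {
    sp <- model_spec("II", control = "A",
                     priors = prior_spec(mu_d_fixed = m,
                                         tau_d_prior = "fixed",
                                         tau_d_fixed = td))
    fit_nma(cd, sp, quick_mcmc(seed = 4, iterations = 6000, burn_in = 500))
  }
  f <- fit_at(0.3)
  expected <- (1 / 0.25 + 0.2 / 0.09) / (1 / 0.25 + 1 / 0.09)
  x <- f$draws[, "d[B]"]
  expect_lt(abs(mean(x) - expected), 3 * sd(x) / sqrt(length(x)))

  f0 <- fit_at(1e-3)
  expect_lt(abs(median(f0$draws[, "d[B]"]) - 0.2), 0.005)

  finf <- fit_at(50)
  g <- fit_nma(cd, model_spec("I"), quick_mcmc(seed = 5, iterations = 6000,
                                               burn_in = 500))
  expect_lt(abs(median(finf$draws[, "d[B]"]) - median(g$draws[, "d[B]"])),
            3 * sqrt(2) * mcse_median(g$draws[, "d[B]"]))
})

test_that("sampled effects reproduce the symmetric prior covariance", {
  # with an uninformative likelihood the posterior equals the prior, so the
  # empirical covariance of the draws must match Sigma_d
  cd <- contrast_data(data.frame(study = paste0("s", 1:3),
                                 t1 = c("A", "A", "A"),
                                 t2 = c("B", "C", "D"),
                                 y = 0, se = 1e4))
  sp <- model_spec("III", priors = prior_spec(tau_d_prior = "fixed",
                                              tau_d_fixed = 1))
  fit <- fit_nma(cd, sp, quick_mcmc(seed = 6, iterations = 11000,
                                    burn_in = 1000))
  d <- fit$draws[, paste0("d[", c("A", "B", "C", "D"), "]")]
  S <- cov(d)
  target <- matrix(0.5, 4, 4); diag(target) <- 1
  expect_lt(max(abs(S - target)), 0.08)
  expect_lt(max(abs(colMeans(d))), 0.05)
})

test_that("Model III preserves symmetry on null data", {
  cd <- contrast_data(data.frame(study = paste0("s", 1:3),
                                 t1 = c("A", "B", "A"),
                                 t2 = c("B", "C", "C"),
                                 y = 0, se = 0.1))
  fit <- fit_nma(cd, model_spec("III"), quick_mcmc(seed = 7))
  ct <- contrast_summaries(fit)
  expect_true(all(abs(ct$median) < 0.05))
  expect_false(any(ct$excludes_zero))
})

test_that("marginalised sampler agrees with the theta-sampled hierarchy", {
  cfg <- custom_scenario(c("1" = 0, "2" = 0.3, "3" = 0.6, "4" = 0),
                         geometry = "star", studies_per_comparison = 3,
                         random_effects = TRUE)
  cd <- simulate_dataset(cfg, seed = 11)
  rec <- cd$records
  fit <- fit_nma(cd, model_spec("I", effects = "random"),
                 mcmc_settings(2, 20000, 5000, seed = 4))

  ms <- "model {
    for (i in 1:S) {
      y[i] ~ dnorm(theta[i], 1/(se[i]*se[i]))
      theta[i] ~ dnorm(d[t2[i]] - d[t1[i]], 1/(tau*tau))
    }
    d[1] <- 0
    for (k in 2:T) { d[k] ~ dnorm(0, 0.0001) }
    tau ~ dunif(0, 5)
  }"
  jm <- rjags::jags.model(textConnection(ms),
                          data = list(y = rec$y, se = rec$se,
                                      t1 = as.integer(rec$t1),
                                      t2 = as.integer(rec$t2),
                                      S = nrow(rec), T = 4),
                          n.chains = 2, quiet = TRUE)
  update(jm, 5000, progress.bar = "none")
  samp <- rjags::coda.samples(jm, c("d", "tau"), n.iter = 15000,
                              progress.bar = "none")
  M <- as.matrix(samp)
  for (k in 2:4) {
    mine <- fit$draws[, paste0("d[", k, "]")]
    theirs <- M[, paste0("d[", k, "]")]
    tol <- 3 * sqrt(mcse_median(mine, ess = 4000)^2 +
                      mcse_median(theirs, ess = 4000)^2)
    expect_lt(abs(median(mine) - median(theirs)), tol)
  }
  expect_lt(abs(median(fit$draws[, "tau"]) - median(M[, "tau"])), 0.05)
})

test_that("multi-class models run and report class hyperparameters", {
  cfg <- make_scenario("H.1")
  cd <- simulate_dataset(cfg, seed = 8)
  fit4 <- fit_nma(cd, paper_model_spec("IV", cfg),
                  quick_mcmc(seed = 8, iterations = 2500))
  expect_true(all(c("mu_d[c1]", "mu_d[c2]", "tau_d[c1]", "tau_d[c2]") %in%
                    fit4$summary$parameter))
  fit5 <- fit_nma(cd, paper_model_spec("V", cfg),
                  quick_mcmc(seed = 8, iterations = 2500))
  expect_true(all(c("mu_d[c1]", "mu_d[c2]") %in% fit5$summary$parameter))
  # class means should track the class-level truths (1 and 2) loosely
  s4 <- fit4$summary
  expect_lt(abs(s4$median[s4$parameter == "mu_d[c1]"] - 1), 0.75)
  expect_lt(abs(s4$median[s4$parameter == "mu_d[c2]"] - 2), 0.75)
  # tying the class SDs collapses them to a single parameter
  sp <- model_spec("IV", control = "1", classes = fit4$spec$classes,
                   common_class_sd = TRUE)
  fitc <- fit_nma(cd, sp, quick_mcmc(seed = 9, iterations = 1500))
  expect_true("tau_d" %in% fitc$summary$parameter)
  expect_false(any(grepl("tau_d\\[", fitc$summary$parameter)))
})

test_that("multi-arm studies get a joint likelihood and PD checks", {
  cd <- contrast_data(data.frame(study = c("s1", "s1", "s2"),
                                 t1 = c("A", "A", "B"),
                                 t2 = c("B", "C", "C"),
                                 y = c(0.4, 0.6, 0.1), se = c(0.3, 0.4, 0.3)))
  fit <- fit_nma(cd, model_spec("I", effects = "random"),
                 quick_mcmc(seed = 10, iterations = 2500))
  expect_true(all(is.finite(fit$summary$median)))
  bad_cov <- matrix(c(0.09, 0.2, 0, 0.2, 0.16, 0, 0, 0, 0.09), 3)
  expect_error(fit_nma(cd, model_spec("I"), quick_mcmc(seed = 1,
                                                       iterations = 1000),
                       sampling_cov = bad_cov),
               "positive definite")
})

test_that("fits are bit-reproducible under a fixed seed", {
  cd <- simulate_dataset(make_scenario("C"), seed = 5)
  f1 <- fit_nma(cd, model_spec("II", control = "1"), quick_mcmc(seed = 42))
  f2 <- fit_nma(cd, model_spec("II", control = "1"), quick_mcmc(seed = 42))
  expect_identical(f1$draws, f2$draws)
})

test_that("invalid specifications fail before sampling", {
  cd <- triangle_data()
  expect_error(fit_nma(cd, model_spec("II", control = "Z"),
                       quick_mcmc(iterations = 1000)), "not in the network")
  dis <- contrast_data(data.frame(study = c("s1", "s2"),
                                  t1 = c("A", "C"), t2 = c("B", "D"),
                                  y = 0, se = 1))
  expect_error(fit_nma(dis, model_spec("I"), quick_mcmc(iterations = 1000)),
               "disconnected")
})
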