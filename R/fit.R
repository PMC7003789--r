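#' Fit a Bayesian NMA model by MCMC
#'
#' Fits one of Models I-V to a contrast-level dataset with a blocked Gibbs
#' sampler: the effect vector is drawn from its conjugate multivariate-normal
#' full conditional, class means from conjugate normals, and the SD
#' parameters (`tau`, `tau_d`) by slice sampling on the SD scale, honouring
#' their uniform or half-normal priors. Study-level random effects are
#' marginalised analytically (`y_i ~ N(d[t2]-d[t1], s_i^2 + tau^2)`), which
#' is equivalent to the hierarchical formulation for two-arm contrast data.
#' Records sharing a `study` id (multi-arm trials) get a joint
#' multivariate-normal likelihood with `tau^2/2` random-effects covariance
#' between contrasts of the same study; their sampling covariance is taken
#' from `sampling_cov` or approximated by a shared baseline-arm variance
#' (half the smallest contrast variance in the study).
#'
#' For Models II and IV the declared control becomes the reference, so that
#' basic parameters are effects versus the control. All pairwise contrasts
#' are formed deterministically from the sampled effects, never sampled
#' separately, so consistency (`d_jk + d_kl = d_jl`) holds exactly per draw.
#'
#' @param data a [contrast_data()] object with a connected network.
#' @param spec a [model_spec()].
#' @param mcmc an [mcmc_settings()].
#' @param sampling_cov optional full within-study sampling covariance matrix
#'   (n records x n records) for datasets with multi-arm studies.
#' @return an object of class `nma_fit`; see [contrast_summaries()],
#'   [rank_probabilities()], and the `summary` element (posterior median, SD,
#'   equal-tailed 95% credible interval, split-Rhat and effective sample size
#'   per parameter). `convergence_flag` is `TRUE` if any split-Rhat exceeds
#'   1.05.
#' @examples
#' cd <- contrast_data(data.frame(study = c("s1", "s2", "s3"),
#'                                t1 = c("A", "B", "A"),
#'                                t2 = c("B", "C", "C"),
#'                                y = c(1, 1, 2), se = 1))
#' fit <- fit_nma(cd, model_spec("I"), mcmc_settings(2, 2000, 500, seed = 7))
#' fit$summary
#' @export
fit_nma <- function(data, spec, mcmc = mcmc_settings(),
                    sampling_cov = NULL) {
  stopifnot(inherits(data, "contrast_data"), inherits(spec, "model_spec"),
            inherits(mcmc, "mcmc_settings"))
  if (!is_connected(data)) {
    stop("network is disconnected; fit each component separately")
  }
  if (!is.null(spec$control) && !spec$control %in% data$treatments) {
    stop_validation("control '", spec$control, "' is not in the network")
  }
  # Models II/IV: basic parameters are effects versus the control
  if (spec$model %in% c("II", "IV") && data$reference != spec$control) {
    data$reference <- spec$control
  }
  st <- effect_structure(spec, data$treatments, data$reference)
  X <- design_matrix(data, symmetric = st$symmetric)
  X <- X[, st$components, drop = FALSE]
  rec <- data$records
  random <- spec$effects == "random"

  multi <- anyDuplicated(rec$study) > 0
  if (multi) {
    blocks <- build_study_blocks(rec, sampling_cov)
    Smat <- blocks$Smat
    Pmat <- blocks$Pmat
  } else {
    Smat <- Pmat <- matrix(0, 0, 0)
  }
  diag_path <- !multi

  p <- ncol(X)
  Cinv <- solve(st$C)
  pr <- spec$priors

  n_keep <- (mcmc$iterations - mcmc$burn_in) %/% mcmc$thin
  draws <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    set.seed(mcmc$seed + ch)
    d0 <- rnorm(p, 0, 0.5)
    mu0 <- if (st$n_mu > 0) rnorm(st$n_mu, 0, 0.5) else numeric()
    tau_d0 <- if (st$n_tau > 0) {
      vapply(seq_len(st$n_tau), function(g) {
        switch(as.character(st$tau_d_type[g]),
               "0" = runif(1, 0.1, 0.9) * st$tau_d_par[g],
               "1" = abs(rnorm(1, 0, st$tau_d_par[g])) + 0.05,
               "2" = st$tau_d_par[g])
      }, numeric(1))
    } else numeric()
    tau0 <- if (random) runif(1, 0.05, min(1, pr$tau_upper)) else 0
    draws[[ch]] <- gibbs_nma_cpp(
      y = rec$y, X = X, s2 = rec$se^2, Smat = Smat, Pmat = Pmat,
      diag_path = diag_path, random_effects = random,
      tau_upper = pr$tau_upper, Cinv = Cinv,
      mu_map = st$mu_map, mu_prior_var = pr$mu_d_var, n_mu = st$n_mu,
      tau_map = st$tau_map, fixed_sd = st$fixed_sd,
      fixed_mean = st$fixed_mean, n_tau = st$n_tau,
      tau_d_type = st$tau_d_type, tau_d_par = st$tau_d_par,
      n_iter = mcmc$iterations, n_burn = mcmc$burn_in, thin = mcmc$thin,
      d0 = d0, mu0 = mu0, tau_d0 = tau_d0, tau0 = tau0)
  }
  par_names <- c(paste0("d[", st$components, "]"), st$mu_names,
                 st$tau_names, if (random) "tau")
  draws <- lapply(draws, function(m) {
    colnames(m) <- par_names
    m
  })
  all_draws <- do.call(rbind, draws)
  chain_id <- rep(seq_len(mcmc$chains), each = n_keep)

  summ <- summarise_draws(draws)
  tau_prior_driven <- random && length(unique(rec$study)) <=
    length(st$components)  # no replication to inform tau

  structure(list(
    draws = all_draws, chain = chain_id,
    components = st$components, symmetric = st$symmetric,
    treatments = data$treatments, reference = data$reference,
    spec = spec, mcmc = mcmc, data = data,
    summary = summ,
    convergence_flag = any(summ$rhat > 1.05, na.rm = TRUE),
    tau_prior_driven = tau_prior_driven
  ), class = "nma_fit")
}

# block-diagonal sampling covariance and random-effects structure matrices
# for datasets containing multi-arm studies
build_study_blocks <- function(rec, sampling_cov) {
  n <- nrow(rec)
  Pmat <- diag(n)
  if (is.null(sampling_cov)) {
    Smat <- diag(rec$se^2)
  } else {
    stopifnot(is.matrix(sampling_cov), all(dim(sampling_cov) == n))
    Smat <- sampling_cov
  }
  for (s in unique(rec$study)) {
    idx <- which(rec$study == s)
    if (length(idx) < 2) next
    for (i in idx) for (j in idx) {
      if (i == j) next
      Pmat[i, j] <- 0.5
      if (is.null(sampling_cov)) {
        # shared baseline-arm variance approximation
        Smat[i, j] <- min(rec$se[idx]^2) / 2
      }
    }
  }
  ok <- tryCatch({ chol(Smat); TRUE }, error = function(e) FALSE)
  if (!ok) {
    stop("within-study sampling covariance is not positive definite; ",
         "supply `sampling_cov` explicitly")
  }
  list(Smat = Smat, Pmat = Pmat)
}

summarise_draws <- function(chain_list) {
  par_names <- colnames(chain_list[[1]])
  rows <- lapply(seq_along(par_names), function(j) {
    x <- unlist(lapply(chain_list, function(m) m[, j]), use.names = FALSE)
    q <- quantile(x, c(0.025, 0.5, 0.975), names = FALSE)
    data.frame(parameter = par_names[j],
               median = q[2], sd = sd(x), lower = q[1], upper = q[3],
               rhat = split_rhat(lapply(chain_list, function(m) m[, j])),
               ess = ess_mean(lapply(chain_list, function(m) m[, j])),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior draws of treatment effects for all treatments
#'
#' Returns a draws x T matrix of treatment effects on a common additive
#' scale: for the asymmetric models the reference column is identically zero;
#' for the symmetric models the sampled effects are returned as-is (only
#' contrasts are identified, but rank statistics are invariant to the common
#' shift).
#'
#' @param fit an `nma_fit` object.
#' @return numeric matrix, columns named by treatment.
#' @export
effect_draws <- function(fit) {
  stopifnot(inherits(fit, "nma_fit"))
  d <- fit$draws[, paste0("d[", fit$components, "]"), drop = FALSE]
  if (fit$symmetric) {
    colnames(d) <- fit$components
    return(d[, fit$treatments, drop = FALSE])
  }
  out <- matrix(0, nrow(d), length(fit$treatments),
                dimnames = list(NULL, fit$treatments))
  out[, fit$components] <- d
  out
}

#' Posterior draws of one pairwise contrast
#'
#' @param fit an `nma_fit` object.
#' @param t1,t2 treatment labels; the returned draws are the effect of `t2`
#'   versus `t1` (`d[t2] - d[t1]`).
#' @return numeric vector of posterior draws.
#' @export
contrast_draws <- function(fit, t1, t2) {
  eff <- effect_draws(fit)
  stopifnot(t1 %in% colnames(eff), t2 %in% colnames(eff))
  eff[, t2] - eff[, t1]
}

#' Summaries of all pairwise contrasts
#'
#' Tabulates the posterior median, SD and equal-tailed 95% credible interval
#' of `d[t2] - d[t1]` for all T(T-1)/2 unordered treatment pairs, plus a flag
#' for intervals excluding zero.
#'
#' @param fit an `nma_fit` object.
#' @param level credible level, 0.95 by default.
#' @return data frame with columns `t1, t2, median, sd, lower, upper,
#'   excludes_zero`.
#' @export
contrast_summaries <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "nma_fit"))
  eff <- effect_draws(fit)
  pairs <- all_pairs(fit$treatments)
  alpha <- (1 - level) / 2
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- eff[, pairs$t2[i]] - eff[, pairs$t1[i]]
    q <- quantile(x, c(alpha, 0.5, 1 - alpha), names = FALSE)
    data.frame(t1 = pairs$t1[i], t2 = pairs$t2[i],
               median = q[2], sd = sd(x), lower = q[1], upper = q[3],
               excludes_zero = q[1] > 0 || q[3] < 0,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.nma_fit <- function(x, ...) {
  cat("Bayesian NMA fit: Model", x$spec$model,
      paste0("(", x$spec$effects, " effects)"),
      "| reference:", x$reference, "\n")
  cat("  ", x$mcmc$chains, " chains x ", x$mcmc$iterations, " iterations (",
      x$mcmc$burn_in, " burn-in), ", nrow(x$draws), " retained draws\n",
      sep = "")
  if (x$convergence_flag) {
    cat("  WARNING: split-Rhat > 1.05 for at least one parameter\n")
  }
  print(x$summary, digits = 3, row.names = FALSE)
  invisible(x)
}
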