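#' Prior settings for NMA models
#'
#' Defaults reproduce the simulation protocol: flat normal priors with SD 100
#' on independent basic parameters, `mu_d ~ N(0, variance 10)` for the
#' exchangeable mean, `tau_d ~ U(0, 2)` for the between-treatment SD and
#' `tau ~ U(0, 5)` for the heterogeneity SD. A half-normal prior on `tau_d`
#' (used in applied analyses without a good guess for its upper bound) and
#' point-mass ("fixed") values of `mu_d` / `tau_d` (useful for conditional
#' shrinkage checks) are also supported.
#'
#' @param d_sd prior SD of independent basic parameters (Model I); 100 is the
#'   flat default, 1 the "informative" variant.
#' @param mu_d_var prior variance of the exchangeable mean(s) `mu_d`.
#' @param mu_d_fixed if numeric, `mu_d` is held at this value, not sampled.
#' @param tau_d_prior `"uniform"`, `"halfnormal"` or `"fixed"`.
#' @param tau_d_upper upper bound of the uniform prior on `tau_d`.
#' @param tau_d_scale scale of the half-normal prior on `tau_d`.
#' @param tau_d_fixed value of `tau_d` when `tau_d_prior = "fixed"`.
#' @param tau_upper upper bound of the uniform prior on the heterogeneity SD.
#' @return a list of class `prior_spec`.
#' @export
prior_spec <- function(d_sd = 100, mu_d_var = 10, mu_d_fixed = NULL,
                       tau_d_prior = c("uniform", "halfnormal", "fixed"),
                       tau_d_upper = 2, tau_d_scale = 1, tau_d_fixed = NULL,
                       tau_upper = 5) {
  tau_d_prior <- match.arg(tau_d_prior)
  stopifnot(d_sd > 0, mu_d_var > 0, tau_d_upper > 0, tau_d_scale > 0,
            tau_upper > 0)
  if (tau_d_prior == "fixed" && is.null(tau_d_fixed)) {
    stop("tau_d_prior = 'fixed' requires tau_d_fixed")
  }
  if (!is.null(tau_d_fixed)) stopifnot(tau_d_fixed > 0)
  structure(list(d_sd = d_sd, mu_d_var = mu_d_var, mu_d_fixed = mu_d_fixed,
                 tau_d_prior = tau_d_prior, tau_d_upper = tau_d_upper,
                 tau_d_scale = tau_d_scale, tau_d_fixed = tau_d_fixed,
                 tau_upper = tau_upper),
            class = "prior_spec")
}

#' Model specification for NMA fitting
#'
#' Selects one of the five models and its effect structure:
#' \describe{
#'   \item{I}{standard NMA: independent normal priors on the basic
#'     parameters (flat, `d_sd = 100`, or informative, `d_sd = 1`).}
#'   \item{II}{exchangeable effects: all non-control basic parameters share
#'     `d_k ~ N(mu_d, tau_d^2)`; requires a declared `control`.}
#'   \item{III}{symmetric exchangeable effects: all `T` treatment effects
#'     jointly normal with pairwise correlation 0.5 and mean 0 (the mean does
#'     not contribute to the likelihood); no control needed.}
#'   \item{IV}{exchangeable effects within multiple classes of non-control
#'     treatments, each class with its own mean and SD; requires `control`
#'     and `classes`.}
#'   \item{V}{symmetric multi-class model: 0.5-correlated effects within each
#'     class, independence across classes, class means sampled; requires
#'     `classes` covering every treatment, no control.}
#' }
#'
#' @param model one of `"I"`, `"II"`, `"III"`, `"IV"`, `"V"`.
#' @param effects `"common"` (heterogeneity fixed at zero) or `"random"`
#'   (heterogeneity SD sampled under `tau ~ U(0, tau_upper)`).
#' @param control control treatment label (required for II and IV).
#' @param classes a [class_map()] (required for IV and V).
#' @param common_class_sd share a single `tau_d` across classes (IV/V).
#' @param priors a [prior_spec()].
#' @return a list of class `model_spec`.
#' @export
model_spec <- function(model = c("I", "II", "III", "IV", "V"),
                       effects = c("common", "random"),
                       control = NULL, classes = NULL,
                       common_class_sd = FALSE,
                       priors = prior_spec()) {
  model <- match.arg(model)
  effects <- match.arg(effects)
  stopifnot(inherits(priors, "prior_spec"))
  if (model %in% c("II", "IV") && is.null(control)) {
    stop_validation("Model ", model, " requires a declared control treatment")
  }
  if (model %in% c("IV", "V") && is.null(classes)) {
    stop_validation("Model ", model, " requires a class map")
  }
  if (!is.null(classes)) stopifnot(inherits(classes, "class_map"))
  structure(list(model = model, effects = effects, control = control,
                 classes = classes, common_class_sd = common_class_sd,
                 priors = priors),
            class = "model_spec")
}

#' MCMC settings
#'
#' Defaults follow the fitting protocol used throughout the simulations: two
#' independent chains of 15000 iterations with a 5000-iteration burn-in.
#' Chain `c` is seeded with `seed + c`, so runs are bit-reproducible.
#'
#' @param chains number of independent chains.
#' @param iterations iterations per chain (including burn-in).
#' @param burn_in discarded initial iterations per chain.
#' @param thin keep every `thin`-th post-burn-in draw.
#' @param seed integer base seed.
#' @return a list of class `mcmc_settings`.
#' @export
mcmc_settings <- function(chains = 2L, iterations = 15000L, burn_in = 5000L,
                          thin = 1L, seed = 1L) {
  stopifnot(chains >= 1, iterations >= 1, burn_in >= 0, thin >= 1,
            burn_in < iterations)
  structure(list(chains = as.integer(chains),
                 iterations = as.integer(iterations),
                 burn_in = as.integer(burn_in),
                 thin = as.integer(thin),
                 seed = as.integer(seed)),
            class = "mcmc_settings")
}

# Internal description of the prior on the effect vector d for a given model:
# which components there are (one per non-reference treatment, or per
# treatment for the symmetric models), the fixed correlation matrix C, and
# maps from components to sampled class means / SDs.
effect_structure <- function(spec, treatments, reference) {
  model <- spec$model
  symmetric <- model %in% c("III", "V")
  comps <- if (symmetric) treatments else setdiff(treatments, reference)
  p <- length(comps)
  C <- diag(p)
  mu_map <- rep(-1L, p)
  tau_map <- rep(-1L, p)
  fixed_sd <- rep(spec$priors$d_sd, p)
  fixed_mean <- rep(0, p)
  mu_names <- character()
  tau_names <- character()

  if (model == "II") {
    if (!is.null(spec$priors$mu_d_fixed)) {
      fixed_mean[] <- spec$priors$mu_d_fixed
    } else {
      mu_map[] <- 0L
      mu_names <- "mu_d"
    }
    tau_map[] <- 0L
    tau_names <- "tau_d"
  } else if (model == "III") {
    C <- matrix(0.5, p, p); diag(C) <- 1
    tau_map[] <- 0L          # mu_d does not contribute; fixed at zero
    tau_names <- "tau_d"
  } else if (model %in% c("IV", "V")) {
    cm <- spec$classes$classes
    need <- if (model == "IV") setdiff(comps, spec$control) else comps
    missing_cls <- setdiff(need, names(cm))
    if (length(missing_cls) > 0) {
      stop_validation("treatment(s) without a class: ",
                      paste(missing_cls, collapse = ", "))
    }
    labels <- unique(unname(cm[need]))
    for (k in seq_len(p)) {
      cls <- cm[[comps[k]]]
      g <- match(cls, labels) - 1L
      mu_map[k] <- g
      tau_map[k] <- if (spec$common_class_sd) 0L else g
    }
    mu_names <- paste0("mu_d[", labels, "]")
    tau_names <- if (spec$common_class_sd) "tau_d"
                 else paste0("tau_d[", labels, "]")
    if (model == "V") {
      for (g in seq_along(labels) - 1L) {
        idx <- which(mu_map == g)
        C[idx, idx] <- 0.5
      }
      diag(C) <- 1
    }
  }
  n_tau <- length(tau_names)
  pr <- spec$priors
  tau_d_type <- rep(switch(pr$tau_d_prior, uniform = 0L, halfnormal = 1L,
                           fixed = 2L), n_tau)
  tau_d_par <- rep(switch(pr$tau_d_prior,
                          uniform = pr$tau_d_upper,
                          halfnormal = pr$tau_d_scale,
                          fixed = pr$tau_d_fixed), n_tau)
  list(components = comps, symmetric = symmetric, C = C,
       mu_map = mu_map, tau_map = tau_map,
       fixed_sd = fixed_sd, fixed_mean = fixed_mean,
       mu_names = mu_names, tau_names = tau_names,
       n_mu = length(mu_names), n_tau = n_tau,
       tau_d_type = tau_d_type, tau_d_par = tau_d_par)
}

#' Prior mean and covariance of the effect vector
#'
#' Returns the conditional prior of the effect vector `d` implied by a model
#' specification at given hyperparameter values: independent `d_sd^2`
#' variances for Model I; `tau_d^2` variances around `mu_d` for Model II;
#' the TxT matrix with `tau_d^2` on the diagonal and `0.5 tau_d^2` elsewhere
#' for Model III; class-blocked versions of these for Models IV and V.
#'
#' @param spec a [model_spec()].
#' @param treatments character vector of treatment labels.
#' @param reference the reference treatment (defaults to the first).
#' @param tau_d between-treatment SD value(s): one per class for IV/V unless
#'   `common_class_sd`, recycled as needed.
#' @param mu_d exchangeable mean value(s), recycled likewise; defaults to 0.
#' @return list with `mean` (named vector) and `cov` (matrix) over the model's
#'   effect components (all treatments for III/V, non-reference otherwise).
#' @examples
#' sp <- model_spec("III")
#' prior_covariance(sp, c("A", "B", "C"), tau_d = 1)$cov
#' @export
prior_covariance <- function(spec, treatments, reference = treatments[1],
                             tau_d = NULL, mu_d = 0) {
  st <- effect_structure(spec, treatments, reference)
  p <- length(st$components)
  sd_vec <- st$fixed_sd
  if (any(st$tau_map >= 0)) {
    if (is.null(tau_d)) stop("model has sampled tau_d; supply `tau_d`")
    tau_d <- rep_len(tau_d, max(st$tau_map) + 1L)
    sd_vec[st$tau_map >= 0] <- tau_d[st$tau_map[st$tau_map >= 0] + 1L]
  }
  mean_vec <- st$fixed_mean
  if (st$n_mu > 0) {
    mu_d <- rep_len(mu_d, st$n_mu)
    mean_vec[st$mu_map >= 0] <- mu_d[st$mu_map[st$mu_map >= 0] + 1L]
  }
  cov <- st$C * tcrossprod(sd_vec)
  dimnames(cov) <- list(st$components, st$components)
  list(mean = setNames(mean_vec, st$components), cov = cov)
}
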