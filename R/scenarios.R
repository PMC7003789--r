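#' Scenario configurations for the simulation study
#'
#' Returns the data-generating configuration for one of the 14 built-in
#' scenarios. Scenario families and their true effects versus treatment 1:
#' \describe{
#'   \item{A}{10 equally effective treatments, 1 study per comparison.}
#'   \item{B}{as A but 3 studies per comparison and study-level random
#'     effects with per-dataset `tau^2 ~ LogNormal(-2.56, 1.74^2)` (an
#'     empirical heterogeneity distribution for log-OR outcomes).}
#'   \item{C}{2 equally effective treatments, 5 studies.}
#'   \item{D}{3 equally effective treatments, fully connected.}
#'   \item{E}{`psi_t = 1` for every active treatment versus control.}
#'   \item{F}{treatments 1-5 worthless, 6-10 effective (`psi = 1`).}
#'   \item{G}{all different: `psi_t = 0.9 + 0.1 t` for `t > 1`.}
#'   \item{H}{control plus two classes: `psi = 1` (treatments 2-5) and
#'     `psi = 2` (treatments 6-10).}
#' }
#' Suffix `.1` denotes a star network (every study versus treatment 1),
#' `.2` a fully connected network; C is a single comparison and D is only
#' fully connected.
#'
#' @param name scenario name: one of `"A.1"`, `"A.2"`, `"B.1"`, `"B.2"`,
#'   `"C"`, `"D"`, `"E.1"`, `"E.2"`, `"F.1"`, `"F.2"`, `"G.1"`, `"G.2"`,
#'   `"H.1"`, `"H.2"`.
#' @return a list of class `scenario_config` with fields `name`,
#'   `n_treatments`, `geometry`, `studies_per_comparison`, `random_effects`,
#'   and `truth` (a `truth_table`).
#' @examples
#' make_scenario("A.1")
#' @export
make_scenario <- function(name) {
  known <- c("A.1", "A.2", "B.1", "B.2", "C", "D",
             "E.1", "E.2", "F.1", "F.2", "G.1", "G.2", "H.1", "H.2")
  if (!name %in% known) {
    stop_validation("unknown scenario '", name, "'; expected one of: ",
                    paste(known, collapse = ", "))
  }
  family <- substr(name, 1, 1)
  variant <- if (nchar(name) > 1) substr(name, 3, 3) else ""
  T_n <- switch(family, C = 2L, D = 3L, 10L)
  geometry <- if (family == "D") "complete"
              else if (family == "C") "star"
              else if (variant == "1") "star" else "complete"
  spc <- switch(family, B = 3L, C = 5L, 1L)
  psi <- switch(family,
    A = , B = , C = , D = rep(0, T_n),
    E = c(0, rep(1, 9)),
    F = c(rep(0, 5), rep(1, 5)),
    G = c(0, 0.9 + 0.1 * (2:10)),
    H = c(0, rep(1, 4), rep(2, 5)))
  structure(list(name = name, n_treatments = T_n, geometry = geometry,
                 studies_per_comparison = spc,
                 random_effects = family == "B",
                 truth = truth_table(setNames(psi, as.character(seq_len(T_n))))),
            class = "scenario_config")
}

#' Custom scenario configuration
#'
#' Builds a `scenario_config` outside the 14 built-in ones.
#'
#' @param psi named numeric vector of true effects versus the first
#'   treatment (first element must be 0).
#' @param geometry `"star"` or `"complete"`.
#' @param studies_per_comparison number of studies per network edge.
#' @param random_effects draw per-dataset heterogeneity
#'   `tau^2 ~ LogNormal(-2.56, 1.74^2)`.
#' @return a `scenario_config`.
#' @export
custom_scenario <- function(psi, geometry = c("star", "complete"),
                            studies_per_comparison = 1L,
                            random_effects = FALSE) {
  geometry <- match.arg(geometry)
  if (is.null(names(psi))) names(psi) <- as.character(seq_along(psi))
  stopifnot(length(psi) >= 2, psi[[1]] == 0, studies_per_comparison >= 1)
  structure(list(name = "custom", n_treatments = length(psi),
                 geometry = geometry,
                 studies_per_comparison = as.integer(studies_per_comparison),
                 random_effects = random_effects,
                 truth = truth_table(psi)),
            class = "scenario_config")
}

#' True treatment effects and derived contrasts
#'
#' @param psi named numeric vector of per-treatment true effects versus the
#'   first treatment (`psi[1] = 0`).
#' @return a list of class `truth_table` with `psi` and `contrasts` (a data
#'   frame of all pairwise true effects `psi[t2] - psi[t1]` with a
#'   `truly_zero` indicator).
#' @export
truth_table <- function(psi) {
  stopifnot(!is.null(names(psi)), length(psi) >= 2)
  pairs <- all_pairs(names(psi))
  pairs$true_effect <- unname(psi[pairs$t2] - psi[pairs$t1])
  pairs$truly_zero <- abs(pairs$true_effect) < 1e-12
  structure(list(psi = psi, contrasts = pairs), class = "truth_table")
}

#' True effect of one contrast
#'
#' @param truth a [truth_table()].
#' @param t1,t2 treatment labels; returns `psi[t2] - psi[t1]`.
#' @return a number.
#' @export
true_contrast <- function(truth, t1, t2) {
  stopifnot(inherits(truth, "truth_table"))
  unname(truth$psi[t2] - truth$psi[t1])
}

#' Draw study standard errors
#'
#' Standard errors follow `s_i = 0.5 + 0.2 * X` with `X ~ chi-square(1)`,
#' giving a minimum of 0.5, mean 0.7 and variance 0.08 -- typical precision
#' of a modest trial on the log-OR scale.
#'
#' @param n number of draws.
#' @return numeric vector of positive standard errors.
#' @export
draw_standard_errors <- function(n) {
  stopifnot(n >= 1)
  0.5 + 0.2 * rchisq(n, df = 1)
}

#' Draw per-dataset heterogeneity variances
#'
#' `tau^2 ~ LogNormal(-2.56, 1.74^2)`, an empirical distribution of
#' between-study heterogeneity for binary-outcome meta-analyses; the median
#' is `exp(-2.56) ~= 0.077`.
#'
#' @param n number of draws (one per dataset).
#' @return numeric vector of heterogeneity variances.
#' @export
draw_heterogeneity <- function(n = 1) {
  stopifnot(n >= 1)
  exp(rnorm(n, mean = -2.56, sd = 1.74))
}

scenario_edges <- function(config) {
  T_n <- config$n_treatments
  trt <- names(config$truth$psi)
  if (config$geometry == "star") {
    data.frame(t1 = trt[1], t2 = trt[-1], stringsAsFactors = FALSE)
  } else {
    all_pairs(trt)  # reference edges first, then lexicographic pairs
  }
}

#' Simulate one contrast-level dataset from a scenario
#'
#' For every network edge and every replicate study, draws the standard
#' error `s_i = 0.5 + 0.2 chi^2_1`, then the observed effect
#' `y_i ~ N(psi[t2] - psi[t1], s_i^2)`; under random effects the
#' study-specific true effect is first drawn as
#' `theta_i ~ N(psi[t2] - psi[t1], tau^2)` with one
#' `tau^2 ~ LogNormal(-2.56, 1.74^2)` shared by all comparisons of the
#' dataset. Only two-arm studies are generated; study ids are `s1, s2, ...`
#' in deterministic edge order (reference edges first, then remaining pairs
#' in lexicographic order, replicates consecutive).
#'
#' @param config a [make_scenario()] or [custom_scenario()] configuration.
#' @param seed optional integer; if given, the RNG is seeded first so the
#'   dataset is a pure function of (config, seed).
#' @return a [contrast_data()] object with attributes `truth` (the
#'   scenario's [truth_table()]) and `tau2` (the heterogeneity variance
#'   used, 0 for common-effect scenarios).
#' @examples
#' cd <- simulate_dataset(make_scenario("A.1"), seed = 1)
#' network_summary(cd)
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  if (!is.null(seed)) set.seed(seed)
  edges <- scenario_edges(config)
  k <- config$studies_per_comparison
  t1 <- rep(edges$t1, each = k)
  t2 <- rep(edges$t2, each = k)
  n <- length(t1)
  true_eff <- unname(config$truth$psi[t2] - config$truth$psi[t1])
  tau2 <- if (config$random_effects) draw_heterogeneity(1) else 0
  s <- draw_standard_errors(n)
  theta <- if (config$random_effects) {
    rnorm(n, true_eff, sqrt(tau2))
  } else true_eff
  y <- rnorm(n, theta, s)
  cd <- contrast_data(data.frame(study = paste0("s", seq_len(n)),
                                 t1 = t1, t2 = t2, y = y, se = s,
                                 stringsAsFactors = FALSE),
                      treatments = names(config$truth$psi))
  attr(cd, "truth") <- config$truth
  attr(cd, "tau2") <- tau2
  cd
}

#' Simulate a batch of datasets with per-dataset substreams
#'
#' Dataset `i` is generated under seed `substream_seed(base_seed, i)`, so any
#' single dataset can be regenerated without replaying the whole batch and
#' the batch is invariant to its total size.
#'
#' @param config a scenario configuration.
#' @param n number of datasets.
#' @param base_seed integer base seed.
#' @return list of [contrast_data()] objects.
#' @export
simulate_datasets <- function(config, n, base_seed) {
  lapply(seq_len(n), function(i) {
    simulate_dataset(config, seed = substream_seed(base_seed, i))
  })
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("Scenario", x$name, "-", x$n_treatments, "treatments,",
      x$geometry, "network,", x$studies_per_comparison,
      "studies/comparison,",
      if (x$random_effects) "random effects" else "common effect", "\n")
  cat("  psi:", paste(x$truth$psi, collapse = ", "), "\n")
  invisible(x)
}
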