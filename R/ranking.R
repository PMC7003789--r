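#' Posterior rank probabilities
#'
#' For each retained draw, treatments are ranked by their effect on the
#' common additive scale (the reference included with effect zero); rank 1 is
#' best. Entry `[k, r]` of the result is the fraction of draws in which
#' treatment `k` attains rank `r`. Ties (probability zero for continuous
#' draws) are broken by treatment order.
#'
#' @param fit an `nma_fit` object.
#' @param direction `"higher"` if larger effects are better (the default,
#'   matching simulations where positive effects denote benefit) or
#'   `"lower"`.
#' @return a T x T matrix of class `rank_matrix`; rows are treatments,
#'   columns ranks. Rows and columns each sum to one.
#' @examples
#' cd <- contrast_data(data.frame(study = c("s1", "s2"), t1 = "A",
#'                                t2 = c("B", "C"), y = c(1, 2), se = 0.1))
#' fit <- fit_nma(cd, model_spec("I"), mcmc_settings(2, 1500, 500, seed = 1))
#' rank_probabilities(fit)
#' @export
rank_probabilities <- function(fit, direction = c("higher", "lower")) {
  direction <- match.arg(direction)
  eff <- effect_draws(fit)
  structure(rank_matrix_from_draws(eff, direction),
            class = c("rank_matrix", "matrix"))
}

# vectorised per-draw ranking: rank of k = 1 + #better + #equal-with-lower-
# index (ties, probability zero for continuous draws, go to treatment order)
rank_matrix_from_draws <- function(eff, direction = "higher") {
  score <- if (direction == "higher") -eff else eff
  T_n <- ncol(score)
  n <- nrow(score)
  ranks <- matrix(1L, n, T_n)
  for (k in seq_len(T_n)) {
    for (j in seq_len(T_n)) {
      if (j == k) next
      better <- score[, j] < score[, k]
      if (j < k) better <- better | (score[, j] == score[, k])
      ranks[, k] <- ranks[, k] + better
    }
  }
  counts <- matrix(0, T_n, T_n, dimnames = list(colnames(eff), seq_len(T_n)))
  for (k in seq_len(T_n)) {
    tab <- tabulate(ranks[, k], nbins = T_n)
    counts[k, ] <- tab
  }
  counts / n
}

#' SUCRA: surface under the cumulative ranking curve
#'
#' `SUCRA_k = sum_{r=1}^{T-1} P(rank_k <= r) / (T-1)`: 1 means certainly
#' best, 0 certainly worst; values always average to 0.5 across treatments.
#'
#' @param ranks a [rank_probabilities()] matrix.
#' @return named numeric vector of SUCRA values in `[0, 1]`.
#' @export
sucra <- function(ranks) {
  stopifnot(is.matrix(ranks), nrow(ranks) == ncol(ranks))
  T_n <- ncol(ranks)
  if (T_n < 2) stop("need at least two treatments")
  cum <- t(apply(ranks, 1, cumsum))
  rowSums(cum[, seq_len(T_n - 1), drop = FALSE]) / (T_n - 1)
}

#' Select the SUCRA-best and SUCRA-worst treatments
#'
#' Argmax and argmin of the SUCRA values; ties broken deterministically by
#' treatment order.
#'
#' @param sucra_values named vector as returned by [sucra()].
#' @return list with elements `best` and `worst` (treatment labels).
#' @export
select_best_worst <- function(sucra_values) {
  stopifnot(length(sucra_values) >= 2, !is.null(names(sucra_values)))
  # best: first maximum in treatment order; worst: last minimum, so that a
  # fully tied vector selects (first, last)
  worst_idx <- max(which(sucra_values == min(sucra_values)))
  list(best = names(sucra_values)[which.max(sucra_values)],
       worst = names(sucra_values)[worst_idx])
}

#' SUCRA table
#'
#' Convenience wrapper producing the exportable `treatment,sucra,mean_rank`
#' table from a fit.
#'
#' @inheritParams rank_probabilities
#' @return data frame with columns `treatment`, `sucra`, `mean_rank`.
#' @export
sucra_table <- function(fit, direction = c("higher", "lower")) {
  ranks <- rank_probabilities(fit, direction)
  s <- sucra(ranks)
  mean_rank <- drop(ranks %*% seq_len(ncol(ranks)))
  data.frame(treatment = rownames(ranks), sucra = unname(s),
             mean_rank = unname(mean_rank), stringsAsFactors = FALSE)
}
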