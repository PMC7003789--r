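#' Analytic common-effect NMA fit by generalized least squares
#'
#' Solves the weighted least-squares problem for the basic parameters with
#' weights `1/se^2` (the common-effect model with heterogeneity fixed at
#' zero). Serves as the analytic counterpart -- and testing oracle -- for the
#' Bayesian common-effect Model I with flat priors.
#'
#' @param data a [contrast_data()] object; the network must be connected.
#' @return a list of class `gls_fit` with `estimate` (named vector of basic
#'   parameters, effects versus the reference), `vcov`, `se`, and `reference`.
#' @examples
#' cd <- contrast_data(data.frame(study = c("s1", "s2", "s3"),
#'                                t1 = c("A", "B", "A"),
#'                                t2 = c("B", "C", "C"),
#'                                y = c(1, 1, 2), se = 1))
#' fit_fixed_effect_gls(cd)$estimate
#' @export
fit_fixed_effect_gls <- function(data) {
  stopifnot(inherits(data, "contrast_data"))
  if (!is_connected(data)) {
    stop("network is disconnected; basic parameters are not estimable")
  }
  X <- design_matrix(data)
  w <- 1 / data$records$se^2
  XtWX <- crossprod(X * sqrt(w))
  XtWy <- crossprod(X, w * data$records$y)
  V <- tryCatch(solve(XtWX), error = function(e) {
    stop("weighted normal equations are singular: ", conditionMessage(e))
  })
  est <- drop(V %*% XtWy)
  names(est) <- colnames(X)
  structure(list(estimate = est, vcov = V,
                 se = sqrt(diag(V)), reference = data$reference),
            class = "gls_fit")
}

#' @export
print.gls_fit <- function(x, ...) {
  cat("Common-effect NMA (GLS), reference:", x$reference, "\n")
  print(data.frame(estimate = x$estimate, se = x$se))
  invisible(x)
}
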