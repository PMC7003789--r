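# Convergence diagnostics: split-Rhat and a basic effective-sample-size
# estimate (initial positive sequence on chain-averaged autocorrelations).

split_chains <- function(chain_list) {
  out <- list()
  for (x in chain_list) {
    n <- length(x)
    if (n < 4) return(chain_list)
    h <- n %/% 2
    out <- c(out, list(x[seq_len(h)], x[(n - h + 1):n]))
  }
  out
}

split_rhat <- function(chain_list) {
  ch <- split_chains(chain_list)
  m <- length(ch)
  n <- min(lengths(ch))
  if (n < 2) return(NA_real_)
  ch <- lapply(ch, function(x) x[seq_len(n)])
  means <- vapply(ch, mean, numeric(1))
  vars <- vapply(ch, var, numeric(1))
  W <- mean(vars)
  B <- n * var(means)
  if (W < .Machine$double.eps) return(1)  # constant draws (degenerate)
  sqrt(((n - 1) / n * W + B / n) / W)
}

ess_mean <- function(chain_list, max_lag = 200L) {
  n <- min(lengths(chain_list))
  m <- length(chain_list)
  if (n < 4) return(NA_real_)
  lag_max <- min(max_lag, n - 2L)
  acfs <- vapply(chain_list, function(x) {
    drop(acf(x[seq_len(n)], lag.max = lag_max, plot = FALSE,
             demean = TRUE)$acf)
  }, numeric(lag_max + 1L))
  rho <- rowMeans(acfs)
  if (!is.finite(rho[1])) return(m * n)  # zero-variance parameter
  # initial positive sequence: sum paired autocorrelations while positive
  s <- 0
  k <- 1L
  while (k + 1L <= lag_max) {
    pair <- rho[k + 1L] + if (k + 2L <= lag_max + 1L) rho[k + 2L] else 0
    if (!is.finite(pair) || pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  max(m * n / (1 + 2 * s), 1)
}
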