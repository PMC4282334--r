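# Effective sample size by Geyer's initial positive sequence estimator:
# sum autocovariances in adjacent pairs until a pair sum goes negative.
ess_chain <- function(x) {
  n <- length(x)
  if (n < 4 || stats::var(x) == 0) return(as.numeric(n))
  lag_max <- min(n - 2L, 500L)
  rho <- as.numeric(stats::acf(x, lag.max = lag_max, plot = FALSE,
                               demean = TRUE)$acf)
  s <- 0
  m <- 0L
  while (2L * m + 2L <= lag_max) {
    pair <- rho[2L * m + 2L] + rho[2L * m + 3L]   # acf[1] is lag 0
    if (pair <= 0) break
    s <- s + pair
    m <- m + 1L
  }
  tau <- max(1, -rho[1] + 2 * (rho[1] + s))  # rho[1] = 1 (lag 0)
  min(n, n / tau)
}

# Gaussian deviance: -2 log likelihood of y given mean mu and residual
# variance sig2e.
gaussian_deviance <- function(y, mu, sig2e) {
  length(y) * log(2 * pi * sig2e) + sum((y - mu)^2) / sig2e
}

as_num <- function(x) as.numeric(as.matrix(x))
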