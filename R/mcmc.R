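# Shared MCMC machinery: inverse-gamma draws, a univariate slice sampler,
# and split-Rhat convergence diagnostics.

.rinvgamma <- function(n, shape, rate) 1 / stats::rgamma(n, shape = shape, rate = rate)

# Univariate slice sampler (Neal 2003, stepping out + shrinkage) on an
# unconstrained coordinate. logf must be finite at x0.
.slice1 <- function(x0, logf, w = 1, max_steps = 50L) {
  y <- logf(x0) - stats::rexp(1L)
  u <- stats::runif(1L)
  lo <- x0 - w * u
  hi <- lo + w
  k <- max_steps
  while (k > 0L && logf(lo) > y) { lo <- lo - w; k <- k - 1L }
  k <- max_steps
  while (k > 0L && logf(hi) > y) { hi <- hi + w; k <- k - 1L }
  repeat {
    x1 <- stats::runif(1L, lo, hi)
    if (logf(x1) > y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
    if (hi - lo < 1e-12) return(x0)
  }
}

# Split-Rhat (Gelman et al.): each chain is split in half; the classical
# potential scale reduction factor is computed over the 2*m half-chains.
.split_rhat <- function(draws_by_chain) {
  halves <- list()
  for (d in draws_by_chain) {
    n <- length(d)
    if (n < 4L) return(NA_real_)
    half <- floor(n / 2)
    halves <- c(halves, list(d[seq_len(half)], d[(n - half + 1L):n]))
  }
  m <- length(halves)
  n <- length(halves[[1L]])
  means <- vapply(halves, mean, numeric(1))
  vars <- vapply(halves, stats::var, numeric(1))
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W <= 0) return(1)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Sampler settings
#'
#' @param chains number of chains.
#' @param warmup warmup (discarded) iterations per chain.
#' @param iter retained sampling iterations per chain.
#' @return list of sampler settings for [fit_coloc] and [fit_slope].
#' @export
mcmc_control <- function(chains = 4L, warmup = 1000L, iter = 1000L) {
  stopifnot(chains >= 1L, warmup >= 0L, iter >= 2L)
  list(chains = as.integer(chains), warmup = as.integer(warmup),
       iter = as.integer(iter))
}
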