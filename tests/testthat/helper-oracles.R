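# Independent oracles used to cross-check the package implementations.
# These are deliberately written as plain enumeration / quadrature and share
# no code with the package internals.

# Greedy clumping, re-derived by explicit looping over SNP indices.
oracle_clump <- function(pv, pos, chrom, r2m, p1, p2, r2, kb) {
  assigned <- rep(FALSE, length(pv))
  out <- list()
  repeat {
    best <- NA_integer_
    for (i in order(pv, pos)) {
      if (!assigned[i] && pv[i] < p1) { best <- i; break }
    }
    if (is.na(best)) break
    mem <- integer()
    for (k in seq_along(pv)) {
      if (!assigned[k] && pv[k] <= p2 && chrom[k] == chrom[best] &&
          abs(pos[k] - pos[best]) <= kb * 1000 && r2m[k, best] >= r2) {
        mem <- c(mem, k)
      }
    }
    mem <- sort(unique(c(best, mem)))
    assigned[mem] <- TRUE
    out[[length(out) + 1L]] <- list(index = best, members = mem)
  }
  out
}

# Sorted-greedy cluster trimming, re-derived.
oracle_trim <- function(key_p, key_pos, key_r2m, r2_max) {
  keep <- integer()
  for (i in order(key_p, key_pos)) {
    ok <- TRUE
    for (k in keep) if (key_r2m[i, k] >= r2_max) ok <- FALSE
    if (ok) keep <- c(keep, i)
  }
  sort(keep)
}

# Greedy collapsing, re-derived.
oracle_collapse <- function(pv, pos, rm, r_threshold) {
  n <- length(pv)
  assigned <- rep(FALSE, n)
  groups <- list()
  for (i in order(pv, pos)) {
    if (assigned[i]) next
    g <- i
    for (k in seq_len(n)) {
      if (!assigned[k] && k != i && rm[k, i] > r_threshold) g <- c(g, k)
    }
    assigned[sort(g)] <- TRUE
    groups[[length(groups) + 1L]] <- list(rep = i, members = sort(g))
  }
  groups
}

# IVW slope by dense grid minimization of the weighted residual sum.
oracle_ivw_grid <- function(bA, bB, seB, lim = 5, step = 1e-4) {
  grid <- seq(-lim, lim, by = step)
  obj <- vapply(grid, function(a) sum((bB - a * bA)^2 / seB^2), numeric(1))
  grid[which.min(obj)]
}

# Posterior of the slope model by grid quadrature. The latent effects
# integrate out analytically: given (alpha, sigma, sd_beta), each observed
# pair (bA_j, bB_j) is bivariate normal with covariance
#   [ sd_beta^2 + seA^2,            alpha sd_beta^2              ]
#   [ alpha sd_beta^2,  alpha^2 sd_beta^2 + sigma^2 + seB^2      ]
# so the 3-parameter posterior is computed exactly (up to grid resolution)
# without any MCMC.
oracle_slope_posterior <- function(ins, n_alpha = 161, n_sigma = 80,
                                   n_sd = 60) {
  bA <- ins$beta_a; sA <- ins$se_a; bB <- ins$beta_b; sB <- ins$se_b
  rms <- function(x) sqrt(mean(x^2))
  w <- 1 / sB^2
  a0 <- sum(w * bA * bB) / sum(w * bA^2)
  se0 <- 1 / sqrt(sum(w * bA^2))
  resid <- bB - a0 * bA
  excess <- mean(resid^2) - mean(sB^2) - a0^2 * mean(sA^2)
  sigma_scale <- 2 * sqrt(max(excess, mean(sB^2) / 4))
  alpha_scale <- 2 * rms(bB) / rms(bA)
  sd_beta_scale <- max(abs(bA))

  half_a <- 6 * max(se0, sigma_scale / rms(bA), abs(a0) / 3)
  alphas <- seq(a0 - half_a, a0 + half_a, length.out = n_alpha)
  sigmas <- seq(sigma_scale / (2 * n_sigma), 4 * sigma_scale,
                length.out = n_sigma)
  sds <- seq(sd_beta_scale / (2 * n_sd), 4 * sd_beta_scale,
             length.out = n_sd)
  g <- expand.grid(alpha = alphas, sigma = sigmas, sd = sds)
  ll <- numeric(nrow(g))
  for (j in seq_along(bA)) {
    s11 <- g$sd^2 + sA[j]^2
    s12 <- g$alpha * g$sd^2
    s22 <- g$alpha^2 * g$sd^2 + g$sigma^2 + sB[j]^2
    det <- s11 * s22 - s12^2
    q <- (s22 * bA[j]^2 - 2 * s12 * bA[j] * bB[j] + s11 * bB[j]^2) / det
    ll <- ll - 0.5 * log(det) - 0.5 * q
  }
  lp <- ll + stats::dnorm(g$alpha, 0, alpha_scale, log = TRUE) +
    stats::dnorm(g$sigma, 0, sigma_scale, log = TRUE) +
    stats::dnorm(g$sd, 0, sd_beta_scale, log = TRUE)
  wts <- exp(lp - max(lp))
  wts <- wts / sum(wts)
  mean_alpha <- sum(wts * g$alpha)
  mean_sigma <- sum(wts * g$sigma)
  marg <- tapply(wts, factor(g$alpha, levels = alphas), sum)
  cdf <- cumsum(marg)
  qfun <- function(p) alphas[which(cdf >= p)[1]]
  list(mean_alpha = mean_alpha, mean_sigma = mean_sigma,
       q10 = qfun(0.10), q90 = qfun(0.90),
       grid_step = alphas[2] - alphas[1])
}

# Posterior mean of a single-observation horseshoe model by exact
# quadrature. Substituting lambda = tan(theta), tau = tau0 tan(phi) makes
# the half-Cauchy priors uniform on (0, pi/2), so a uniform grid in
# (theta, phi) integrates them exactly up to resolution.
oracle_horseshoe1_mean <- function(y, se, tau0, n_grid = 400) {
  th <- seq(1e-4, pi / 2 - 1e-4, length.out = n_grid)
  lam <- tan(th)
  tau <- tau0 * tan(th)
  g <- expand.grid(lam = lam, tau = tau)
  v <- g$tau^2 * g$lam^2
  w <- stats::dnorm(y, 0, sqrt(se^2 + v))
  m <- y * v / (v + se^2)
  sum(w * m) / sum(w)
}

# A small joined locus with identical allele codings, built from explicit
# tables (no simulation); LD from a factor-structure correlation matrix.
make_toy_locus <- function(n = 10, seed = 1, n_chrom = 1) {
  set.seed(seed)
  L <- matrix(rnorm(n * 2), n, 2)
  S <- tcrossprod(L) + diag(runif(n, 0.5, 2), n)
  d <- 1 / sqrt(diag(S))
  R <- d * S * rep(d, each = n)
  ids <- paste0("rs", seq_len(n))
  df <- function(beta) data.frame(
    id = ids, chrom = rep_len(as.character(seq_len(n_chrom)), n),
    pos = sort(sample.int(2e6, n)),
    a1 = "A", a2 = "G", beta = beta, se = runif(n, 0.02, 0.1),
    pvalue = runif(n)^3, maf = runif(n, 0.05, 0.5),
    stringsAsFactors = FALSE)
  a <- sumstats(df(rnorm(n, 0, 0.3)), "A")
  b <- sumstats(df(rnorm(n, 0, 0.1)), "B")
  match_studies(a, b, ld_a = ld_matrix(R, ids = ids))
}

# A bare signal cluster from explicit per-SNP values.
make_cluster <- function(beta_a, se_a, beta_b, se_b, R, pvalue = NULL,
                         pos = NULL) {
  n <- length(beta_a)
  ids <- paste0("rs", seq_len(n))
  if (is.null(pvalue)) pvalue <- 2 * pnorm(-abs(beta_a / se_a))
  if (is.null(pos)) pos <- seq_len(n) * 1000L
  mk <- function(beta, se) data.frame(
    id = ids, chrom = "1", pos = pos, a1 = "A", a2 = "G",
    beta = beta, se = se, pvalue = pvalue, maf = 0.3,
    stringsAsFactors = FALSE)
  ld <- ld_matrix(R, ids = ids)
  idx <- ids[which.min(pvalue)]
  hetmr:::signal_cluster(a = mk(beta_a, se_a), b = mk(beta_b, se_b),
                         ld_a = ld, ld_b = ld, index_id = idx)
}

fast_ctrl <- function() mcmc_control(chains = 2, warmup = 300, iter = 600)
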