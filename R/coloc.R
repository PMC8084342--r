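# Per-cluster colocalization: a univariate-likelihood shrinkage model for
# the observed eQTL and GWAS coefficients.
#
# For each study S, the observed coefficient of SNP i in the cluster is
# modelled as beta_hat_i ~ Normal((R beta)_i, se_i), with R the signed LD
# matrix and beta the vector of true (joint) effects, carrying a horseshoe
# prior: beta_i = tau * lambda_i * z_i, z_i ~ N(0,1),
# lambda_i ~ half-Cauchy(0,1), tau ~ half-Cauchy(0, tau0). The global scale
# tau0 adapts to the data: median(se) times the expected nonzero fraction
# (one causal SNP among n members). The half-Cauchy scales admit an exact
# inverse-gamma augmentation, so the posterior is sampled by Gibbs updates
# that are conjugate at every step.

.horseshoe_gibbs <- function(y, se, R, tau0, control, seed) {
  n <- length(y)
  R <- unclass(R)
  R <- R + diag(1e-3, n)  # ridge regularization for conditioning
  Dinv <- 1 / se^2
  RtDinvR <- R %*% (Dinv * R)        # t(R) %*% diag(Dinv) %*% R, R symmetric
  RtDinvy <- as.vector(R %*% (Dinv * y))

  total <- control$chains * control$iter
  beta_draws <- matrix(NA_real_, total, n)
  tau_draws <- numeric(total)
  chain_draws <- vector("list", control$chains)

  for (chain in seq_len(control$chains)) {
    set.seed(seed + (chain - 1L))
    beta <- y / 2
    lambda2 <- rep(1, n)
    nu <- rep(1, n)
    tau2 <- tau0^2
    xi <- 1
    keep0 <- (chain - 1L) * control$iter
    for (it in seq_len(control$warmup + control$iter)) {
      # beta | scales: multivariate normal
      A <- RtDinvR + diag(1 / (tau2 * lambda2), n)
      ch <- tryCatch(chol(A), error = function(e) chol(A + diag(1e-8, n)))
      m <- backsolve(ch, backsolve(ch, RtDinvy, transpose = TRUE))
      beta <- m + backsolve(ch, stats::rnorm(n))
      # local scales
      lambda2 <- .rinvgamma(n, 1, 1 / nu + beta^2 / (2 * tau2))
      nu <- .rinvgamma(n, 1, 1 + 1 / lambda2)
      # global scale
      tau2 <- .rinvgamma(1, (n + 1) / 2, 1 / xi + sum(beta^2 / lambda2) / 2)
      xi <- .rinvgamma(1, 1, 1 / tau0^2 + 1 / tau2)
      if (it > control$warmup) {
        k <- keep0 + it - control$warmup
        beta_draws[k, ] <- beta
        tau_draws[k] <- sqrt(tau2)
      }
    }
    chain_draws[[chain]] <- beta_draws[keep0 + seq_len(control$iter), , drop = FALSE]
  }

  rhat <- vapply(seq_len(n), function(j) {
    if (control$chains < 2L) return(NA_real_)
    .split_rhat(lapply(chain_draws, function(m) m[, j]))
  }, numeric(1))

  list(beta = beta_draws, tau = tau_draws, rhat = rhat)
}

#' Fit the per-cluster colocalization model
#'
#' Samples the posterior of the true eQTL and GWAS effects for every SNP in a
#' flipped, collapsed signal cluster under independent horseshoe-shrinkage
#' models per study (see the package vignette for the model). If one SNP
#' underlies both signals, its posterior effect means are large in both
#' studies and the others shrink toward zero; a SNP driving only the eQTL
#' signal keeps a GWAS posterior mean near zero.
#'
#' @param cluster a `signal_cluster` (after [flip_to_index] and
#'   [collapse_correlated]).
#' @param ld_a,ld_b LD matrices for the two studies; default to the cluster's
#'   own sub-matrices.
#' @param control sampler settings from [mcmc_control].
#' @param seed integer seed; draws are reproducible given seed and settings.
#' @param tau0_a,tau0_b global-scale hyperparameters; when `NULL` they are
#'   set by `tau0_rule`.
#' @param likelihood `"joint"` (default) places the LD matrix in the
#'   likelihood mean, `beta_hat ~ N(R beta, se)`, so `beta` are joint
#'   (conditional) effects; `"marginal"` drops R from the mean and shrinks
#'   the observed marginal coefficients directly.
#' @param tau0_rule adaptation rule for the global scale when `tau0_a`/
#'   `tau0_b` are not given: `"se"` (default) sets `median(se) / n` per
#'   study (noise scale times the expected nonzero fraction of one causal
#'   SNP among the n members); `"scale"` sets `max(|beta_hat|) / n`
#'   (coefficient-scale adaptation).
#' @param rhat_max split-Rhat threshold above which a convergence warning is
#'   attached to the fit.
#' @return A `coloc_fit`: per-SNP posterior summaries (`$snps`), posterior
#'   draws (`$draws`), the selected `$candidate_id`, and `$diagnostics`.
#' @export
fit_coloc <- function(cluster, ld_a = cluster$ld_a, ld_b = cluster$ld_b,
                      control = mcmc_control(), seed = 1L,
                      tau0_a = NULL, tau0_b = NULL,
                      tau0_rule = c("se", "se_sqrt", "se_full", "scale"),
                      likelihood = c("joint", "marginal"),
                      rhat_max = 1.05) {
  likelihood <- match.arg(likelihood)
  a <- cluster$a
  b <- cluster$b
  n <- nrow(a)
  if (any(!is.finite(c(a$beta, a$se, b$beta, b$se)))) {
    stop("fit_coloc: non-finite inputs")
  }
  tau0_rule <- match.arg(tau0_rule)
  tau0_default <- function(tab) {
    switch(tau0_rule,
           se = stats::median(tab$se) / n,
           se_sqrt = stats::median(tab$se) / sqrt(n),
           se_full = stats::median(tab$se),
           scale = max(abs(tab$beta)) / n)
  }
  if (is.null(tau0_a)) tau0_a <- tau0_default(a)
  if (is.null(tau0_b)) tau0_b <- tau0_default(b)

  Ra <- unclass(ld_subset(ld_a, a$id))
  Rb <- unclass(ld_subset(ld_b, b$id))
  if (likelihood == "marginal") {
    Ra <- Rb <- diag(1, n)
  }
  fa <- .horseshoe_gibbs(a$beta, a$se, Ra, tau0_a, control, seed)
  fb <- .horseshoe_gibbs(b$beta, b$se, Rb, tau0_b, control, seed + 7919L)
  # fitted marginal effects (R beta): the model's reconstruction of the
  # observed per-SNP coefficients; equals beta itself for the marginal model
  fit_a <- fa$beta %*% Ra
  fit_b <- fb$beta %*% Rb

  snps <- data.frame(id = a$id, pos = a$pos, pvalue_a = a$pvalue,
                     beta_hat_a = a$beta, se_a = a$se,
                     beta_hat_b = b$beta, se_b = b$se,
                     post_mean_a = colMeans(fa$beta),
                     post_sd_a = apply(fa$beta, 2, stats::sd),
                     post_mean_b = colMeans(fb$beta),
                     post_sd_b = apply(fb$beta, 2, stats::sd),
                     fitted_mean_a = colMeans(fit_a),
                     fitted_sd_a = apply(fit_a, 2, stats::sd),
                     fitted_mean_b = colMeans(fit_b),
                     fitted_sd_b = apply(fit_b, 2, stats::sd),
                     rhat_a = fa$rhat, rhat_b = fb$rhat,
                     stringsAsFactors = FALSE)
  fit <- structure(list(snps = snps,
                        draws = list(beta_a = fa$beta, beta_b = fb$beta,
                                     tau_a = fa$tau, tau_b = fb$tau),
                        cluster = cluster,
                        diagnostics = list(divergences = 0L,
                                           max_rhat = suppressWarnings(
                                             max(c(fa$rhat, fb$rhat), na.rm = TRUE))),
                        candidate_id = NA_character_),
                   class = "coloc_fit")
  if (is.finite(fit$diagnostics$max_rhat) && fit$diagnostics$max_rhat > rhat_max) {
    warning(sprintf("fit_coloc: split-Rhat %.3f exceeds %.2f; chains may not have mixed",
                    fit$diagnostics$max_rhat, rhat_max))
    fit$diagnostics$converged <- FALSE
  } else {
    fit$diagnostics$converged <- TRUE
  }
  fit$candidate_id <- select_candidate(fit)
  fit
}

#' @export
print.coloc_fit <- function(x, ...) {
  cat(sprintf("coloc_fit: %d SNP(s), candidate %s\n",
              nrow(x$snps), x$candidate_id))
  print(x$snps[, c("id", "post_mean_a", "post_sd_a", "post_mean_b", "post_sd_b")])
  invisible(x)
}

#' Select the candidate causal SNP from a colocalization fit
#'
#' Returns the member SNP with the largest posterior mean eQTL effect (after
#' flipping all effects are oriented positive; the absolute value is used
#' defensively). Ties within machine precision are broken by smaller eQTL
#' p-value, then smaller position.
#'
#' @param fit a `coloc_fit`.
#' @return SNP id.
#' @export
select_candidate <- function(fit) {
  s <- fit$snps
  score <- abs(s$post_mean_a)
  top <- which(score >= max(score) - 1e-12)
  if (length(top) > 1L) top <- top[order(s$pvalue_a[top], s$pos[top])]
  s$id[top[1L]]
}

#' Assemble the instrument set for slope fitting
#'
#' One instrument row per signal cluster. In `"fitted"` mode (the default
#' pathway) the candidate SNP's posterior mean and SD of its *fitted
#' marginal* effect (`R beta` at the candidate) are used per study: both
#' studies are then on the same marginal scale, so LD between the candidate
#' and the underlying causal SNP cancels in the slope. `"posterior"` mode
#' uses the posterior of the joint effect `beta` itself (scale mismatch
#' between a well-powered and a weakly powered study can bias the slope;
#' see the vignette). `"raw"` mode passes through the candidate's original
#' observed coefficients and SEs (the pathway used when candidates are
#' chosen by an external colocalization method).
#'
#' @param fits list of `coloc_fit` objects.
#' @param mode `"fitted"`, `"posterior"` or `"raw"`.
#' @param candidates optional character vector of candidate SNP ids (one per
#'   fit) overriding the fits' own selections (used with `"raw"`).
#' @return An [instrument_set] with J = `length(fits)` rows.
#' @export
build_instruments <- function(fits, mode = c("fitted", "posterior", "raw"),
                              candidates = NULL) {
  mode <- match.arg(mode)
  stopifnot(length(fits) >= 1L)
  if (is.null(candidates)) {
    candidates <- vapply(fits, function(f) f$candidate_id, character(1))
  }
  stopifnot(length(candidates) == length(fits))
  rows <- lapply(seq_along(fits), function(j) {
    s <- fits[[j]]$snps
    i <- match(candidates[j], s$id)
    if (is.na(i)) stop("build_instruments: candidate not in cluster: ",
                       candidates[j])
    if (mode == "fitted") {
      data.frame(id = s$id[i],
                 beta_a = s$fitted_mean_a[i], se_a = s$fitted_sd_a[i],
                 beta_b = s$fitted_mean_b[i], se_b = s$fitted_sd_b[i])
    } else if (mode == "posterior") {
      data.frame(id = s$id[i], beta_a = s$post_mean_a[i], se_a = s$post_sd_a[i],
                 beta_b = s$post_mean_b[i], se_b = s$post_sd_b[i])
    } else {
      data.frame(id = s$id[i], beta_a = s$beta_hat_a[i], se_a = s$se_a[i],
                 beta_b = s$beta_hat_b[i], se_b = s$se_b[i])
    }
  })
  tab <- do.call(rbind, rows)
  instrument_set(tab$beta_a, tab$se_a, tab$beta_b, tab$se_b,
                 id = tab$id, cluster = seq_along(fits))
}

#' Export per-SNP colocalization summaries as a data frame
#'
#' @param fit a `coloc_fit`.
#' @return data frame with SNP id, posterior means/sds for both studies and
#'   a candidate flag, suitable for `write.table`.
#' @export
coloc_summary <- function(fit) {
  s <- fit$snps
  data.frame(id = s$id,
             post_mean_A = s$post_mean_a, post_sd_A = s$post_sd_a,
             post_mean_B = s$post_mean_b, post_sd_B = s$post_sd_b,
             candidate = s$id == fit$candidate_id,
             stringsAsFactors = FALSE)
}
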