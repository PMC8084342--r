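# Hierarchical gene-to-trait slope model across signal clusters.
#
# For clusters j = 1..J, with observed instrument coefficients and SEs:
#   beta_hat_jA ~ N(beta_jA, se_jA)     (eQTL, exposure)
#   beta_hat_jB ~ N(beta_jB, se_jB)     (GWAS, outcome)
#   beta_jA     ~ N(0, SD_beta)
#   beta_jB     ~ N(alpha * beta_jA, sigma)
# with no intercept: the mediation line passes through the origin. alpha is
# the gene-to-trait slope and sigma the dispersion of per-cluster allelic
# effects around the line. All scale parameters are SDs. Hyperpriors (scales
# adapt to the data; see the vignette): SD_beta ~ halfN(max|beta_hat_A|),
# alpha ~ N(0, 2 * rms(beta_hat_B)/rms(beta_hat_A)), sigma ~ halfN(s) with
# s twice the moment-matched excess dispersion of a preliminary weighted
# least-squares fit (residual variance minus the stated observation noise).
#
# The posterior is sampled by Gibbs: beta_A, beta_B and alpha have conjugate
# normal conditionals; sigma and SD_beta are updated by slice sampling on the
# log scale.

#' Check for sufficient allelic heterogeneity
#'
#' The slope model is only identified across two or more nearly-LD-independent
#' signal clusters. With a single cluster no dispersion can be estimated and
#' fitting is refused unless forced.
#'
#' @param instruments an [instrument_set].
#' @return list with elements `pass` (logical) and `message`. J = 0 is an
#'   error; J = 1 yields `pass = FALSE` with a warning.
#' @export
check_heterogeneity <- function(instruments) {
  J <- nrow(instruments)
  if (J == 0L) stop("check_heterogeneity: empty instrument set")
  if (J < 2L) {
    warning("insufficient allelic heterogeneity: only one signal cluster; ",
            "slope fitting is not recommended")
    return(list(pass = FALSE,
                message = "insufficient allelic heterogeneity (J < 2)"))
  }
  list(pass = TRUE, message = "ok")
}

.slope_prior <- function(instruments, prior = NULL) {
  bA <- instruments$beta_a; bB <- instruments$beta_b
  seB <- instruments$se_b
  rms <- function(x) sqrt(mean(x^2))
  seA <- instruments$se_a
  w <- 1 / seB^2
  alpha0 <- sum(w * bA * bB) / sum(w * bA^2)
  resid <- bB - alpha0 * bA
  # moment-matched dispersion scale: excess residual variance beyond the
  # stated observation noise (floored at half the outcome noise scale),
  # doubled so the half-normal keeps mass above the point estimate
  excess <- mean(resid^2) - mean(seB^2) - alpha0^2 * mean(seA^2)
  defaults <- list(
    sd_beta_scale = max(abs(bA)),
    alpha_scale = 2 * rms(bB) / rms(bA),
    sigma_scale = 2 * sqrt(max(excess, mean(seB^2) / 4))
  )
  if (!is.null(prior)) defaults[names(prior)] <- prior
  defaults
}

#' Fit the hierarchical gene-to-trait slope model
#'
#' @param instruments an [instrument_set] (J >= 2 unless `force = TRUE`).
#' @param level credible level for the quantile-based interval
#'   (default 0.80).
#' @param control sampler settings from [mcmc_control].
#' @param seed integer seed.
#' @param prior optional named list overriding hyperprior scales
#'   (`sd_beta_scale`, `alpha_scale`, `sigma_scale`).
#' @param force fit even with a single instrument.
#' @param rhat_max split-Rhat warning threshold.
#' @return A `slope_fit`: posterior draws of `alpha`, `sigma`, `sd_beta` and
#'   the latent per-cluster effects, posterior summaries, and the
#'   quantile-based credible intervals for `alpha` and `sigma` at `level`.
#'   Returns `NULL` (with a warning) when heterogeneity is insufficient and
#'   `force = FALSE`.
#' @export
fit_slope <- function(instruments, level = 0.80, control = mcmc_control(),
                      seed = 1L, prior = NULL, force = FALSE,
                      rhat_max = 1.05) {
  stopifnot(inherits(instruments, "instrument_set"))
  if (any(!is.finite(as.matrix(instruments[, c("beta_a", "se_a", "beta_b", "se_b")])))) {
    stop("fit_slope: non-finite instrument values")
  }
  het <- check_heterogeneity(instruments)
  if (!het$pass && !force) return(invisible(NULL))

  J <- nrow(instruments)
  bA <- instruments$beta_a; sA <- instruments$se_a
  bB <- instruments$beta_b; sB <- instruments$se_b
  pr <- .slope_prior(instruments, prior)

  total <- control$chains * control$iter
  draws <- list(alpha = numeric(total), sigma = numeric(total),
                sd_beta = numeric(total),
                beta_a = matrix(NA_real_, total, J),
                beta_b = matrix(NA_real_, total, J))
  chain_cols <- vector("list", control$chains)

  for (chain in seq_len(control$chains)) {
    set.seed(seed + (chain - 1L))
    betaA <- bA
    betaB <- bB
    w <- 1 / sB^2
    alpha <- sum(w * bA * bB) / sum(w * bA^2)
    sigma <- max(pr$sigma_scale / 2, 1e-6)
    sd_beta <- max(if (J > 1L) stats::sd(bA) else 0, max(abs(bA)) / 2, 1e-6)
    keep0 <- (chain - 1L) * control$iter
    for (it in seq_len(control$warmup + control$iter)) {
      # latent outcome effects
      prec_b <- 1 / sB^2 + 1 / sigma^2
      mu_b <- (bB / sB^2 + alpha * betaA / sigma^2) / prec_b
      betaB <- stats::rnorm(J, mu_b, sqrt(1 / prec_b))
      # latent exposure effects
      prec_a <- 1 / sA^2 + 1 / sd_beta^2 + alpha^2 / sigma^2
      mu_a <- (bA / sA^2 + alpha * betaB / sigma^2) / prec_a
      betaA <- stats::rnorm(J, mu_a, sqrt(1 / prec_a))
      # slope
      prec_al <- sum(betaA^2) / sigma^2 + 1 / pr$alpha_scale^2
      mu_al <- (sum(betaA * betaB) / sigma^2) / prec_al
      alpha <- stats::rnorm(1L, mu_al, sqrt(1 / prec_al))
      # dispersion (slice on log sigma)
      ss_b <- sum((betaB - alpha * betaA)^2)
      sigma <- exp(.slice1(log(sigma), function(u) {
        (1 - J) * u - ss_b * exp(-2 * u) / 2 - exp(2 * u) / (2 * pr$sigma_scale^2)
      }))
      # instrument-effect scale (slice on log sd_beta)
      ss_a <- sum(betaA^2)
      sd_beta <- exp(.slice1(log(sd_beta), function(u) {
        (1 - J) * u - ss_a * exp(-2 * u) / 2 - exp(2 * u) / (2 * pr$sd_beta_scale^2)
      }))
      if (it > control$warmup) {
        k <- keep0 + it - control$warmup
        draws$alpha[k] <- alpha
        draws$sigma[k] <- sigma
        draws$sd_beta[k] <- sd_beta
        draws$beta_a[k, ] <- betaA
        draws$beta_b[k, ] <- betaB
      }
    }
    chain_cols[[chain]] <- keep0 + seq_len(control$iter)
  }

  rhat <- vapply(c("alpha", "sigma", "sd_beta"), function(p) {
    if (control$chains < 2L) return(NA_real_)
    .split_rhat(lapply(chain_cols, function(ix) draws[[p]][ix]))
  }, numeric(1))

  qs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  fit <- structure(list(
    draws = draws,
    level = level,
    summary = data.frame(
      parameter = c("alpha", "sigma", "sd_beta"),
      mean = c(mean(draws$alpha), mean(draws$sigma), mean(draws$sd_beta)),
      sd = c(stats::sd(draws$alpha), stats::sd(draws$sigma),
             stats::sd(draws$sd_beta)),
      lower = c(stats::quantile(draws$alpha, qs[1], names = FALSE),
                stats::quantile(draws$sigma, qs[1], names = FALSE),
                stats::quantile(draws$sd_beta, qs[1], names = FALSE)),
      upper = c(stats::quantile(draws$alpha, qs[2], names = FALSE),
                stats::quantile(draws$sigma, qs[2], names = FALSE),
                stats::quantile(draws$sd_beta, qs[2], names = FALSE)),
      stringsAsFactors = FALSE),
    alpha_interval = stats::quantile(draws$alpha, qs, names = FALSE),
    sigma_interval = stats::quantile(draws$sigma, qs, names = FALSE),
    instruments = instruments,
    prior = pr,
    diagnostics = list(rhat = rhat, divergences = 0L)
  ), class = "slope_fit")
  if (any(is.finite(rhat) & rhat > rhat_max)) {
    warning(sprintf("fit_slope: split-Rhat up to %.3f exceeds %.2f",
                    max(rhat, na.rm = TRUE), rhat_max))
    fit$diagnostics$converged <- FALSE
  } else {
    fit$diagnostics$converged <- TRUE
  }
  fit
}

#' @export
print.slope_fit <- function(x, ...) {
  cat(sprintf("slope_fit over J = %d signal clusters\n", nrow(x$instruments)))
  s <- x$summary
  for (i in seq_len(nrow(s))) {
    cat(sprintf("  %-8s %8.4f (sd %.4f)  %d%% CI [%.4f, %.4f]\n",
                s$parameter[i], s$mean[i], s$sd[i],
                round(100 * x$level), s$lower[i], s$upper[i]))
  }
  invisible(x)
}

#' Mean mediated effect
#'
#' The posterior-mean slope times the arithmetic mean of the instrument eQTL
#' coefficients: the typical trait change delivered through the gene at this
#' locus, in trait units.
#'
#' @param fit a `slope_fit`.
#' @param instruments the [instrument_set] the fit was run on (defaults to
#'   the one stored in the fit).
#' @return numeric scalar.
#' @export
mean_mediated <- function(fit, instruments = fit$instruments) {
  mean(fit$draws$alpha) * mean(instruments$beta_a)
}

#' Dispersion-to-mediated-effect ratio
#'
#' The posterior-mean dispersion divided by the absolute mean mediated
#' effect: how much per-cluster allelic effects vary relative to the typical
#' mediated effect, comparable across loci.
#'
#' Either pass a `slope_fit` (with its instrument set), or two numbers:
#' `dispersion_ratio(sigma_hat, mm)` computes `sigma_hat / abs(mm)` directly.
#'
#' @param fit a `slope_fit`, or a numeric posterior-mean dispersion.
#' @param instruments an [instrument_set], or the numeric mean mediated
#'   effect when `fit` is numeric.
#' @return numeric scalar; 0 when the dispersion is 0, `NA` (with attribute
#'   `reason = "mean mediated effect is 0"`) when the mediated effect is 0.
#' @export
dispersion_ratio <- function(fit, instruments = NULL) {
  if (is.numeric(fit)) {
    sigma_hat <- fit
    mm <- instruments
    stopifnot(is.numeric(mm), length(sigma_hat) == 1L, length(mm) == 1L)
  } else {
    if (is.null(instruments)) instruments <- fit$instruments
    sigma_hat <- mean(fit$draws$sigma)
    mm <- mean_mediated(fit, instruments)
  }
  if (sigma_hat == 0) return(0)
  if (mm == 0) {
    return(structure(NA_real_, reason = "mean mediated effect is 0"))
  }
  sigma_hat / abs(mm)
}

#' Export the slope-fit report as a data frame
#'
#' @param fit a `slope_fit`.
#' @return data frame with the parameter summaries plus the mean mediated
#'   effect and dispersion ratio rows.
#' @export
slope_summary <- function(fit) {
  mm <- mean_mediated(fit)
  dr <- dispersion_ratio(fit)
  extra <- data.frame(parameter = c("mean_mediated", "dispersion_ratio"),
                      mean = c(mm, as.numeric(dr)), sd = NA_real_,
                      lower = NA_real_, upper = NA_real_,
                      stringsAsFactors = FALSE)
  rbind(fit$summary, extra)
}
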