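# Synthetic-data generators: AR(1)-correlated genotype panels, paired
# eQTL/GWAS study simulation (mediated, null, horizontal-pleiotropy modes),
# marginal summary statistics, correlated-instrument draws, and direct draws
# from the slope model. Every generator is a pure function of its parameters
# and seed.

#' Simulate an LD-structured genotype panel
#'
#' Two latent Gaussian haplotypes per individual follow an AR(1) process with
#' correlation `rho` across adjacent SNPs; each is thresholded at the
#' MAF-matched normal quantile and the two haplotype alleles are summed to a
#' dosage in \{0, 1, 2\}, then columns are standardized to zero mean and unit
#' variance. This emulates a block/AR-correlated locus without requiring a
#' real reference panel. Monomorphic columns are redrawn (bounded retries).
#'
#' @param n_ind number of individuals (>= 2).
#' @param n_snp number of SNPs (>= 1).
#' @param ld_spec list with `rho` (adjacent-haplotype latent correlation in
#'   [0, 1)) and `maf_range` (interval for per-SNP MAF draws).
#' @param seed integer seed.
#' @param maf optional length-`n_snp` vector of population MAFs, overriding
#'   the `maf_range` draw; pass one panel's `target_maf` when simulating a
#'   second cohort from the same population.
#' @param pos_start,pos_step base-pair position of the first SNP and spacing.
#' @return A `genotype_panel`: standardized dosage matrix `Z` (n_ind x
#'   n_snp), SNP metadata (`ids`, `pos`, `chrom`, `a1`, `a2`, realized
#'   `maf`), and the generating specification.
#' @export
simulate_genotypes <- function(n_ind, n_snp,
                               ld_spec = list(rho = 0.9,
                                              maf_range = c(0.05, 0.5)),
                               seed = 1L,
                               pos_start = 1e6L, pos_step = 1000L,
                               maf = NULL) {
  stopifnot(n_ind >= 2L, n_snp >= 1L,
            ld_spec$rho >= 0, ld_spec$rho < 1)
  set.seed(seed)
  rho <- ld_spec$rho
  if (is.null(maf)) {
    maf <- stats::runif(n_snp, ld_spec$maf_range[1], ld_spec$maf_range[2])
  }
  stopifnot(length(maf) == n_snp, all(maf > 0), all(maf <= 0.5))
  Z <- matrix(0L, n_ind, n_snp)
  x1 <- stats::rnorm(n_ind)
  x2 <- stats::rnorm(n_ind)
  innov_sd <- sqrt(1 - rho^2)
  for (j in seq_len(n_snp)) {
    if (j > 1L) {
      x1 <- rho * x1 + innov_sd * stats::rnorm(n_ind)
      x2 <- rho * x2 + innov_sd * stats::rnorm(n_ind)
    }
    thr <- stats::qnorm(1 - maf[j])
    dose <- (x1 > thr) + (x2 > thr)
    tries <- 0L
    while (stats::var(dose) == 0 && tries < 10L) {
      x1 <- rho * x1 + innov_sd * stats::rnorm(n_ind)
      x2 <- rho * x2 + innov_sd * stats::rnorm(n_ind)
      dose <- (x1 > thr) + (x2 > thr)
      tries <- tries + 1L
    }
    if (stats::var(dose) == 0) {  # last resort for tiny panels
      flip <- sample.int(n_ind, 1L)
      dose[flip] <- if (dose[flip] == 0L) 1L else dose[flip] - 1L
    }
    Z[, j] <- dose
  }
  freq <- colMeans(Z) / 2
  realized_maf <- pmin(freq, 1 - freq)
  Zs <- scale(Z)
  attr(Zs, "scaled:center") <- NULL
  attr(Zs, "scaled:scale") <- NULL
  structure(list(Z = Zs,
                 ids = sprintf("snp%05d", seq_len(n_snp)),
                 chrom = rep("1", n_snp),
                 pos = as.integer(pos_start + (seq_len(n_snp) - 1L) * pos_step),
                 a1 = rep("A", n_snp), a2 = rep("G", n_snp),
                 maf = realized_maf, target_maf = maf,
                 ld_spec = ld_spec, seed = seed,
                 n_ind = n_ind, n_snp = n_snp),
            class = "genotype_panel")
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat(sprintf("genotype_panel: %d individuals x %d SNPs (rho = %g)\n",
              x$n_ind, x$n_snp, x$ld_spec$rho))
  invisible(x)
}

#' Sample LD matrix of a genotype panel
#'
#' @param panel a `genotype_panel`.
#' @return [ld_matrix] of pairwise Pearson correlations between dosages.
#' @export
panel_ld <- function(panel) {
  r <- stats::cor(panel$Z)
  r[r > 1] <- 1; r[r < -1] <- -1
  ld_matrix(r, ids = panel$ids, tol = 1e-6)
}

# Build a phenotype with target heritability from genetic values g = Z beta:
# error variance is set from the unbiased sample variance of g so that the
# realized sample heritability matches the target in expectation.
.build_pheno <- function(Z, beta, h2) {
  g <- as.vector(Z %*% beta)
  s2_g <- stats::var(g)
  s2_err <- s2_g * (1 / h2 - 1)
  y <- g + stats::rnorm(nrow(Z), 0, sqrt(s2_err))
  list(y_std = as.vector(scale(y)), sd_raw = stats::sd(y),
       s2_gene = s2_g, s2_err = s2_err)
}

#' Per-SNP marginal summary statistics
#'
#' Simple-regression coefficient, SE and two-sided p-value of each
#' (standardized) SNP dosage against a standardized phenotype.
#'
#' @param panel a `genotype_panel`.
#' @param y phenotype vector of length `n_ind` (standardized internally).
#' @param study_label `"A"` or `"B"`.
#' @return A [sumstats] table, one row per SNP.
#' @export
marginal_sumstats <- function(panel, y, study_label = c("A", "B")) {
  study_label <- match.arg(study_label)
  n <- panel$n_ind
  stopifnot(length(y) == n)
  y <- as.vector(scale(y))
  Z <- panel$Z
  zz <- rep(n - 1, panel$n_snp)  # columns are standardized
  zy <- as.vector(crossprod(Z, y))
  beta <- zy / zz
  rss <- sum(y^2) - beta^2 * zz
  rss[rss < 0] <- 0
  se <- sqrt(rss / (n - 2) / zz)
  tstat <- beta / se
  pval <- 2 * stats::pt(-abs(tstat), df = n - 2)
  pval <- pmax(pval, .Machine$double.xmin)  # keep p in (0, 1]
  sumstats(data.frame(id = panel$ids, chrom = panel$chrom, pos = panel$pos,
                      a1 = panel$a1, a2 = panel$a2,
                      beta = beta, se = se, pvalue = pval, maf = panel$maf,
                      stringsAsFactors = FALSE),
           study_label = study_label)
}

#' Simulate a paired eQTL/GWAS study over a locus
#'
#' Draws a causal SNP set C of size `ceiling(causal_frac * n_snp)` and eQTL
#' effects `beta_j ~ N(0, h2g / n_causal)` on C; builds gene expression on
#' the eQTL panel with error variance set so the target cis heritability is
#' `h2g`, standardizes it, and emits per-SNP marginal summary statistics.
#' The GWAS trait is built on the GWAS panel the same way:
#' \describe{
#'   \item{mediated}{same causal set; GWAS effects are the eQTL effects
#'     rescaled by `sqrt(h2med/h2g)` so a single gene-to-trait slope exists;
#'     trait heritability target `h2med`.}
#'   \item{null}{an independently drawn causal set and effects at the same
#'     causal fraction, heritability `h2g` (distinct-seed semantics); gene
#'     and trait are unrelated and the true slope is 0.}
#'   \item{hp}{mediated plus `n_hp` large-effect trait-only association
#'     signals (horizontal pleiotropy) drawn at SD `sqrt(h2med)`.}
#' }
#'
#' @param panel_e,panel_g `genotype_panel` objects for the eQTL and GWAS
#'   cohorts (same SNP set).
#' @param h2g target cis expression heritability (default 0.1).
#' @param h2med target expression-mediated trait heritability (default 0.01).
#' @param causal_frac fraction of SNPs that are causal eQTLs (default 0.01).
#' @param mode `"mediated"`, `"null"` or `"hp"`.
#' @param seed integer seed.
#' @param n_hp number of trait-only signals in `"hp"` mode (default 3).
#' @return list with `a` (eQTL [sumstats]), `b` (GWAS [sumstats]) and
#'   `truth` (a `sim_truth`: causal sets, true effect vectors, realized
#'   phenotype SDs, intermediate variances, and the true slope).
#' @export
simulate_study <- function(panel_e, panel_g, h2g = 0.1, h2med = 0.01,
                           causal_frac = 0.01,
                           mode = c("mediated", "null", "hp"),
                           seed = 1L, n_hp = 3L) {
  mode <- match.arg(mode)
  stopifnot(identical(panel_e$ids, panel_g$ids), h2g > 0, h2g < 1,
            h2med >= 0, h2med < 1)
  if (mode %in% c("mediated", "hp") && h2med == 0) {
    warning("simulate_study: h2med = 0 with mediated mode; using null semantics")
    mode <- "null"
  }
  set.seed(seed)
  n <- panel_e$n_snp
  n_causal <- ceiling(causal_frac * n)
  causal <- sort(sample.int(n, n_causal))
  beta_e <- numeric(n)
  beta_e[causal] <- stats::rnorm(n_causal, 0, sqrt(h2g / n_causal))

  gene <- .build_pheno(panel_e$Z, beta_e, h2g)

  hp_idx <- integer()
  if (mode == "mediated" || mode == "hp") {
    beta_g <- sqrt(h2med / h2g) * beta_e
    causal_g <- causal
    h2_trait <- h2med
    if (mode == "hp") {
      hp_idx <- sort(sample(setdiff(seq_len(n), causal), n_hp))
      beta_g[hp_idx] <- stats::rnorm(n_hp, 0, sqrt(h2med))
      causal_g <- sort(c(causal, hp_idx))
    }
  } else {
    causal_g <- sort(sample.int(n, n_causal))
    beta_g <- numeric(n)
    beta_g[causal_g] <- stats::rnorm(n_causal, 0, sqrt(h2g / n_causal))
    h2_trait <- h2g
  }
  trait <- .build_pheno(panel_g$Z, beta_g, h2_trait)

  truth <- structure(list(
    causal = causal, causal_ids = panel_e$ids[causal],
    causal_g = causal_g, causal_g_ids = panel_e$ids[causal_g],
    hp_idx = hp_idx,
    beta_eqtl = beta_e, beta_gwas = beta_g,
    h2g = h2g, h2med = h2med, mode = mode, seed = seed,
    s2_gene = gene$s2_gene, s2_err = gene$s2_err,
    s2_trait = trait$s2_gene, s2_err_trait = trait$s2_err,
    sd_gene = gene$sd_raw, sd_trait = trait$sd_raw
  ), class = "sim_truth")
  truth$alpha <- true_alpha(truth)

  list(a = marginal_sumstats(panel_e, gene$y_std, "A"),
       b = marginal_sumstats(panel_g, trait$y_std, "B"),
       truth = truth)
}

#' True gene-to-trait slope of a simulated study
#'
#' The common ratio of GWAS to eQTL causal effects after scaling each by the
#' corresponding realized phenotype SD (coefficients from standardized
#' phenotypes are on the per-SD scale). In mediated mode the ratio is
#' constant across causal SNPs by construction (asserted to 1e-8) and
#' satisfies `h2med ~= h2g * alpha^2`. In null mode there is no mediation
#' slope: 0 is returned with attribute `defined = FALSE`.
#'
#' @param truth a `sim_truth`.
#' @param sd_gene,sd_trait realized phenotype SDs (default: stored values).
#' @return numeric slope (attribute `defined` is FALSE for null mode).
#' @export
true_alpha <- function(truth, sd_gene = truth$sd_gene,
                       sd_trait = truth$sd_trait) {
  if (truth$mode == "null") {
    return(structure(0, defined = FALSE))
  }
  j <- truth$causal
  ratios <- (truth$beta_gwas[j] / sd_trait) / (truth$beta_eqtl[j] / sd_gene)
  if (diff(range(ratios)) > 1e-8) {
    stop("true_alpha: causal-SNP ratios are not constant")
  }
  structure(ratios[1], defined = TRUE)
}

#' Simulate correlated instrument coefficients (null slope)
#'
#' Direct multivariate-normal draws of per-cluster coefficients used to probe
#' false-positive calibration of slope fitting under residual LD between
#' signal clusters. eQTL coefficients are centered on 10 for every cluster,
#' GWAS coefficients on 0 (so the true gene-to-trait slope is 0), with
#' correlation `sqrt(r2_adjacent)` between adjacent clusters and 0 elsewhere.
#' Unit SEs are attached. For `r2_adjacent` large enough that the banded
#' correlation matrix loses positive-definiteness, eigenvalues are clipped
#' and the matrix rescaled to unit diagonal.
#'
#' @param J number of signal clusters (the study design used 4, 6 and 8).
#' @param r2_adjacent target squared correlation between adjacent clusters.
#' @param n_iter number of instrument sets to draw.
#' @param seed integer seed.
#' @param mean_a eQTL coefficient mean (default 10).
#' @param se instrument SE attached to both studies (default 1).
#' @return list of `n_iter` [instrument_set] objects.
#' @export
simulate_correlated_instruments <- function(J, r2_adjacent, n_iter,
                                            seed = 1L, mean_a = 10, se = 1) {
  stopifnot(J >= 2L, r2_adjacent >= 0, r2_adjacent < 1, n_iter >= 1L)
  r <- sqrt(r2_adjacent)
  C <- diag(1, J)
  if (J >= 2L) {
    idx <- cbind(seq_len(J - 1L), seq_len(J - 1L) + 1L)
    C[idx] <- r
    C[idx[, 2:1, drop = FALSE]] <- r
  }
  e <- eigen(C, symmetric = TRUE)
  if (min(e$values) < 1e-8) {  # PSD guard for large adjacent correlation
    vals <- pmax(e$values, 1e-8)
    C <- e$vectors %*% (vals * t(e$vectors))
    d <- 1 / sqrt(diag(C))
    C <- d * C * rep(d, each = J)
  }
  L <- chol(C)
  set.seed(seed)
  out <- vector("list", n_iter)
  for (i in seq_len(n_iter)) {
    bA <- mean_a + as.vector(crossprod(L, stats::rnorm(J)))
    bB <- as.vector(crossprod(L, stats::rnorm(J)))
    out[[i]] <- instrument_set(bA, rep(se, J), bB, rep(se, J))
  }
  out
}

#' Simulate instruments directly from the slope model
#'
#' Draws latent effects `beta_jA ~ N(0, sd_beta)`,
#' `beta_jB ~ N(alpha * beta_jA, sigma)` and observes them with Gaussian
#' noise at the stated SEs. Used for parameter-recovery and dispersion
#' calibration studies.
#'
#' @param J number of instruments.
#' @param alpha true gene-to-trait slope.
#' @param sigma true dispersion (SD).
#' @param sd_beta SD of latent instrument effects.
#' @param se_a,se_b observation SEs (scalars or length-J).
#' @param seed integer seed.
#' @return An [instrument_set]; attributes `beta_a_true`, `beta_b_true` hold
#'   the latent effects.
#' @export
simulate_from_slope_model <- function(J, alpha, sigma, sd_beta,
                                      se_a, se_b, seed = 1L) {
  stopifnot(J >= 1L, sigma >= 0, sd_beta > 0, all(se_a > 0), all(se_b > 0))
  se_a <- rep_len(se_a, J); se_b <- rep_len(se_b, J)
  set.seed(seed)
  beta_a <- stats::rnorm(J, 0, sd_beta)
  beta_b <- stats::rnorm(J, alpha * beta_a, sigma)
  obs_a <- stats::rnorm(J, beta_a, se_a)
  obs_b <- stats::rnorm(J, beta_b, se_b)
  out <- instrument_set(obs_a, se_a, obs_b, se_b)
  attr(out, "beta_a_true") <- beta_a
  attr(out, "beta_b_true") <- beta_b
  out
}
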