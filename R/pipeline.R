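# Run configuration and the end-to-end locus pipeline:
# harmonize -> per-cluster colocalization -> second-round trimming on
# candidate SNPs -> hierarchical slope fitting.

#' Pipeline run configuration
#'
#' Bundles every tunable threshold with its default: MAF filter 0.01,
#' clumping p1 0.001 / p2 1 / r2 0.1 / kb 500, collapse correlation 0.95,
#' across-cluster trim r-squared 0.05, credible level 0.80.
#'
#' @param maf MAF filter threshold.
#' @param clump_p1,clump_p2,clump_r2,clump_kb clumping settings.
#' @param collapse_r collapse threshold on r.
#' @param trim_r2 across-cluster r-squared ceiling.
#' @param level credible level for slope intervals.
#' @param instrument_mode `"fitted"` (posterior fitted marginal effects at
#'   the candidate, the default), `"posterior"` (posterior joint effects) or
#'   `"raw"` (observed candidate coefficients).
#' @param coloc_likelihood `"joint"` or `"marginal"` (see [fit_coloc]).
#' @param tau0_rule global-scale adaptation rule for [fit_coloc].
#' @param force fit the slope even with a single cluster.
#' @param coloc_control,slope_control sampler settings ([mcmc_control]).
#' @param seed root seed; all pipeline randomness derives from it.
#' @return list of class `mr_config`.
#' @export
mr_config <- function(maf = 0.01, clump_p1 = 0.001, clump_p2 = 1.0,
                      clump_r2 = 0.1, clump_kb = 500L, collapse_r = 0.95,
                      trim_r2 = 0.05, level = 0.80,
                      instrument_mode = c("fitted", "posterior", "raw"),
                      coloc_likelihood = c("joint", "marginal"),
                      tau0_rule = c("se", "se_sqrt", "se_full", "scale"),
                      force = FALSE,
                      coloc_control = mcmc_control(),
                      slope_control = mcmc_control(),
                      seed = 1L) {
  instrument_mode <- match.arg(instrument_mode)
  coloc_likelihood <- match.arg(coloc_likelihood)
  tau0_rule <- match.arg(tau0_rule)
  stopifnot(maf >= 0, maf < 0.5, clump_p1 > 0, clump_p1 <= 1,
            clump_p2 > 0, clump_p2 <= 1, clump_r2 >= 0, clump_r2 <= 1,
            clump_kb > 0, collapse_r > 0, collapse_r <= 1,
            trim_r2 > 0, trim_r2 <= 1, level > 0, level < 1)
  structure(list(maf = maf, clump_p1 = clump_p1, clump_p2 = clump_p2,
                 clump_r2 = clump_r2, clump_kb = as.integer(clump_kb),
                 collapse_r = collapse_r, trim_r2 = trim_r2, level = level,
                 instrument_mode = instrument_mode, tau0_rule = tau0_rule,
                 coloc_likelihood = coloc_likelihood,
                 force = force,
                 coloc_control = coloc_control, slope_control = slope_control,
                 seed = as.integer(seed)),
            class = "mr_config")
}

.trim_keep <- function(key_ids, key_p, key_pos, ld, r2_max) {
  r2_mat <- unclass(ld_subset(ld, key_ids))^2
  ord <- order(key_p, key_pos)
  kept <- integer()
  for (i in ord) {
    if (all(r2_mat[i, kept] < r2_max)) kept <- c(kept, i)
  }
  sort(kept)
}

#' Run the full gene-to-trait pipeline on a joined locus
#'
#' Chains: MAF filter, greedy clumping on eQTL p-values, first-round
#' across-cluster trimming keyed on clump index SNPs, per-cluster allele
#' flipping and collapsing, colocalization fits, second-round trimming keyed
#' on the candidate causal SNPs, instrument assembly, heterogeneity check,
#' and hierarchical slope fitting. SNP and cluster counts at every stage are
#' recorded in `$log`.
#'
#' @param locus a `joined_locus` from [match_studies] (or a simulated one).
#' @param config an [mr_config].
#' @param seed overrides `config$seed`.
#' @return list of class `mr_result`: `clusters`, `fits` (coloc fits),
#'   `instruments`, `slope` (a `slope_fit`, or `NULL` when fewer than two
#'   clusters survive and `force` is off), `log`, `config`. When no SNP
#'   reaches the clumping threshold, `$no_signal` is `TRUE` (the caller may
#'   draw a new seed in simulation studies).
#' @export
run_pipeline <- function(locus, config = mr_config(), seed = config$seed) {
  log <- list(n_input = nrow(locus$a))
  locus <- filter_maf(locus, config$maf)
  log$n_after_maf <- nrow(locus$a)

  clusters <- clump(locus, p1 = config$clump_p1, p2 = config$clump_p2,
                    r2 = config$clump_r2, kb = config$clump_kb)
  log$n_clumps <- length(clusters)
  if (length(clusters) == 0L) {
    return(structure(list(no_signal = TRUE, log = log, config = config,
                          clusters = list(), fits = list(),
                          instruments = NULL, slope = NULL),
                     class = "mr_result"))
  }

  keep1 <- .trim_keep(
    vapply(clusters, `[[`, character(1), "key_id"),
    vapply(clusters, function(cl) cl$a$pvalue[match(cl$key_id, cl$a$id)], numeric(1)),
    vapply(clusters, function(cl) cl$a$pos[match(cl$key_id, cl$a$id)], numeric(1)),
    locus$ld_a, config$trim_r2)
  clusters <- clusters[keep1]
  log$n_after_trim1 <- length(clusters)

  clusters <- lapply(clusters, function(cl) {
    collapse_correlated(flip_to_index(cl), r_threshold = config$collapse_r)
  })

  fits <- lapply(seq_along(clusters), function(j) {
    fit_coloc(clusters[[j]], control = config$coloc_control,
              seed = seed + 100L * j, tau0_rule = config$tau0_rule,
              likelihood = config$coloc_likelihood)
  })
  for (j in seq_along(clusters)) {
    clusters[[j]]$key_id <- fits[[j]]$candidate_id
  }

  keep2 <- .trim_keep(
    vapply(clusters, `[[`, character(1), "key_id"),
    vapply(clusters, function(cl) cl$a$pvalue[match(cl$key_id, cl$a$id)], numeric(1)),
    vapply(clusters, function(cl) cl$a$pos[match(cl$key_id, cl$a$id)], numeric(1)),
    locus$ld_a, config$trim_r2)
  clusters <- clusters[keep2]
  fits <- fits[keep2]
  log$n_after_trim2 <- length(clusters)

  instruments <- build_instruments(fits, mode = config$instrument_mode)
  slope <- if (nrow(instruments) >= 2L || config$force) {
    fit_slope(instruments, level = config$level,
              control = config$slope_control, seed = seed + 9999L,
              force = config$force)
  } else {
    warning("run_pipeline: fewer than 2 signal clusters after trimming; ",
            "no slope fit")
    NULL
  }

  structure(list(no_signal = FALSE, clusters = clusters, fits = fits,
                 instruments = instruments, slope = slope,
                 log = log, config = config, seed = seed),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  if (isTRUE(x$no_signal)) {
    cat("mr_result: no signal (no SNP below the clumping p-value threshold)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "mr_result: %d SNPs -> %d clumps -> %d clusters after trimming\n",
    x$log$n_after_maf, x$log$n_clumps, x$log$n_after_trim2))
  if (!is.null(x$slope)) print(x$slope)
  invisible(x)
}

#' Plot the gene-to-trait fit
#'
#' Scatter of instrument coefficients (outcome vs exposure) with SE bars,
#' the origin-anchored posterior-mean slope (solid line), the credible
#' interval on the slope (dashed lines), and the +/- posterior-mean
#' dispersion band around the fitted line (shaded).
#'
#' @param fit a `slope_fit`.
#' @param instruments defaults to the fit's instrument set.
#' @param path optional file path; when given, a PNG is written there.
#' @param ... further arguments to [graphics::plot].
#' @return invisibly, `path` (or `NULL` when plotting to the active device).
#' @export
plot_slope <- function(fit, instruments = fit$instruments, path = NULL, ...) {
  if (!is.null(path)) {
    grDevices::png(path, width = 600, height = 600)
    on.exit(grDevices::dev.off())
  }
  bA <- instruments$beta_a; sA <- instruments$se_a
  bB <- instruments$beta_b; sB <- instruments$se_b
  a_hat <- mean(fit$draws$alpha)
  s_hat <- mean(fit$draws$sigma)
  ci <- fit$alpha_interval
  xr <- range(0, bA + sA, bA - sA)
  yr <- range(0, bB + sB, bB - sB, a_hat * xr + s_hat, a_hat * xr - s_hat)
  graphics::plot(NA, xlim = xr, ylim = yr,
                 xlab = "eQTL coefficient", ylab = "GWAS coefficient", ...)
  xs <- seq(xr[1], xr[2], length.out = 50L)
  graphics::polygon(c(xs, rev(xs)),
                    c(a_hat * xs - s_hat, rev(a_hat * xs + s_hat)),
                    col = grDevices::adjustcolor("lightblue", 0.5),
                    border = NA)
  graphics::segments(bA - sA, bB, bA + sA, bB, col = "grey40")
  graphics::segments(bA, bB - sB, bA, bB + sB, col = "grey40")
  graphics::points(bA, bB, pch = 19)
  graphics::abline(0, a_hat, col = "blue", lwd = 2)
  graphics::abline(0, ci[1], col = "blue", lty = 2)
  graphics::abline(0, ci[2], col = "blue", lty = 2)
  invisible(path)
}
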