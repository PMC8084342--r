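# Benchmark metrics and the classical IVW fixed-effects comparator.

#' Inverse-variance-weighted fixed-effects slope
#'
#' The classical no-intercept MR estimator: regression of outcome on
#' exposure coefficients through the origin with weights `1/se_b^2`:
#' `slope = sum(w * bA * bB) / sum(w * bA^2)`,
#' `se = 1 / sqrt(sum(w * bA^2))`.
#'
#' @param instruments an [instrument_set].
#' @return list with `slope` and `se`.
#' @export
ivw_fixed_effects <- function(instruments) {
  bA <- instruments$beta_a; bB <- instruments$beta_b
  w <- 1 / instruments$se_b^2
  denom <- sum(w * bA^2)
  if (denom == 0) stop("ivw_fixed_effects: all exposure coefficients are 0")
  list(slope = sum(w * bA * bB) / denom, se = 1 / sqrt(denom))
}

#' Relative mean absolute error
#'
#' `mean(|estimate - truth|) / |truth|`. For a null truth of exactly 0 the
#' plain mean absolute error is returned with attribute `relative = FALSE`.
#'
#' @param estimates numeric vector of estimates.
#' @param truth true value.
#' @return numeric scalar (attribute `relative` indicates which pathway).
#' @export
rmae <- function(estimates, truth) {
  mae <- mean(abs(estimates - truth))
  if (truth == 0) {
    return(structure(mae, relative = FALSE))
  }
  structure(mae / abs(truth), relative = TRUE)
}

#' Estimator bias
#'
#' Sample mean of the estimates minus the true value.
#'
#' @param estimates numeric vector.
#' @param truth true value.
#' @return numeric scalar.
#' @export
estimator_bias <- function(estimates, truth) mean(estimates) - truth

#' Interval coverage
#'
#' Fraction of intervals containing the truth (closed endpoints).
#'
#' @param intervals two-column matrix (lower, upper) or list of length-2
#'   vectors.
#' @param truth true value.
#' @return numeric in [0, 1].
#' @export
coverage <- function(intervals, truth) {
  if (is.list(intervals)) intervals <- do.call(rbind, intervals)
  intervals <- as.matrix(intervals)
  stopifnot(ncol(intervals) == 2L)
  mean(intervals[, 1] <= truth & truth <= intervals[, 2])
}

#' Candidate-SNP accuracy
#'
#' Over signal clusters containing a true causal eSNP, the fraction where
#' the chosen candidate equals the causal SNP or is in high LD with it
#' (`|r| > r_threshold`).
#'
#' @param chosen character vector of chosen SNP ids (one per cluster).
#' @param causal character vector (or list of vectors, one per cluster) of
#'   true causal SNP ids in the cluster.
#' @param ld [ld_matrix] covering chosen and causal SNPs.
#' @param r_threshold high-LD threshold on |r| (default 0.95).
#' @return numeric in [0, 1].
#' @export
candidate_accuracy <- function(chosen, causal, ld, r_threshold = 0.95) {
  if (!is.list(causal)) causal <- as.list(causal)
  stopifnot(length(chosen) == length(causal))
  hit <- vapply(seq_along(chosen), function(k) {
    cand <- chosen[k]
    any(vapply(causal[[k]], function(cs) {
      cand == cs || abs(unclass(ld)[cand, cs]) > r_threshold
    }, logical(1)))
  }, logical(1))
  mean(hit)
}

#' Summarize a set of benchmark replicates
#'
#' @param estimates numeric vector of slope estimates.
#' @param intervals two-column matrix of interval endpoints.
#' @param truth true slope.
#' @return list (class `eval_report`) with `rmae`, `bias`, `coverage`,
#'   `fp_rate` (fraction of intervals excluding 0) and the inputs.
#' @export
eval_report <- function(estimates, intervals, truth) {
  intervals <- as.matrix(intervals)
  stopifnot(length(estimates) == nrow(intervals))
  structure(list(
    estimates = estimates, intervals = intervals, truth = truth,
    rmae = rmae(estimates, truth),
    bias = estimator_bias(estimates, truth),
    coverage = coverage(intervals, truth),
    fp_rate = mean(!(intervals[, 1] <= 0 & 0 <= intervals[, 2]))
  ), class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report (%d replicates, truth %.4g): RMAE %.3f, bias %.4f, coverage %.3f, fp rate %.3f\n",
    length(x$estimates), x$truth, as.numeric(x$rmae), x$bias, x$coverage,
    x$fp_rate))
  invisible(x)
}
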