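#' Construct a summary-statistics table
#'
#' A `sumstats` object is a data frame with one row per SNP and the canonical
#' columns `id`, `chrom`, `pos`, `a1` (effect allele), `a2` (other allele),
#' `beta` (estimated coefficient per copy of `a1`), `se`, `pvalue`, `maf`.
#' Rows violating the per-SNP invariants (positive SE, p-value in (0, 1],
#' distinct alleles, MAF in (0, 0.5], unique id) are removed and recorded in
#' the `rejected` attribute with a per-row reason.
#'
#' @param df data frame holding the canonical columns.
#' @param study_label `"A"` for the exposure (eQTL) study, `"B"` for the
#'   outcome (GWAS) study.
#' @return A `sumstats` data frame; `attr(, "rejected")` holds the per-row
#'   validation log and `attr(, "study_label")` the study label.
#' @export
sumstats <- function(df, study_label = c("A", "B")) {
  study_label <- match.arg(study_label)
  needed <- c("id", "chrom", "pos", "a1", "a2", "beta", "se", "pvalue", "maf")
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols) > 0L) {
    stop("sumstats: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[, needed, drop = FALSE]
  df$id <- as.character(df$id)
  df$chrom <- as.character(df$chrom)
  df$pos <- as.integer(df$pos)
  df$a1 <- toupper(as.character(df$a1))
  df$a2 <- toupper(as.character(df$a2))
  for (nm in c("beta", "se", "pvalue", "maf")) df[[nm]] <- as.numeric(df[[nm]])

  reason <- rep(NA_character_, nrow(df))
  bad <- function(cond, why) {
    cond[is.na(cond)] <- TRUE
    ifelse(is.na(reason) & cond, why, reason)
  }
  reason <- bad(!is.finite(df$beta), "non-finite beta")
  reason <- bad(!is.finite(df$se) | df$se <= 0, "se <= 0")
  reason <- bad(!is.finite(df$pvalue) | df$pvalue <= 0 | df$pvalue > 1,
                "pvalue outside (0, 1]")
  reason <- bad(!is.finite(df$maf) | df$maf <= 0 | df$maf > 0.5,
                "maf outside (0, 0.5]")
  reason <- bad(df$a1 == df$a2, "effect allele equals other allele")
  reason <- bad(duplicated(df$id), "duplicated id")

  rejected <- data.frame(id = df$id[!is.na(reason)],
                         reason = reason[!is.na(reason)],
                         stringsAsFactors = FALSE)
  out <- df[is.na(reason), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, study_label = study_label, rejected = rejected,
            class = c("sumstats", "data.frame"))
}

#' Construct a signed LD matrix
#'
#' @param r square numeric matrix of signed Pearson correlations between
#'   effect-allele dosages.
#' @param ids SNP identifiers for rows/columns (defaults to `rownames(r)`).
#' @param tol tolerance for the symmetry / unit-diagonal checks.
#' @return A symmetric matrix with unit diagonal and `ids` as dimnames,
#'   of class `ld_matrix`.
#' @export
ld_matrix <- function(r, ids = rownames(r), tol = 1e-8) {
  r <- as.matrix(r)
  if (nrow(r) != ncol(r)) stop("ld_matrix: matrix is not square")
  if (is.null(ids)) stop("ld_matrix: SNP ids are required")
  ids <- as.character(ids)
  if (anyDuplicated(ids)) stop("ld_matrix: duplicated SNP ids")
  if (length(ids) != nrow(r)) stop("ld_matrix: ids do not match dimension")
  if (max(abs(r - t(r))) > tol) stop("ld_matrix: asymmetric beyond tolerance")
  if (max(abs(diag(r) - 1)) > tol) stop("ld_matrix: diagonal is not 1")
  if (max(abs(r)) > 1 + tol) stop("ld_matrix: entries outside [-1, 1]")
  r <- (r + t(r)) / 2
  diag(r) <- 1
  dimnames(r) <- list(ids, ids)
  structure(r, class = c("ld_matrix", "matrix", "array"))
}

#' Subset an LD matrix to a set of SNPs (order preserved as given)
#' @param ld `ld_matrix`.
#' @param ids SNP ids to keep, in the desired order.
#' @keywords internal
ld_subset <- function(ld, ids) {
  missing <- setdiff(ids, rownames(ld))
  if (length(missing) > 0L) {
    stop("LD matrix is missing SNP(s): ", paste(missing, collapse = ", "))
  }
  ld_matrix(unclass(ld)[ids, ids, drop = FALSE], ids = ids)
}

#' @export
print.sumstats <- function(x, ...) {
  cat(sprintf("sumstats (study %s): %d SNPs, %d rejected rows\n",
              attr(x, "study_label"), nrow(x), nrow(attr(x, "rejected"))))
  print(utils::head(as.data.frame(x)), ...)
  invisible(x)
}

#' Construct a joined locus (matched studies A and B)
#' @keywords internal
joined_locus <- function(a, b, ld_a, ld_b = ld_a, drop_log = NULL) {
  stopifnot(identical(a$id, b$id))
  if (is.null(drop_log)) {
    drop_log <- data.frame(id = character(), reason = character(),
                           stringsAsFactors = FALSE)
  }
  structure(list(a = a, b = b, ld_a = ld_a, ld_b = ld_b, drop_log = drop_log),
            class = "joined_locus")
}

#' @export
print.joined_locus <- function(x, ...) {
  cat(sprintf("joined_locus: %d matched SNPs (%d dropped)\n",
              nrow(x$a), nrow(x$drop_log)))
  invisible(x)
}

#' Construct an instrument set for slope fitting
#'
#' One row per nearly-LD-independent signal cluster: the candidate SNP's
#' eQTL coefficient/SE and GWAS coefficient/SE.
#'
#' @param beta_a,se_a,beta_b,se_b numeric vectors of length J.
#' @param id optional candidate SNP ids.
#' @param cluster optional cluster labels.
#' @return data frame of class `instrument_set`.
#' @export
instrument_set <- function(beta_a, se_a, beta_b, se_b,
                           id = NULL, cluster = NULL) {
  J <- length(beta_a)
  stopifnot(J >= 1, length(se_a) == J, length(beta_b) == J, length(se_b) == J)
  if (any(!is.finite(c(beta_a, se_a, beta_b, se_b)))) {
    stop("instrument_set: non-finite values")
  }
  if (any(se_a <= 0) || any(se_b <= 0)) stop("instrument_set: SEs must be > 0")
  if (is.null(id)) id <- paste0("cluster", seq_len(J))
  if (is.null(cluster)) cluster <- seq_len(J)
  structure(data.frame(cluster = cluster, id = as.character(id),
                       beta_a = beta_a, se_a = se_a,
                       beta_b = beta_b, se_b = se_b,
                       stringsAsFactors = FALSE),
            class = c("instrument_set", "data.frame"))
}
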