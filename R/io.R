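#' Read a summary-statistics table from delimited text
#'
#' Reads a tab- or comma-delimited file with a header and maps its columns to
#' the canonical names `id`, `chrom`, `pos`, `a1`, `a2`, `beta`, `se`,
#' `pvalue`, `maf`. Rows that violate the per-SNP invariants are rejected and
#' reported in the `rejected` attribute of the result.
#'
#' @param path file path.
#' @param study_label `"A"` (exposure/eQTL) or `"B"` (outcome/GWAS).
#' @param column_map named character vector mapping canonical names to file
#'   column names, e.g. `c(id = "SNP", pvalue = "P")`. Canonical names absent
#'   from the map are assumed to appear verbatim in the file.
#' @param sep field separator; `NULL` (default) auto-detects tab vs comma
#'   from the header line.
#' @return A [sumstats] object.
#' @export
read_sumstats <- function(path, study_label = c("A", "B"),
                          column_map = NULL, sep = NULL) {
  study_label <- match.arg(study_label)
  if (!file.exists(path)) stop("read_sumstats: no such file: ", path)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl(",", header, fixed = TRUE) &&
               !grepl("\t", header, fixed = TRUE)) "," else "\t"
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  canonical <- c("id", "chrom", "pos", "a1", "a2", "beta", "se", "pvalue", "maf")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) map[names(column_map)] <- column_map
  missing_cols <- map[!map %in% names(raw)]
  if (length(missing_cols) > 0L) {
    stop("read_sumstats: file lacks column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  df <- stats::setNames(raw[, map, drop = FALSE], canonical)
  sumstats(df, study_label = study_label)
}

#' Read a signed LD matrix
#'
#' Accepts either a labelled square matrix (tab-delimited, SNP ids as header
#' and first column) or a PLINK-style long format with columns `SNP_A`,
#' `SNP_B`, `R`. In long format, unlisted pairs default to r = 0 and the
#' diagonal to 1.
#'
#' @param path file path.
#' @param ids SNP ids the matrix is restricted and reordered to.
#' @param tol symmetry tolerance for the square format.
#' @return An [ld_matrix].
#' @export
read_ld <- function(path, ids, tol = 1e-8) {
  if (!file.exists(path)) stop("read_ld: no such file: ", path)
  ids <- as.character(ids)
  header <- strsplit(readLines(path, n = 1L), "[\t ,]+")[[1]]
  long_format <- all(c("SNP_A", "SNP_B", "R") %in% header)
  if (long_format) {
    pairs <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
    r <- diag(1, length(ids))
    dimnames(r) <- list(ids, ids)
    keep <- pairs$SNP_A %in% ids & pairs$SNP_B %in% ids
    pairs <- pairs[keep, , drop = FALSE]
    for (k in seq_len(nrow(pairs))) {
      i <- pairs$SNP_A[k]; j <- pairs$SNP_B[k]
      r[i, j] <- r[j, i] <- pairs$R[k]
    }
    diag(r) <- 1
    ld_matrix(r, ids = ids, tol = tol)
  } else {
    m <- as.matrix(utils::read.table(path, header = TRUE, row.names = 1L,
                                     check.names = FALSE))
    missing <- setdiff(ids, rownames(m))
    if (length(missing) > 0L) {
      stop("read_ld: SNP(s) absent from file: ", paste(missing, collapse = ", "))
    }
    ld_matrix(m[ids, ids, drop = FALSE], ids = ids, tol = tol)
  }
}

#' Write an LD matrix as labelled square text
#'
#' Inverse of the square-format branch of [read_ld]; values are written with
#' full precision so that a write/read round trip reproduces the matrix.
#'
#' @param ld an [ld_matrix].
#' @param path output file path.
#' @export
write_ld <- function(ld, path) {
  df <- as.data.frame(unclass(ld))
  df <- cbind(id = rownames(ld), df)
  utils::write.table(format(df, digits = 17, trim = TRUE), path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a PLINK bim-style allele reference
#'
#' Six tab-delimited columns without header: chromosome, SNP id, genetic
#' distance, position, minor allele (A1), major allele (A2).
#'
#' @param path file path.
#' @return data frame with columns `id`, `chrom`, `pos`, `minor`, `major`.
#' @export
read_allele_ref <- function(path) {
  if (!file.exists(path)) stop("read_allele_ref: no such file: ", path)
  bim <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "id", "cm", "pos",
                                         "minor", "major"))
  if (anyDuplicated(bim$id)) stop("read_allele_ref: duplicated SNP ids")
  if (any(toupper(bim$minor) == toupper(bim$major))) {
    stop("read_allele_ref: identical major/minor allele")
  }
  data.frame(id = as.character(bim$id), chrom = as.character(bim$chrom),
             pos = as.integer(bim$pos), minor = toupper(bim$minor),
             major = toupper(bim$major), stringsAsFactors = FALSE)
}

.complement <- c(A = "T", C = "G", G = "C", T = "A")

.flip_strand <- function(allele) {
  out <- .complement[allele]
  out[is.na(out)] <- allele[is.na(out)]
  unname(out)
}

.is_palindromic <- function(a1, a2) .flip_strand(a1) == a2

#' Match two studies on SNP identity with allele reconciliation
#'
#' Intersects the studies on SNP id and reconciles study B's allele coding to
#' study A's orientation. Where B's effect/other alleles are swapped relative
#' to A, B's beta sign is negated and its alleles swapped. No strand
#' inference is attempted: allele pairs that only match after strand
#' complementation are dropped, as are swapped strand-ambiguous (A/T, C/G)
#' SNPs, where a swap is indistinguishable from a strand flip. Every removed
#' SNP is recorded with a reason.
#'
#' @param a,b [sumstats] for study A (exposure) and B (outcome).
#' @param ld_a LD matrix aligned to study A's effect alleles.
#' @param ld_b LD matrix for study B; defaults to `ld_a` (a single matrix may
#'   be shared when both studies come from the same population).
#' @param ref optional allele reference from [read_allele_ref]; SNPs whose
#'   allele pair does not match the reference panel's pair are dropped.
#' @return A `joined_locus`: matched tables `a` and `b` on a common
#'   orientation, LD matrices restricted to the matched SNPs, and a
#'   `drop_log` data frame.
#' @export
match_studies <- function(a, b, ld_a = NULL, ld_b = ld_a, ref = NULL) {
  common <- intersect(a$id, b$id)
  drop_log <- data.frame(id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  log_drop <- function(id, reason) {
    rbind(drop_log, data.frame(id = id, reason = reason,
                               stringsAsFactors = FALSE))
  }
  only_a <- setdiff(a$id, common)
  only_b <- setdiff(b$id, common)
  if (length(only_a)) drop_log <- log_drop(only_a, "absent from study B")
  if (length(only_b)) drop_log <- log_drop(only_b, "absent from study A")
  if (length(common) == 0L) stop("match_studies: no common SNPs")

  a <- a[match(common, a$id), , drop = FALSE]
  b <- b[match(common, b$id), , drop = FALSE]

  keep <- rep(TRUE, length(common))
  for (i in seq_along(common)) {
    a1 <- a$a1[i]; a2 <- a$a2[i]
    b1 <- b$a1[i]; b2 <- b$a2[i]
    pal <- .is_palindromic(a1, a2)
    if (b1 == a1 && b2 == a2) {
      next  # identical coding; for palindromic SNPs assume same strand
    } else if (b1 == a2 && b2 == a1) {
      if (pal) {  # swap indistinguishable from strand flip
        keep[i] <- FALSE
        drop_log <- log_drop(common[i], "strand-ambiguous palindromic SNP")
        next
      }
      b$beta[i] <- -b$beta[i]
      b$a1[i] <- a1; b$a2[i] <- a2
    } else if (.flip_strand(b1) == a1 && .flip_strand(b2) == a2 ||
               .flip_strand(b1) == a2 && .flip_strand(b2) == a1) {
      keep[i] <- FALSE
      drop_log <- log_drop(common[i], "strand mismatch (complement coding)")
    } else {
      keep[i] <- FALSE
      drop_log <- log_drop(common[i], "irreconcilable allele pair")
    }
  }

  if (!is.null(ref)) {
    m <- match(a$id, ref$id)
    for (i in which(keep & !is.na(m))) {
      pair <- sort(c(a$a1[i], a$a2[i]))
      rp <- sort(c(ref$minor[m[i]], ref$major[m[i]]))
      if (!identical(pair, rp)) {
        keep[i] <- FALSE
        drop_log <- log_drop(a$id[i], "alleles disagree with reference panel")
      }
    }
  }

  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  if (nrow(a) == 0L) stop("match_studies: no reconcilable SNPs")
  if (!is.null(ld_a)) ld_a <- ld_subset(ld_a, a$id)
  if (!is.null(ld_b)) ld_b <- ld_subset(ld_b, a$id) else ld_b <- ld_a
  joined_locus(a, b, ld_a, ld_b, drop_log)
}
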