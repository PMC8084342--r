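#' Signal-cluster constructor
#'
#' A signal cluster is one nearly-LD-independent clump: the index SNP (lowest
#' eQTL p-value), member records for both studies after orientation, signed
#' sub-LD matrices, and a key SNP used for across-cluster r-squared checks
#' (the index SNP before colocalization, the candidate causal SNP after).
#'
#' @keywords internal
signal_cluster <- function(a, b, ld_a, ld_b, index_id, key_id = index_id,
                           groups = NULL) {
  stopifnot(identical(a$id, b$id), index_id %in% a$id)
  structure(list(a = a, b = b, ld_a = ld_a, ld_b = ld_b,
                 index_id = index_id, key_id = key_id, groups = groups),
            class = "signal_cluster")
}

#' @export
print.signal_cluster <- function(x, ...) {
  cat(sprintf("signal_cluster: index %s, %d member SNP(s)\n",
              x$index_id, nrow(x$a)))
  invisible(x)
}

#' Minor-allele-frequency filter
#'
#' Removes SNPs whose MAF (in either study) falls below the threshold from
#' both studies and the LD matrices. The boundary is kept: `maf >= threshold`
#' is retained.
#'
#' @param locus a `joined_locus`.
#' @param threshold MAF threshold, default 0.01.
#' @return Filtered `joined_locus`; removals are appended to the drop log.
#' @export
filter_maf <- function(locus, threshold = 0.01) {
  keep <- pmin(locus$a$maf, locus$b$maf) >= threshold
  if (all(keep)) return(locus)
  dropped <- locus$a$id[!keep]
  locus$drop_log <- rbind(locus$drop_log,
                          data.frame(id = dropped,
                                     reason = sprintf("maf < %g", threshold),
                                     stringsAsFactors = FALSE))
  locus$a <- locus$a[keep, , drop = FALSE]
  locus$b <- locus$b[keep, , drop = FALSE]
  rownames(locus$a) <- rownames(locus$b) <- NULL
  if (nrow(locus$a) == 0L) {
    warning("filter_maf: no SNPs remain after MAF filter")
    return(locus)
  }
  locus$ld_a <- ld_subset(locus$ld_a, locus$a$id)
  locus$ld_b <- ld_subset(locus$ld_b, locus$a$id)
  locus
}

#' Greedy LD clumping on eQTL p-values
#'
#' Repeatedly takes the unassigned SNP with the smallest eQTL p-value below
#' `p1` as a clump index, and assigns to its cluster every unassigned SNP with
#' p-value at most `p2`, within `kb` kilobases on the same chromosome, and
#' squared correlation at least `r2` with the index. Ties on p-value are
#' broken by smaller genomic position.
#'
#' @param locus a `joined_locus` (typically after [filter_maf]).
#' @param p1 index p-value threshold (default 0.001).
#' @param p2 member p-value threshold (default 1).
#' @param r2 member r-squared threshold with the index (default 0.1).
#' @param kb window half-width in kilobases (default 500).
#' @return List of `signal_cluster` objects, ordered by index p-value. When
#'   no SNP reaches `p1` the list is empty and carries attribute
#'   `no_signal = TRUE`.
#' @export
clump <- function(locus, p1 = 0.001, p2 = 1.0, r2 = 0.1, kb = 500L) {
  a <- locus$a
  n <- nrow(a)
  r2_mat <- unclass(locus$ld_a)^2
  unassigned <- rep(TRUE, n)
  ord <- order(a$pvalue, a$pos)
  clusters <- list()
  repeat {
    cand <- ord[unassigned[ord] & a$pvalue[ord] < p1]
    if (length(cand) == 0L) break
    idx <- cand[1L]
    members <- which(unassigned &
                       a$pvalue <= p2 &
                       a$chrom == a$chrom[idx] &
                       abs(a$pos - a$pos[idx]) <= kb * 1000 &
                       r2_mat[, idx] >= r2)
    members <- union(idx, members)
    members <- members[order(a$pos[members])]
    unassigned[members] <- FALSE
    ids <- a$id[members]
    clusters[[length(clusters) + 1L]] <-
      signal_cluster(a = a[members, , drop = FALSE],
                     b = locus$b[members, , drop = FALSE],
                     ld_a = ld_subset(locus$ld_a, ids),
                     ld_b = ld_subset(locus$ld_b, ids),
                     index_id = a$id[idx])
  }
  if (length(clusters) == 0L) attr(clusters, "no_signal") <- TRUE
  clusters
}

.flip_snps <- function(cluster, flip_idx) {
  if (length(flip_idx) == 0L) return(cluster)
  for (tab in c("a", "b")) {
    cluster[[tab]]$beta[flip_idx] <- -cluster[[tab]]$beta[flip_idx]
    tmp <- cluster[[tab]]$a1[flip_idx]
    cluster[[tab]]$a1[flip_idx] <- cluster[[tab]]$a2[flip_idx]
    cluster[[tab]]$a2[flip_idx] <- tmp
  }
  for (mat in c("ld_a", "ld_b")) {
    m <- unclass(cluster[[mat]])
    m[flip_idx, ] <- -m[flip_idx, , drop = FALSE]
    m[, flip_idx] <- -m[, flip_idx, drop = FALSE]
    diag(m) <- 1
    cluster[[mat]] <- ld_matrix(m, ids = rownames(m))
  }
  cluster
}

#' Flip member alleles into the positive-index orientation
#'
#' Orients the cluster so that the index SNP has a positive eQTL coefficient
#' and every member is in non-negative LD correlation with the index: if the
#' index eQTL beta is negative the index itself is flipped first, then every
#' member negatively correlated with the index has both study betas negated,
#' alleles swapped, and its LD row/column sign-flipped. Idempotent.
#'
#' @param cluster a `signal_cluster`.
#' @return The oriented `signal_cluster`.
#' @export
flip_to_index <- function(cluster) {
  i <- match(cluster$index_id, cluster$a$id)
  if (cluster$a$beta[i] < 0) cluster <- .flip_snps(cluster, i)
  r_index <- unclass(cluster$ld_a)[, i]
  neg <- which(r_index < 0)
  .flip_snps(cluster, setdiff(neg, i))
}

#' Collapse highly correlated SNPs to representatives
#'
#' Greedy grouping: seeds are chosen in ascending eQTL p-value order (ties by
#' position); each seed absorbs every unassigned SNP with signed correlation
#' above `r_threshold` to it and becomes the group representative. Only
#' representatives are carried forward; the grouping is retained in
#' `$groups` (a list mapping representative id to absorbed member ids).
#'
#' @param cluster a flipped `signal_cluster`.
#' @param r_threshold collapse threshold on r (default 0.95).
#' @return `signal_cluster` containing the representatives only.
#' @export
collapse_correlated <- function(cluster, r_threshold = 0.95) {
  a <- cluster$a
  n <- nrow(a)
  r <- unclass(cluster$ld_a)
  ord <- order(a$pvalue, a$pos)
  assigned <- rep(FALSE, n)
  groups <- list()
  reps <- integer()
  for (i in ord) {
    if (assigned[i]) next
    absorb <- which(!assigned & r[, i] > r_threshold)
    absorb <- union(i, absorb)
    assigned[absorb] <- TRUE
    reps <- c(reps, i)
    groups[[a$id[i]]] <- a$id[absorb]
  }
  reps <- sort(reps)  # keep genomic order
  ids <- a$id[reps]
  index_id <- if (cluster$index_id %in% ids) cluster$index_id else {
    # index absorbed into a representative's group: the absorbing rep stands in
    names(groups)[vapply(groups, function(g) cluster$index_id %in% g, logical(1))][1]
  }
  signal_cluster(a = a[reps, , drop = FALSE],
                 b = cluster$b[reps, , drop = FALSE],
                 ld_a = ld_subset(cluster$ld_a, ids),
                 ld_b = ld_subset(cluster$ld_b, ids),
                 index_id = index_id,
                 key_id = if (cluster$key_id %in% ids) cluster$key_id else index_id,
                 groups = groups)
}

#' Trim clusters to pairwise-independent key SNPs
#'
#' Sorts clusters by their key SNP's eQTL p-value (ascending) and keeps a
#' cluster iff its key SNP has squared correlation below `r2_max` with the
#' key SNP of every previously kept cluster; clusters with weaker index
#' signals are removed first. Run once keyed on clump index SNPs before
#' colocalization and again keyed on candidate causal SNPs after.
#'
#' @param clusters list of `signal_cluster`.
#' @param ld full-locus LD matrix covering all key SNPs (study A orientation).
#' @param r2_max maximum allowed across-cluster squared correlation
#'   (default 0.05).
#' @return The retained clusters (original relative order). Fewer than two
#'   survivors triggers an `insufficient allelic heterogeneity` warning.
#' @export
trim_clusters <- function(clusters, ld, r2_max = 0.05) {
  if (length(clusters) == 0L) return(clusters)
  key_ids <- vapply(clusters, function(cl) cl$key_id, character(1))
  key_p <- vapply(clusters, function(cl) {
    cl$a$pvalue[match(cl$key_id, cl$a$id)]
  }, numeric(1))
  key_pos <- vapply(clusters, function(cl) {
    cl$a$pos[match(cl$key_id, cl$a$id)]
  }, numeric(1))
  r2_mat <- unclass(ld_subset(ld, key_ids))^2
  ord <- order(key_p, key_pos)
  kept <- integer()
  for (i in ord) {
    if (all(r2_mat[i, kept] < r2_max)) kept <- c(kept, i)
  }
  out <- clusters[sort(kept)]
  if (length(out) < 2L) {
    warning("trim_clusters: insufficient allelic heterogeneity ",
            "(fewer than 2 independent signal clusters)")
  }
  out
}
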