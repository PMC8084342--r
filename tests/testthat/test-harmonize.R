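test_that("filter_maf applies a keep-at-boundary rule", {
  j <- make_toy_locus(6, seed = 3)
  j$a$maf <- c(0.005, 0.01, 0.2, 0.3, 0.009, 0.5)
  j$b$maf <- j$a$maf
  f <- filter_maf(j, 0.01)
  expect_setequal(f$a$id, j$a$id[c(2, 3, 4, 6)])
  expect_setequal(f$drop_log$id[grepl("maf", f$drop_log$reason)],
                  j$a$id[c(1, 5)])
  # all above threshold: identity
  j$a$maf <- j$b$maf <- rep(0.3, 6)
  expect_equal(filter_maf(j, 0.01)$a$id, j$a$id)
})

test_that("clump handles singleton and no-signal edge cases", {
  j <- make_toy_locus(1, seed = 5)
  j$a$pvalue <- 1e-4
  cl <- clump(j)
  expect_length(cl, 1L)
  expect_equal(cl[[1]]$index_id, j$a$id)

  j2 <- make_toy_locus(8, seed = 6)
  j2$a$pvalue <- runif(8, 0.01, 1)
  cl2 <- clump(j2)
  expect_length(cl2, 0L)
  expect_true(attr(cl2, "no_signal"))
})

test_that("clump matches an independently coded greedy oracle", {
  for (seed in 1:20) {
    j <- make_toy_locus(10, seed = seed)
    j$a$pvalue <- runif(10)^4
    cl <- clump(j, p1 = 0.05, p2 = 0.8, r2 = 0.2, kb = 600)
    orc <- oracle_clump(j$a$pvalue, j$a$pos, j$a$chrom,
                        unclass(j$ld_a)^2, 0.05, 0.8, 0.2, 600)
    expect_length(cl, length(orc))
    for (k in seq_along(cl)) {
      expect_equal(cl[[k]]$index_id, j$a$id[orc[[k]]$index])
      expect_setequal(cl[[k]]$a$id, j$a$id[orc[[k]]$members])
    }
  }
})

test_that("clusters are disjoint and raising p1 never decreases clump count", {
  j <- make_toy_locus(10, seed = 11)
  j$a$pvalue <- runif(10)^3
  all_ids <- unlist(lapply(clump(j, p1 = 0.1), function(cl) cl$a$id))
  expect_false(anyDuplicated(all_ids) > 0)
  expect_true(all(all_ids %in% j$a$id))
  counts <- vapply(c(1e-4, 1e-2, 0.1, 1),
                   function(p1) length(clump(j, p1 = p1)), numeric(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("flip_to_index orients betas and LD consistently and is idempotent", {
  R <- matrix(c(1, -0.8, -0.8, 1), 2)
  cl <- make_cluster(beta_a = c(0.5, 0.2), se_a = c(0.05, 0.05),
                     beta_b = c(0.3, -0.1), se_b = c(0.05, 0.05), R = R,
                     pvalue = c(1e-6, 1e-3))
  fl <- flip_to_index(cl)
  expect_equal(fl$a$beta, c(0.5, -0.2))
  expect_equal(fl$b$beta, c(0.3, 0.1))
  expect_equal(unclass(fl$ld_a)[1, 2], 0.8)
  expect_equal(fl$a$a1[2], cl$a$a2[2])  # alleles swapped with the sign
  expect_identical(flip_to_index(fl)$a$beta, fl$a$beta)

  # negative index beta: index flipped first, correlations re-signed
  cl2 <- make_cluster(beta_a = c(-0.5, 0.2), se_a = c(0.05, 0.05),
                      beta_b = c(0.3, -0.1), se_b = c(0.05, 0.05), R = R,
                      pvalue = c(1e-6, 1e-3))
  fl2 <- flip_to_index(cl2)
  i <- match(fl2$index_id, fl2$a$id)
  expect_gt(fl2$a$beta[i], 0)
  expect_true(all(unclass(fl2$ld_a)[, i] >= 0))
  expect_identical(flip_to_index(fl2)$a$beta, fl2$a$beta)
})

test_that("collapse_correlated groups by the greedy seed rule", {
  # two SNPs r = 0.99: one representative, the smaller-p SNP
  R <- matrix(c(1, 0.99, 0.99, 1), 2)
  cl <- make_cluster(c(0.5, 0.45), c(0.05, 0.05), c(0.2, 0.2), c(0.05, 0.05),
                     R, pvalue = c(1e-6, 1e-4))
  co <- collapse_correlated(cl)
  expect_equal(nrow(co$a), 1L)
  expect_equal(co$a$id, "rs1")
  expect_setequal(co$groups[["rs1"]], c("rs1", "rs2"))

  # all pairwise r below threshold: identity
  R2 <- diag(3); R2[1, 2] <- R2[2, 1] <- 0.5
  cl2 <- make_cluster(c(0.5, 0.3, 0.2), rep(0.05, 3), rep(0.1, 3),
                      rep(0.05, 3), R2)
  expect_equal(nrow(collapse_correlated(cl2)$a), 3L)

  # chain r(1,2) = r(2,3) = 0.96, r(1,3) = 0.90, p ascending in id order:
  # seed 1 absorbs 2; 3 is left alone -> groups {1,2}, {3}
  R3 <- matrix(c(1, 0.96, 0.90, 0.96, 1, 0.96, 0.90, 0.96, 1), 3)
  cl3 <- make_cluster(c(0.5, 0.4, 0.3), rep(0.05, 3), rep(0.1, 3),
                      rep(0.05, 3), R3, pvalue = c(1e-6, 1e-5, 1e-4))
  co3 <- collapse_correlated(cl3)
  expect_equal(co3$a$id, c("rs1", "rs3"))
  expect_setequal(co3$groups[["rs1"]], c("rs1", "rs2"))
  expect_equal(co3$groups[["rs3"]], "rs3")
})

test_that("collapse_correlated matches the enumeration oracle on random toys", {
  for (seed in 1:10) {
    set.seed(seed)
    n <- 7
    L <- matrix(rnorm(n), n, 1)
    S <- tcrossprod(L) + diag(runif(n, 0.01, 0.5))
    d <- 1 / sqrt(diag(S)); R <- d * S * rep(d, each = n)
    pv <- sort(runif(n, 1e-8, 1e-3))
    cl <- flip_to_index(make_cluster(runif(n, 0.1, 0.5), rep(0.05, n),
                                     rnorm(n, 0, 0.1), rep(0.05, n),
                                     R, pvalue = pv))
    co <- collapse_correlated(cl, r_threshold = 0.9)
    orc <- oracle_collapse(cl$a$pvalue, cl$a$pos, unclass(cl$ld_a), 0.9)
    expect_setequal(co$a$id, cl$a$id[vapply(orc, `[[`, numeric(1), "rep")])
  }
})

test_that("trim_clusters keeps the stronger cluster and matches the oracle", {
  mk_clusters <- function(r2m, pv) {
    n <- nrow(r2m)
    ids <- paste0("rs", seq_len(n))
    d <- 1 / sqrt(diag(r2m))
    lapply(seq_len(n), function(i) {
      make_cluster(0.5, 0.05, 0.1, 0.05, matrix(1), pvalue = pv[i])
    })
  }
  # two clusters with key r^2 = 0.06: the larger-p one is dropped
  R <- matrix(c(1, sqrt(0.06), sqrt(0.06), 1), 2,
              dimnames = list(c("k1", "k2"), c("k1", "k2")))
  cls <- lapply(1:2, function(i) {
    cl <- make_cluster(0.5, 0.05, 0.1, 0.05, matrix(1),
                       pvalue = c(1e-6, 1e-4)[i])
    cl$a$id <- cl$b$id <- cl$index_id <- cl$key_id <- paste0("k", i)
    cl
  })
  out <- suppressWarnings(trim_clusters(cls, ld_matrix(R, ids = c("k1", "k2"))))
  expect_length(out, 1L)
  expect_equal(out[[1]]$key_id, "k1")

  # random 4-cluster systems vs the enumeration oracle
  for (seed in 1:10) {
    set.seed(seed)
    n <- 4
    L <- matrix(rnorm(n), n, 1)
    S <- tcrossprod(L) + diag(runif(n, 0.05, 1))
    d <- 1 / sqrt(diag(S)); R <- d * S * rep(d, each = n)
    ids <- paste0("k", 1:n)
    pv <- runif(n, 1e-8, 1e-3)
    cls <- lapply(seq_len(n), function(i) {
      cl <- make_cluster(0.5, 0.05, 0.1, 0.05, matrix(1), pvalue = pv[i])
      cl$a$id <- cl$b$id <- cl$index_id <- cl$key_id <- ids[i]
      cl
    })
    ld <- ld_matrix(R, ids = ids)
    out <- suppressWarnings(trim_clusters(cls, ld, r2_max = 0.3))
    orc <- oracle_trim(pv, rep(0, n), R^2, 0.3)
    expect_equal(vapply(out, `[[`, character(1), "key_id"), ids[orc])
    # invariant: all pairwise key r^2 below the ceiling
    if (length(orc) > 1) {
      expect_lt(max((R^2)[orc, orc] - diag(length(orc))), 0.3)
    }
  }
})

test_that("lowering the trim ceiling never increases retained clusters", {
  set.seed(99)
  n <- 6
  L <- matrix(rnorm(2 * n), n, 2)
  S <- tcrossprod(L) + diag(runif(n, 0.05, 1))
  d <- 1 / sqrt(diag(S)); R <- d * S * rep(d, each = n)
  ids <- paste0("k", 1:n)
  cls <- lapply(seq_len(n), function(i) {
    cl <- make_cluster(0.5, 0.05, 0.1, 0.05, matrix(1),
                       pvalue = runif(1, 1e-8, 1e-3))
    cl$a$id <- cl$b$id <- cl$index_id <- cl$key_id <- ids[i]
    cl
  })
  ld <- ld_matrix(R, ids = ids)
  counts <- vapply(c(0.5, 0.2, 0.1, 0.02),
                   function(r2) length(suppressWarnings(trim_clusters(cls, ld, r2))),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("the harmonization pipeline is deterministic", {
  j <- make_toy_locus(10, seed = 21)
  j$a$pvalue <- runif(10)^4
  run <- function() {
    cls <- clump(j, p1 = 0.05)
    lapply(cls, function(cl) collapse_correlated(flip_to_index(cl)))
  }
  expect_identical(run(), run())
})
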