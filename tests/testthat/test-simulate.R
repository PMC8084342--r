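test_that("genotype panels are reproducible and standardized", {
  p1 <- simulate_genotypes(200, 30, seed = 5)
  p2 <- simulate_genotypes(200, 30, seed = 5)
  expect_identical(p1$Z, p2$Z)
  expect_lt(max(abs(colMeans(p1$Z))), 1e-8)
  expect_lt(max(abs(apply(p1$Z, 2, sd) - 1)), 1e-8)
  p3 <- simulate_genotypes(200, 30, seed = 6)
  expect_false(identical(p1$Z, p3$Z))
})

test_that("rho = 0 gives near-independent SNPs", {
  p <- simulate_genotypes(1500, 40, ld_spec = list(rho = 0,
                                                   maf_range = c(0.1, 0.5)),
                          seed = 7)
  r <- cor(p$Z)
  off <- abs(r[upper.tri(r)])
  expect_lt(mean(off), 3 / sqrt(1500))
})

test_that("adjacent-SNP correlation matches a brute-force threshold model", {
  rho <- 0.9; maf <- 0.3
  p <- simulate_genotypes(5000, 2, ld_spec = list(rho = rho,
                                                  maf_range = c(maf, maf)),
                          seed = 8)
  obs_r <- cor(p$Z[, 1], p$Z[, 2])
  # Monte-Carlo oracle: correlate thresholded bivariate normals directly
  set.seed(99)
  n_mc <- 1e6
  x <- rnorm(n_mc)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n_mc)
  thr <- qnorm(1 - maf)
  mc_r <- cor(x > thr, y > thr)  # haplotype allele correlation = dosage correlation
  expect_lt(abs(obs_r - mc_r), 0.02)
})

test_that("marginal summary statistics follow simple-regression algebra", {
  p <- simulate_genotypes(300, 25, seed = 9)
  set.seed(10)
  y <- rnorm(300)
  ss <- marginal_sumstats(p, y, "A")
  ys <- as.vector(scale(y))
  k <- 7
  expect_equal(ss$beta[k], cor(p$Z[, k], ys) * sd(ys) / sd(p$Z[, k]),
               tolerance = 1e-10)
  # y equal to one column: beta 1 and a floored, representable p-value
  ss2 <- marginal_sumstats(p, p$Z[, 3], "A")
  expect_equal(ss2$beta[3], 1, tolerance = 1e-10)
  expect_gt(ss2$pvalue[3], 0)
  expect_lte(ss2$pvalue[3], 1e-200)
})

test_that("null p-values are uniform", {
  p <- simulate_genotypes(400, 500, seed = 11)
  set.seed(12)
  y <- rnorm(400)  # independent of Z
  ss <- marginal_sumstats(p, y, "A")
  # account for LD between SNPs by testing a spaced subset
  keep <- seq(1, 500, by = 10)
  expect_gt(ks.test(ss$pvalue[keep], "punif")$p.value, 0.01)
})

test_that("realized expression heritability concentrates on the target", {
  h2 <- numeric(50)
  for (i in 1:50) {
    p <- simulate_genotypes(500, 50, seed = 7000 + i)
    set.seed(8000 + i)
    n_causal <- 3
    idx <- sample.int(50, n_causal)
    beta <- numeric(50)
    beta[idx] <- rnorm(n_causal, 0, sqrt(0.1 / n_causal))
    ph <- hetmr:::.build_pheno(p$Z, beta, 0.1)
    g <- as.vector(p$Z %*% beta)
    h2[i] <- var(g) / (ph$sd_raw^2)
  }
  expect_lt(abs(mean(h2) - 0.1), 0.01)
})

test_that("study modes wire causal sets and effects as specified", {
  pe <- simulate_genotypes(300, 100, seed = 13)
  pg <- simulate_genotypes(400, 100, seed = 14, maf = pe$target_maf)

  med <- simulate_study(pe, pg, h2g = 0.1, h2med = 0.01, mode = "mediated",
                        seed = 15)
  expect_identical(which(med$truth$beta_gwas != 0), med$truth$causal)
  expect_equal(med$truth$beta_gwas[med$truth$causal],
               sqrt(0.1) * med$truth$beta_eqtl[med$truth$causal],
               tolerance = 1e-12)

  # null: independent effects; correlation across replicates centers at 0
  r <- vapply(1:60, function(i) {
    s <- simulate_study(pe, pg, h2g = 0.1, h2med = 0, mode = "null",
                        seed = 100 + i)
    suppressWarnings(cor(s$truth$beta_eqtl, s$truth$beta_gwas))
  }, numeric(1))
  expect_lt(abs(mean(r, na.rm = TRUE)), 0.05)

  hp <- simulate_study(pe, pg, h2g = 0.1, h2med = 0.01, mode = "hp",
                       seed = 16)
  expect_equal(sum(hp$truth$beta_gwas != 0),
               sum(hp$truth$beta_eqtl != 0) + 3L)
  expect_length(hp$truth$hp_idx, 3L)

  expect_warning(simulate_study(pe, pg, h2g = 0.1, h2med = 0,
                                mode = "mediated", seed = 17),
                 "null semantics")
})

test_that("the true slope satisfies the heritability relationship", {
  pe <- simulate_genotypes(500, 100, seed = 18)
  pg <- simulate_genotypes(2000, 100, seed = 19, maf = pe$target_maf)
  alphas <- vapply(1:20, function(i) {
    s <- simulate_study(pe, pg, h2g = 0.1, h2med = 0.01, mode = "mediated",
                        seed = 200 + i)
    as.numeric(s$truth$alpha)
  }, numeric(1))
  expect_lt(abs(mean(abs(alphas)) - sqrt(0.01 / 0.1)), 0.05)
  # constant-ratio construction holds by assertion inside true_alpha
  s <- simulate_study(pe, pg, mode = "mediated", seed = 21)
  expect_true(attr(true_alpha(s$truth), "defined"))
  s0 <- simulate_study(pe, pg, h2med = 0, mode = "null", seed = 22)
  a0 <- true_alpha(s0$truth)
  expect_equal(as.numeric(a0), 0)
  expect_false(attr(a0, "defined"))
})

test_that("correlated-instrument draws have the designed correlation", {
  sets <- simulate_correlated_instruments(4, 0.05, 1000, seed = 23)
  bA <- t(vapply(sets, function(s) s$beta_a, numeric(4)))
  bB <- t(vapply(sets, function(s) s$beta_b, numeric(4)))
  adj <- mean(c(cor(bA[, 1], bA[, 2]), cor(bA[, 2], bA[, 3]),
                cor(bA[, 3], bA[, 4])))
  expect_lt(abs(adj - sqrt(0.05)), 0.03)
  expect_lt(max(abs(colMeans(bB))), 0.15)     # true slope 0 by construction
  expect_lt(abs(mean(colMeans(bA)) - 10), 0.15)

  sets0 <- simulate_correlated_instruments(4, 0, 1000, seed = 24)
  bA0 <- t(vapply(sets0, function(s) s$beta_a, numeric(4)))
  expect_lt(abs(cor(bA0[, 1], bA0[, 2])), 0.08)
})

test_that("slope-model draws behave as the generating equations dictate", {
  # sigma = 0, tiny SEs: points collinear through the origin
  ins <- simulate_from_slope_model(10, 0.4, 0, 1, 1e-6, 1e-6, seed = 25)
  expect_lt(max(abs(ins$beta_b - 0.4 * ins$beta_a)), 1e-4)
  # large J: WLS slope near truth
  big <- simulate_from_slope_model(200, 0.3, 0.02, 1, 0.02, 0.02, seed = 26)
  wls <- sum(big$beta_a * big$beta_b) / sum(big$beta_a^2)
  expect_lt(abs(wls - 0.3), 0.05)
  expect_identical(simulate_from_slope_model(5, 0.3, 0.1, 1, 0.05, 0.05, seed = 1),
                   simulate_from_slope_model(5, 0.3, 0.1, 1, 0.05, 0.05, seed = 1))
})
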