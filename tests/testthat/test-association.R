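test_that("wald_test matches chi-square tail probabilities", {
  w0 <- wald_test(c(0, 0, 0), diag(3))
  expect_equal(w0$statistic, 0)
  expect_equal(w0$p, 1)
  w1 <- wald_test(c(1, 1, 1), diag(3))
  expect_equal(w1$statistic, 3)
  expect_equal(w1$p, pchisq(3, 3, lower.tail = FALSE))
  expect_equal(w1$p, 0.3916, tolerance = 1e-4)
  w2 <- wald_test(2, matrix(1))
  expect_equal(w2$statistic, 4)
  expect_equal(w2$p, 0.0455, tolerance = 1e-3)
  expect_error(wald_test(c(1, 1), matrix(c(1, 2, 2, 1), 2)),
               "not positive definite")
})

test_that("wald statistic is invariant under joint linear transformation", {
  set.seed(141)
  a <- rnorm(3)
  A <- matrix(rnorm(9), 3); S <- crossprod(A) + diag(0.5, 3)
  M <- matrix(rnorm(9), 3)
  expect_equal(wald_test(as.numeric(M %*% a), M %*% S %*% t(M))$statistic,
               wald_test(a, S)$statistic, tolerance = 1e-10)
})

test_that("t=1 scan equals a dense GLS z-square oracle", {
  co <- sim_cohort(seed = 149, n = 8, m = 40, t_traits = 1, n_chrom = 1,
                   covariates = "sex")
  fr <- co$frame
  # the scan holds the variance components fixed, so pin them to known
  # values rather than relying on a boundary-prone n=8 REML fit
  fit <- fit_mtlmm(fr, max_iter = 5)
  fit$Sigma_u <- matrix(0.8); fit$Sigma_e <- matrix(0.6)
  scan <- multivariate_gwas(fit, co$g)
  # dense oracle: GLS of y on [X w] under V = su K + se I
  V <- as.numeric(fit$Sigma_u) * fr$K + as.numeric(fit$Sigma_e) * diag(8)
  Vi <- solve(V)
  for (r in sample(nrow(scan), 5)) {
    j <- scan$variant[r]
    w <- as.numeric(co$g$calls[match(fr$sample_ids, co$g$sample_ids), j])
    D <- cbind(fr$X, w)
    bb <- solve(t(D) %*% Vi %*% D, t(D) %*% Vi %*% fr$Y)
    vb <- solve(t(D) %*% Vi %*% D)
    z2 <- (bb[ncol(D)]^2) / vb[ncol(D), ncol(D)]
    expect_equal(scan$wald[r], as.numeric(z2), tolerance = 1e-8)
  }
})

test_that("monomorphic SNPs are skipped with a count", {
  co <- sim_cohort(seed = 151, n = 50, m = 30, t_traits = 2, n_chrom = 1)
  g <- co$g
  g$calls[, 5] <- 1L            # no variance
  fit <- fit_mtlmm(co$frame)
  scan <- multivariate_gwas(fit, g)
  expect_false(5 %in% scan$variant)
  expect_gte(attr(scan, "n_skipped"), 1L)
})

test_that("null p-values are calibrated and uniform", {
  co <- sim_cohort(seed = 157, n = 400, m = 2000, t_traits = 3)
  fit <- fit_mtlmm(co$frame)
  scan <- multivariate_gwas(fit, co$g)
  frac <- mean(scan$p < 0.05)
  env <- qbinom(c(0.005, 0.995), nrow(scan), 0.05) / nrow(scan)
  expect_gte(frac, env[1])
  expect_lte(frac, env[2])
  ks <- suppressWarnings(stats::ks.test(scan$p, "punif")$p.value)
  expect_gt(ks, 0.01)
})

test_that("reported effects and covariances reproduce the Wald statistic", {
  co <- sim_cohort(seed = 163, n = 100, m = 50, t_traits = 2, n_chrom = 1)
  fit <- fit_mtlmm(co$frame)
  scan <- multivariate_gwas(fit, co$g)
  cv <- attr(scan, "alpha_cov")
  for (r in c(1, 10, 25)) {
    a <- as.numeric(scan[r, c("beta_T1", "beta_T2")])
    wt <- wald_test(a, cv[, , r])
    expect_equal(wt$statistic, scan$wald[r], tolerance = 1e-8)
    expect_equal(wt$p, scan$p[r], tolerance = 1e-10)
  }
})

test_that("conditional scan drops the lead and collinear SNPs, kills its signal", {
  co <- sim_cohort(seed = 167, n = 400, m = 500, t_traits = 2, n_chrom = 1,
                   qtl = list(list(snp = 250, frac = 0.05)))
  fit <- fit_mtlmm(co$frame)
  scan <- multivariate_gwas(fit, co$g)
  lead <- scan$variant[which.min(scan$p)]
  cond <- conditional_gwas(fit, co$g, lead)
  expect_false(lead %in% cond$variant)
  # duplicate of the lead is dropped as collinear
  g_dup <- co$g
  g_dup$calls[, 1] <- g_dup$calls[, lead]
  cond_dup <- conditional_gwas(fit, g_dup, lead)
  expect_false(1 %in% cond_dup$variant)
  expect_gte(attr(cond_dup, "n_collinear"), 1L)
  # after conditioning on the causal lead, the region behaves like a null
  frac <- mean(cond$p < 0.05)
  env <- qbinom(c(0.005, 0.995), nrow(cond), 0.05) / nrow(cond)
  expect_gte(frac, env[1] - 0.01)
  expect_lte(frac, env[2] + 0.01)
})

test_that("two unlinked causal SNPs: conditioning on one leaves the other", {
  co <- sim_cohort(seed = 173, n = 600, m = 600, t_traits = 2,
                   n_chrom = 2,
                   qtl = list(list(snp = 150, frac = 0.08),
                              list(snp = 450, frac = 0.08)))
  g <- co$g
  expect_lt(ld_r2(g, 150, 450), 0.05)          # different chromosomes
  fit <- fit_mtlmm(co$frame)
  scan <- multivariate_gwas(fit, g)
  # regional Bonferroni: tests on the second QTL's chromosome
  n_region <- sum(g$variants$chrom == g$variants$chrom[450])
  thr <- bonferroni_threshold(0.05, n_region)
  lead1 <- scan$variant[scan$chrom == g$variants$chrom[150]][
    which.min(scan$p[scan$chrom == g$variants$chrom[150]])]
  cond <- conditional_gwas(fit, g, lead1)
  p2 <- cond$p[cond$variant == 450]
  expect_lt(p2, thr)
})

test_that("cluster_qtl merges by distance and finds the lead", {
  rec <- data.frame(variant = 1:4, chrom = c("c1", "c1", "c1", "c2"),
                    pos = c(1e6, 1.2e6, 5e6, 2e6),
                    ref = "A", alt = "G", maf = 0.3,
                    wald = c(30, 40, 35, 1), df = 3,
                    p = c(1e-7, 1e-9, 1e-8, 0.9))
  q <- cluster_qtl(rec, threshold = 1e-5, merge_dist_bp = 1e6)
  expect_equal(nrow(q), 2L)
  expect_equal(q$lead_pos[1], 1.2e6)
  expect_equal(q$start[1], 1e6)
  expect_equal(q$end[1], 1.2e6)
  expect_equal(q$n_snps, c(2L, 1L))

  expect_equal(nrow(cluster_qtl(rec, threshold = 1e-20)), 0L)
  q1 <- cluster_qtl(rec[2, ], threshold = 1e-5)
  expect_equal(q1$start, q1$end)
  expect_equal(q1$lead_variant, 2)
})
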