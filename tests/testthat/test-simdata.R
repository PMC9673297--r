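test_that("generators are reproducible under the seed and respond to it", {
  cfg <- sim_config(seed = 401, n_individuals = 50, n_snps = 100,
                    n_chromosomes = 2)
  g1 <- simulate_genotypes(cfg)
  g2 <- simulate_genotypes(cfg)
  expect_identical(g1$calls, g2$calls)
  expect_identical(g1$variants, g2$variants)
  cfg2 <- sim_config(seed = 402, n_individuals = 50, n_snps = 100,
                     n_chromosomes = 2)
  expect_false(identical(simulate_genotypes(cfg2)$calls, g1$calls))

  ph1 <- simulate_phenotypes(g1, cfg)
  ph2 <- simulate_phenotypes(g1, cfg)
  expect_identical(ph1, ph2)
})

test_that("simulated MAF stays near the configured range", {
  cfg <- sim_config(seed = 409, n_individuals = 1000, n_snps = 300,
                    n_chromosomes = 1, maf_range = c(0.1, 0.5))
  g <- simulate_genotypes(cfg)
  p <- colMeans(g$calls) / 2
  maf <- pmin(p, 1 - p)
  # founder-pool drift widens the range a little; the bulk must stay inside
  expect_gt(mean(maf >= 0.1 - 0.05), 0.95)
  expect_true(all(maf <= 0.5))
})

test_that("frequent founder switching destroys LD", {
  cfg <- sim_config(seed = 419, n_individuals = 400, n_snps = 60,
                    n_chromosomes = 1, switch_rate = 1)
  g <- simulate_genotypes(cfg)
  r2_adj <- vapply(seq_len(59), function(j)
    suppressWarnings(cor(g$calls[, j], g$calls[, j + 1])^2), numeric(1))
  # under independence E[r2] ~ 1/(n-1)
  expect_lt(mean(r2_adj, na.rm = TRUE), 3 / 399)

  cfg_ld <- sim_config(seed = 419, n_individuals = 400, n_snps = 60,
                       n_chromosomes = 1, switch_rate = 0.01)
  g_ld <- simulate_genotypes(cfg_ld)
  r2_ld <- vapply(seq_len(59), function(j)
    suppressWarnings(cor(g_ld$calls[, j], g_ld$calls[, j + 1])^2),
    numeric(1))
  # copying LD is bounded by founder-panel LD (~1/H), so the informative
  # comparison is against the no-LD limit rather than an absolute level
  expect_gt(mean(r2_ld, na.rm = TRUE), 5 * mean(r2_adj, na.rm = TRUE))
})

test_that("noiseless limit returns exactly the fixed effects", {
  cfg <- sim_config(seed = 421, n_individuals = 40, n_snps = 60,
                    n_chromosomes = 1, t_traits = 2,
                    sigma_u = diag(0, 2), sigma_e = diag(0, 2))
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  Xb <- outer(ph$sex, cfg$sex_effects) +
    cfg$house_effects[ph$house, , drop = FALSE]
  expect_equal(unname(as.matrix(ph[, c("T1", "T2")])), unname(Xb),
               tolerance = 1e-12)
})

test_that("breeding values follow Sigma_u and phenotypic variance adds up", {
  cfg <- sim_config(seed = 431, n_individuals = 600, n_snps = 400,
                    n_chromosomes = 1, t_traits = 2)
  g <- simulate_genotypes(cfg)
  covs <- matrix(0, 2, 2)
  vars <- matrix(0, 50, 2)
  for (s in 1:50) {
    cfg_s <- cfg; cfg_s$seed <- 431 + s
    ph <- simulate_phenotypes(g, cfg_s)
    bv <- attr(ph, "breeding_values")
    covs <- covs + cov(bv) / 50
    vars[s, ] <- apply(ph[, c("T1", "T2")], 2, var)
  }
  rel_err <- norm(covs - cfg$sigma_u, "F") / norm(cfg$sigma_u, "F")
  expect_lt(rel_err, 0.15)
  # total variance ~ Sigma_u + Sigma_e + fixed-effect variance
  fx <- 0.25 * cfg$sex_effects^2 + apply(cfg$house_effects, 2, var) *
    (4 / 5)                                     # popn variance of 5 levels
  expected <- diag(cfg$sigma_u) + diag(cfg$sigma_e) + fx
  expect_equal(colMeans(vars), expected, tolerance = 0.15,
               ignore_attr = TRUE)
})

test_that("injected QTL carry the requested variance fraction", {
  cfg <- sim_config(seed = 439, n_individuals = 800, n_snps = 200,
                    n_chromosomes = 1, t_traits = 2,
                    qtl = list(list(snp = 100, frac = 0.10)))
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  beta <- attr(ph, "qtl_beta")[[1]]
  w <- g$calls[, 100]
  frac <- var(w) * beta^2 /
    (diag(cfg$sigma_u) + diag(cfg$sigma_e) + var(w) * beta^2)
  expect_equal(unname(frac), c(0.10, 0.10), tolerance = 0.05)
})

test_that("dosage model: prior at zero depth, truth at extreme depth, bounded", {
  cfg <- sim_config(seed = 443, n_individuals = 30, n_snps = 50,
                    n_chromosomes = 1)
  g <- simulate_genotypes(cfg)
  d0 <- simulate_lcs_dosages(g, depth = 0, seed = 1)
  expect_true(all(attr(d0, "n_reads") == 0))
  pf <- attr(d0, "prior_freq")
  expect_equal(unname(d0$dosages[1, ]), unname(2 * pf), tolerance = 1e-10)

  dInf <- simulate_lcs_dosages(g, depth = 1000, base_error = 0,
                               seed = 1)
  expect_equal(unname(dInf$dosages), unname(g$calls + 0), tolerance = 1e-6)

  d1 <- simulate_lcs_dosages(g, depth = 0.5, seed = 2)
  expect_true(all(d1$dosages >= 0 & d1$dosages <= 2))
  expect_true(all(abs(d1$gp[[1]] + d1$gp[[2]] + d1$gp[[3]] - 1) < 1e-6))
})

test_that("a simulated dataset round-trips through disk", {
  cfg <- sim_config(seed = 449, n_individuals = 12, n_snps = 25,
                    n_chromosomes = 1)
  g <- simulate_genotypes(cfg)
  dos <- simulate_lcs_dosages(g, depth = 1, seed = 3)
  ph <- simulate_phenotypes(g, cfg)
  dir <- tempfile()
  write_sim_dataset(g, dos, ph, cfg, dir)
  g2 <- read_genotypes(file.path(dir, "truth.vcf"), "GT")
  expect_equal(unname(g2$calls), unname(g$calls))
  d2 <- read_genotypes(file.path(dir, "imputed.vcf"), "DS")
  expect_equal(unname(d2$dosages), unname(dos$dosages), tolerance = 1e-5)
  ph2 <- utils::read.delim(file.path(dir, "phenotypes.tsv"))
  expect_equal(ph2$T1, ph$T1, tolerance = 1e-10)
  expect_true(file.exists(file.path(dir, "config.yaml")))
})
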