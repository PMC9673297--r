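test_that("site matching requires identical chrom, pos, ref and alt", {
  tv <- data.frame(chrom = "chr1", pos = c(100L, 200L, 300L),
                   ref = c("A", "A", "G"), alt = c("G", "G", "A"))
  sv <- data.frame(chrom = "chr1", pos = c(100L, 200L, 400L),
                   ref = c("A", "G", "C"), alt = c("G", "A", "T"))
  m <- match_sites(tv, sv)
  expect_equal(nrow(m$pairs), 1L)            # pos 200 has ref/alt swapped
  expect_equal(unname(m$pairs[1, ]), c(1L, 1L))
  expect_equal(m$n_truth_only, 2L)
  expect_equal(m$n_test_only, 2L)

  m2 <- match_sites(tv[1, ], data.frame(chrom = "chr2", pos = 100L,
                                        ref = "A", alt = "G"))
  expect_equal(nrow(m2$pairs), 0L)
  m3 <- match_sites(rbind(tv[1, ], tv[1, ]), sv)
  expect_equal(m3$n_dup_truth, 1L)
})

test_that("genotype concordance counts exact hard-call matches", {
  truth <- toy_geno(cbind(c(0L, 1L, 1L, 2L), c(0L, 1L, 0L, 2L)))
  gc0 <- genotype_concordance(truth, truth)
  expect_equal(gc0$per_site$gc, c(1, 1))
  expect_equal(gc0$mean_gc, 1)

  test1 <- toy_geno(cbind(c(0L, 1L, 2L, 2L), c(0L, 1L, 0L, 2L)))
  gc1 <- genotype_concordance(truth, test1)
  expect_equal(gc1$per_site$gc, c(0.75, 1))

  truth_na <- toy_geno(cbind(c(0L, NA)))
  test_na <- toy_geno(cbind(c(0L, 0L)))
  expect_equal(genotype_concordance(truth_na, test_na)$mean_gc, 1.0)
})

test_that("hard-calling uses GP argmax with het ties, else rounded dosage", {
  truth <- toy_geno(cbind(c(0L, 1L, 2L)))
  gp <- list(matrix(c(0.5, 0.2, 0.0)), matrix(c(0.5, 0.6, 0.1)),
             matrix(c(0.0, 0.2, 0.9)))
  d <- toy_dosage(matrix(gp[[2]] + 2 * gp[[3]]), gp = gp)
  gc <- genotype_concordance(truth, d)
  expect_equal(gc$per_site$gc, 2 / 3)          # tie at sample 1 -> het
  truth2 <- toy_geno(cbind(c(0L, 0L, 2L)))
  d2 <- toy_dosage(matrix(c(0.4, 0.5, 1.9)))
  gc2 <- genotype_concordance(truth2, d2)
  expect_equal(gc2$per_site$gc, 2 / 3)         # exact 0.5 rounds up to het
})

test_that("genotype accuracy is the per-site dosage-truth correlation", {
  truth <- toy_geno(cbind(c(0L, 1L, 2L, 1L), c(2L, 1L, 0L, 1L),
                          c(0L, 1L, 2L, 0L)))
  exact <- toy_dosage(matrix(as.double(truth$calls), 4, 3))
  expect_equal(genotype_accuracy(truth, exact)$mean_ga, 1.0)

  anti <- toy_dosage(2 - matrix(as.double(truth$calls), 4, 3))
  expect_equal(genotype_accuracy(truth, anti)$mean_ga, -1.0)

  flat <- toy_dosage(matrix(c(1, 1, 1, 1, 0, 1, 2, 1, 0, 1, 2, 0), 4, 3))
  ga <- genotype_accuracy(truth, flat)
  expect_equal(ga$n_sites_skipped, 1L)         # constant dosage column
  expect_equal(nrow(ga$per_site), 3L)
})

test_that("MAF bins are half-open on truth-set MAF and aggregate correctly", {
  calls <- cbind(c(rep(0L, 17), 1L, 1L, 1L),     # MAF 0.075
                 c(rep(0L, 19), 1L))             # MAF 0.025
  truth <- toy_geno(calls)
  test <- toy_geno(calls)
  gc <- genotype_concordance(truth, test)
  b <- binned_metrics(truth, gc = gc)
  expect_equal(b$n_sites[b$bin_lo == 0], 1L)
  expect_equal(b$n_sites[b$bin_lo == 0.05], 1L)
  expect_equal(sum(b$n_sites), 2L)
  # overall mean equals the site-count-weighted mean of bin means
  ok <- b$n_sites > 0
  expect_equal(sum(b$mean_gc[ok] * b$n_sites[ok]) / sum(b$n_sites[ok]),
               gc$mean_gc)
})

test_that("weighted bin identity holds on heterogeneous simulated data", {
  cfg <- sim_config(seed = 41, n_individuals = 60, n_snps = 120,
                    n_chromosomes = 1)
  g <- simulate_genotypes(cfg)
  dos <- simulate_lcs_dosages(g, depth = 1, seed = 41)
  gc <- genotype_concordance(g, dos)
  ga <- genotype_accuracy(g, dos)
  b <- binned_metrics(g, gc = gc, ga = ga)
  ok <- b$n_sites > 0 & !is.na(b$mean_gc)
  expect_equal(sum(b$mean_gc[ok] * b$n_sites[ok]) / sum(b$n_sites[ok]),
               gc$mean_gc, tolerance = 1e-10)
})

test_that("design-grid evaluation reproduces single-cell metrics", {
  cfg <- sim_config(seed = 43, n_individuals = 50, n_snps = 80,
                    n_chromosomes = 1)
  g <- simulate_genotypes(cfg)
  dos <- simulate_lcs_dosages(g, depth = 2, seed = 43)
  grid <- evaluate_design_grid(g, list(list(sample_size = 50, depth = 2,
                                            data = dos)))
  expect_equal(nrow(grid), 1L)
  expect_equal(grid$mean_gc, genotype_concordance(g, dos)$mean_gc)
  expect_equal(grid$mean_ga, genotype_accuracy(g, dos)$mean_ga)
  expect_equal(nrow(evaluate_design_grid(g, list())), 0L)
})

test_that("metrics are invariant to sample and site ordering", {
  cfg <- sim_config(seed = 47, n_individuals = 40, n_snps = 60,
                    n_chromosomes = 1)
  g <- simulate_genotypes(cfg)
  dos <- simulate_lcs_dosages(g, depth = 1, seed = 47)
  perm <- sample(seq_len(40))
  g_p <- subset_variants(g, sample_idx = perm)
  dos_p <- subset_variants(dos, sample_idx = perm)
  expect_equal(genotype_concordance(g_p, dos_p)$mean_gc,
               genotype_concordance(g, dos)$mean_gc)
  expect_equal(genotype_accuracy(g_p, dos_p)$mean_ga,
               genotype_accuracy(g, dos)$mean_ga)
})
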