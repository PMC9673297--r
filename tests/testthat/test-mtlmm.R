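test_that("model frame drops incomplete cases and aligns the GRM by id", {
  co <- sim_cohort(seed = 101, n = 40, m = 200, t_traits = 2)
  ph <- co$ph; K <- attr(co$ph, "grm")
  ph$T1[3] <- NA
  fr <- build_model_frame(ph, K, c("T1", "T2"))
  expect_equal(nrow(fr$Y), 39L)
  expect_equal(fr$n_dropped, 1L)
  expect_equal(dim(fr$K), c(39L, 39L))
  expect_equal(fr$K, K$K[-3, -3])

  # shuffled phenotype rows give the same frame after id alignment
  perm <- sample(nrow(ph))
  fr2 <- build_model_frame(ph[perm, ], K, c("T1", "T2"))
  o <- match(fr$sample_ids, fr2$sample_ids)
  expect_equal(fr2$Y[o, ], fr$Y)
  expect_equal(fr2$K[o, o], fr$K)
})

test_that("degenerate covariates are handled: single level dropped, rank checked", {
  co <- sim_cohort(seed = 103, n = 30, m = 150, t_traits = 2)
  ph <- co$ph
  ph$house <- 1L
  expect_warning(fr <- build_model_frame(ph, attr(co$ph, "grm"),
                                         c("T1", "T2")),
                 "single level")
  expect_equal(colnames(fr$X), c("(Intercept)", "sex"))
  ph2 <- co$ph
  ph2$dup <- ph2$sex
  expect_error(build_model_frame(ph2, attr(co$ph, "grm"), c("T1", "T2"),
                                 covariate_columns = c("sex", "house", "dup")),
               "rank deficient")
})

test_that("rotated REML objective equals the dense-matrix oracle", {
  co <- sim_cohort(seed = 107, n = 6, m = 60, t_traits = 2, n_chrom = 1,
                   covariates = "sex")
  fr <- co$frame
  for (s in 1:3) {
    set.seed(s)
    A <- matrix(rnorm(4), 2); Su <- crossprod(A) + diag(0.1, 2)
    B <- matrix(rnorm(4), 2); Se <- crossprod(B) + diag(0.3, 2)
    expect_equal(mtlmm_loglik(fr, Su, Se), dense_reml_loglik(fr, Su, Se),
                 tolerance = 1e-8)
  }
  # t = 1 degenerate case
  fr1 <- build_model_frame(co$ph, attr(co$ph, "grm"), "T1",
                           covariate_columns = "sex",
                           factor_covariates = character(0))
  expect_equal(mtlmm_loglik(fr1, matrix(0.7), matrix(1.2)),
               dense_reml_loglik(fr1, matrix(0.7), matrix(1.2)),
               tolerance = 1e-8)
})

test_that("the fitted maximum dominates nearby component values", {
  co <- sim_cohort(seed = 109, n = 120, m = 400, t_traits = 2)
  fit <- fit_mtlmm(co$frame)
  expect_true(fit$converged)
  ll0 <- mtlmm_loglik(co$frame, fit$Sigma_u, fit$Sigma_e)
  expect_equal(ll0, fit$loglik, tolerance = 1e-6)
  for (s in 1:4) {
    set.seed(s)
    J <- matrix(rnorm(4, sd = 0.05), 2); J <- (J + t(J)) / 2
    ll <- try(mtlmm_loglik(co$frame, fit$Sigma_u + J, fit$Sigma_e + J),
              silent = TRUE)
    if (!inherits(ll, "try-error")) expect_lte(ll, ll0 + 1e-6)
  }
})

test_that("pure-residual data give near-zero heritability", {
  cfg <- sim_config(seed = 113, n_individuals = 300, n_snps = 800,
                    n_chromosomes = 2, t_traits = 2,
                    sigma_u = diag(1e-12, 2), sigma_e = diag(1, 2))
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  fr <- build_model_frame(ph, attr(ph, "grm"), c("T1", "T2"))
  fit <- fit_mtlmm(fr)
  expect_true(all(fit$h2 < 0.05))
})

test_that("an identity-like GRM triggers the identifiability warning", {
  n <- 40
  K_id <- structure(list(K = diag(n), denominator = 1, n_snps_used = 100,
                         sample_ids = sprintf("ind%04d", 1:n),
                         freq_convention = "alt"), class = "grm")
  co <- sim_cohort(seed = 127, n = n, m = 100, t_traits = 2)
  fr <- build_model_frame(co$ph, K_id, c("T1", "T2"))
  expect_warning(fit <- fit_mtlmm(fr, max_iter = 30), "identified")
  expect_false(fit$identifiable)
})

test_that("estimates are invariant to individual reordering and equivariant to scaling", {
  co <- sim_cohort(seed = 131, n = 100, m = 300, t_traits = 2)
  fit <- fit_mtlmm(co$frame)
  perm <- sample(nrow(co$ph))
  fr_p <- build_model_frame(co$ph[perm, ], attr(co$ph, "grm"),
                            c("T1", "T2"))
  fit_p <- fit_mtlmm(fr_p)
  expect_equal(fit_p$Sigma_u, fit$Sigma_u, tolerance = 1e-4)
  expect_equal(fit_p$loglik, fit$loglik, tolerance = 1e-6)

  ph_s <- co$ph; ph_s$T2 <- ph_s$T2 * 3
  fr_s <- build_model_frame(ph_s, attr(co$ph, "grm"), c("T1", "T2"))
  fit_s <- fit_mtlmm(fr_s)
  S <- diag(c(1, 3))
  expect_equal(unname(fit_s$Sigma_u), unname(S %*% fit$Sigma_u %*% S),
               tolerance = 0.02)
  expect_equal(fit_s$h2, fit$h2, tolerance = 0.01)
})

test_that("heritability ratios follow the variance components", {
  vc <- list(Sigma_u = diag(c(1, 0, 2)), Sigma_e = diag(c(3, 1, 2)))
  expect_equal(heritability_from_vc(vc), c(0.25, 0, 0.5))
  expect_equal(heritability_from_vc(vc, 2), 0)
  expect_error(heritability_from_vc(list(Sigma_u = matrix(0),
                                         Sigma_e = matrix(0))),
               "undefined")
})

test_that("fit methods expose coefficients, likelihood and residuals", {
  co <- sim_cohort(seed = 137, n = 80, m = 200, t_traits = 2)
  fit <- fit_mtlmm(co$frame)
  expect_equal(dim(coef(fit)), c(ncol(co$frame$X), 2L))
  expect_s3_class(logLik(fit), "logLik")
  expect_equal(dim(residuals(fit)), dim(co$frame$Y))
  expect_equal(fitted(fit) + residuals(fit), co$frame$Y,
               ignore_attr = TRUE)
  expect_output(print(summary(fit)), "Heritability")
})
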