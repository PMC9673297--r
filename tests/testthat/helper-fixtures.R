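# Small constructors used across the test files.

# geno_matrix from a samples x variants matrix of calls, positions optional
toy_geno <- function(calls, pos = NULL, chrom = NULL, info = NA_real_) {
  calls <- as.matrix(calls)
  m <- ncol(calls)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  geno_matrix(calls,
              data.frame(chrom = chrom, pos = pos,
                         ref = rep("A", m), alt = rep("G", m),
                         info_score = rep(info, length.out = m)))
}

toy_dosage <- function(dosages, pos = NULL, chrom = NULL, gp = NULL) {
  dosages <- as.matrix(dosages)
  m <- ncol(dosages)
  if (is.null(pos)) pos <- seq_len(m) * 1000L
  if (is.null(chrom)) chrom <- rep("chr1", m)
  dosage_matrix(dosages,
                data.frame(chrom = chrom, pos = pos,
                           ref = rep("A", m), alt = rep("G", m),
                           info_score = NA_real_),
                gp = gp)
}

# a simulated cohort (genotypes + phenotypes + model frame), memoised per
# call signature so several tests can share one dataset
sim_cohort <- function(seed, n = 300, m = 1000, t_traits = 3, n_chrom = 2,
                       qtl = list(), sigma_u = NULL, sigma_e = NULL,
                       switch_rate = 0.01,
                       covariates = c("sex", "house")) {
  cfg <- sim_config(seed = seed, n_individuals = n, n_snps = m,
                    n_chromosomes = n_chrom, t_traits = t_traits,
                    qtl = qtl, sigma_u = sigma_u, sigma_e = sigma_e,
                    switch_rate = switch_rate)
  g <- simulate_genotypes(cfg)
  ph <- simulate_phenotypes(g, cfg)
  fr <- build_model_frame(ph, attr(ph, "grm"),
                          paste0("T", seq_len(t_traits)),
                          covariate_columns = covariates,
                          factor_covariates = intersect("house", covariates))
  list(cfg = cfg, g = g, ph = ph, frame = fr)
}

# index of a common, well-tagged SNP near the middle of chromosome 1
pick_common_snp <- function(g, maf_min = 0.2) {
  p <- colMeans(g$calls, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  mid <- stats::median(g$variants$pos[g$variants$chrom == "chr1"])
  cand <- which(g$variants$chrom == "chr1" & maf > maf_min)
  cand[order(abs(g$variants$pos[cand] - mid))][1]
}

# dense-matrix REML log-likelihood: the brute-force oracle used against the
# rotated block computation (explicit (tn x tn) covariance and projection)
dense_reml_loglik <- function(frame, Sigma_u, Sigma_e) {
  n <- nrow(frame$Y); t_ <- ncol(frame$Y)
  V <- kronecker(Sigma_u, frame$K) + kronecker(Sigma_e, diag(n))
  X <- kronecker(diag(t_), frame$X)
  y <- as.vector(frame$Y)
  Vi <- solve(V)
  XtVX <- t(X) %*% Vi %*% X
  P <- Vi - Vi %*% X %*% solve(XtVX) %*% t(X) %*% Vi
  as.numeric(-0.5 * ((n * t_ - ncol(X)) * log(2 * pi) +
                       determinant(V)$modulus +
                       determinant(XtVX)$modulus +
                       t(y) %*% P %*% y))
}
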