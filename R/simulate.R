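#' Configuration for the synthetic cohort generator
#'
#' Bundles every knob of the generator with defaults emulating the study
#' population the analysis pipeline targets: roughly 600 diploid
#' individuals from one cohort, raised in 5 houses with both sexes,
#' genotyped at biallelic SNPs whose MAF lies mostly in `[0.05, 0.5]`,
#' with distance-decaying LD produced by haplotype copying from a founder
#' pool, traits measured at 3 time points with moderate heritability and
#' positive genetic correlation, and optional injected QTL explaining a
#' few percent of phenotypic variance each.
#'
#' @param seed RNG seed; every generator consumes it reproducibly.
#' @param n_individuals number of diploid individuals.
#' @param n_snps total SNP count, split evenly across chromosomes.
#' @param n_chromosomes number of chromosomes.
#' @param chrom_length_bp chromosome length; positions are sorted uniform
#'   draws within it.
#' @param n_founder_haplotypes size of the founder haplotype pool.
#' @param switch_rate per-SNP probability that the copying process jumps
#'   to a random founder (smaller = longer LD blocks).
#' @param maf_range range of founder allele frequencies.
#' @param t_traits number of traits (time points).
#' @param sigma_u,sigma_e t x t genetic and residual covariance matrices;
#'   defaults give per-trait `h2 = 0.3` on unit phenotypic variance with
#'   genetic correlation 0.5 and residual correlation 0.2.
#' @param sex_effects per-trait additive effect of sex (level 1 vs 0).
#' @param house_effects `n_houses x t` matrix of house effects.
#' @param n_houses number of houses.
#' @param qtl list of injected QTL, each a list with `snp` (variant index)
#'   and `frac` (per-trait fraction of phenotypic variance, recycled).
#' @param depth mean sequencing depth (reads per site) for the
#'   low-coverage model.
#' @param base_error per-read base miscall probability.
#' @return list of class `"sim_config"`.
#' @export
sim_config <- function(seed = 1, n_individuals = 600, n_snps = 2000,
                       n_chromosomes = 2, chrom_length_bp = 5e7,
                       n_founder_haplotypes = 20, switch_rate = 0.01,
                       maf_range = c(0.05, 0.5), t_traits = 3,
                       sigma_u = NULL, sigma_e = NULL,
                       sex_effects = rep(0.5, t_traits),
                       house_effects = NULL, n_houses = 5,
                       qtl = list(), depth = 1.0, base_error = 0.01) {
  t_ <- t_traits
  if (is.null(sigma_u)) {
    sigma_u <- 0.3 * (0.5 + 0.5 * diag(t_))        # h2 0.3, rg 0.5
  }
  if (is.null(sigma_e)) {
    sigma_e <- 0.7 * (0.2 + 0.8 * diag(t_))        # residual corr 0.2
  }
  if (is.null(house_effects)) {
    house_effects <- matrix(rep(seq(-0.3, 0.3, length.out = n_houses), t_),
                            n_houses, t_)
  }
  stopifnot(depth >= 0, base_error >= 0, base_error < 0.5,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            nrow(as.matrix(sigma_u)) == t_, nrow(as.matrix(sigma_e)) == t_)
  frac_tot <- rep(0, t_)
  for (q in qtl) frac_tot <- frac_tot + rep(q$frac, length.out = t_)
  if (any(frac_tot >= 1))
    stop("QTL variance fractions must total below 1 per trait")
  structure(list(seed = seed, n_individuals = n_individuals, n_snps = n_snps,
                 n_chromosomes = n_chromosomes,
                 chrom_length_bp = chrom_length_bp,
                 n_founder_haplotypes = n_founder_haplotypes,
                 switch_rate = switch_rate, maf_range = maf_range,
                 t_traits = t_, sigma_u = as.matrix(sigma_u),
                 sigma_e = as.matrix(sigma_e), sex_effects = sex_effects,
                 house_effects = house_effects, n_houses = n_houses,
                 qtl = qtl, depth = depth, base_error = base_error),
            class = "sim_config")
}

#' Simulate genotypes with distance-decaying LD
#'
#' Founder haplotypes are drawn per site with alternate-allele frequency
#' uniform in `maf_range`; each individual haplotype is generated by a
#' Markov copying process over the founder pool (switching to a random
#' founder with probability `switch_rate` at each SNP step, restarting at
#' chromosome boundaries), and diploid genotypes are the sum of two
#' haplotypes. Copying produces LD that decays with inter-SNP distance at
#' a rate set by `switch_rate`.
#'
#' @param cfg a `"sim_config"`.
#' @return a [geno_matrix()]; attribute `haplotypes` holds the
#'   `2n x m` haplotype matrix and attribute `founder_freq` the founder
#'   allele frequencies.
#' @export
simulate_genotypes <- function(cfg) {
  set.seed(cfg$seed)
  n <- cfg$n_individuals
  m_per <- rep(cfg$n_snps %/% cfg$n_chromosomes, cfg$n_chromosomes)
  m_per[seq_len(cfg$n_snps %% cfg$n_chromosomes)] <-
    m_per[seq_len(cfg$n_snps %% cfg$n_chromosomes)] + 1L
  H <- cfg$n_founder_haplotypes
  bases <- c("A", "C", "G", "T")
  hap <- matrix(0L, 2L * n, 0L)
  vlist <- list(); freq_all <- numeric(0)
  for (chr in seq_len(cfg$n_chromosomes)) {
    m <- m_per[chr]
    pos <- sort(sample.int(cfg$chrom_length_bp, m))
    freq <- stats::runif(m, cfg$maf_range[1], cfg$maf_range[2])
    founders <- matrix(stats::rbinom(H * m, 1L, rep(freq, each = H)), H, m)
    # founder index path per haplotype: piecewise constant between switches
    switch <- matrix(stats::runif(2L * n * m) < cfg$switch_rate, 2L * n, m)
    switch[, 1L] <- TRUE
    draw <- matrix(sample.int(H, 2L * n * m, replace = TRUE), 2L * n, m)
    path <- draw
    for (s in 2:m) {
      stay <- !switch[, s]
      path[stay, s] <- path[stay, s - 1L]
    }
    hap_chr <- matrix(founders[cbind(as.vector(path),
                                     rep(seq_len(m), each = 2L * n))],
                      2L * n, m)
    hap <- cbind(hap, hap_chr)
    freq_all <- c(freq_all, freq)
    ra <- t(vapply(seq_len(m), function(j) sample(bases, 2L), character(2)))
    vlist[[chr]] <- data.frame(chrom = paste0("chr", chr), pos = pos,
                               ref = ra[, 1], alt = ra[, 2],
                               info_score = NA_real_,
                               stringsAsFactors = FALSE)
  }
  variants <- do.call(rbind, vlist)
  calls <- hap[seq_len(n) * 2L - 1L, , drop = FALSE] +
    hap[seq_len(n) * 2L, , drop = FALSE]
  g <- geno_matrix(calls, variants, sprintf("ind%04d", seq_len(n)))
  attr(g, "haplotypes") <- hap
  attr(g, "founder_freq") <- freq_all
  g
}

#' Simulate multi-trait phenotypes from genotypes
#'
#' Generates `y = X b + QTL + u + e` with `u ~ N(0, Sigma_u (x) K)` (via
#' matrix square roots of `Sigma_u` and of the VanRaden GRM of `g`),
#' `e ~ N(0, Sigma_e (x) I)`, sex and house fixed effects, and injected
#' QTL whose per-trait effect sizes are solved from the requested
#' phenotypic-variance fractions via `2 p (1 - p) beta^2 = frac * V_ph`,
#' where `V_ph` is the phenotypic variance implied by the configuration
#' (`Sigma_u + Sigma_e` scaled up so the QTL fractions are fractions of
#' the total).
#'
#' @param g a `geno_matrix` from [simulate_genotypes()].
#' @param cfg the `"sim_config"` used (its `seed` offsets the phenotype
#'   stream so genotypes and phenotypes are independently reproducible).
#' @return data.frame with `sample_id`, `sex` (0/1), `house` (1..H) and
#'   one column per trait (`T1`, ..). Attributes: `breeding_values`
#'   (n x t), `qtl_beta` (per-QTL per-trait effect sizes), `grm`.
#' @export
simulate_phenotypes <- function(g, cfg) {
  set.seed(cfg$seed + 1000003L)
  n <- n_samples(g); t_ <- cfg$t_traits
  sex <- stats::rbinom(n, 1L, 0.5)
  house <- sample.int(cfg$n_houses, n, replace = TRUE)
  Xb <- outer(sex, cfg$sex_effects) + cfg$house_effects[house, , drop = FALSE]

  frac_tot <- rep(0, t_)
  for (q in cfg$qtl) frac_tot <- frac_tot + rep(q$frac, length.out = t_)
  v_polygenic <- diag(cfg$sigma_u) + diag(cfg$sigma_e)
  v_total <- v_polygenic / (1 - frac_tot)

  qtl_effect <- matrix(0, n, t_)
  qtl_beta <- list()
  K <- vanraden_grm(g)
  for (qi in seq_along(cfg$qtl)) {
    q <- cfg$qtl[[qi]]
    frac <- rep(q$frac, length.out = t_)
    w <- as.numeric(g$calls[, q$snp])
    p <- mean(w) / 2
    if (p <= 0 || p >= 1) stop("QTL SNP ", q$snp, " is monomorphic")
    beta <- sqrt(frac * v_total / (2 * p * (1 - p)))
    qtl_effect <- qtl_effect + outer(w - 2 * p, beta)
    qtl_beta[[qi]] <- beta
  }

  eK <- eigen(K$K, symmetric = TRUE)
  Ksq <- eK$vectors %*% (sqrt(pmax(eK$values, 0)) * t(eK$vectors))
  Lu <- .mat_sqrt(cfg$sigma_u)
  Le <- .mat_sqrt(cfg$sigma_e)
  U_bv <- Ksq %*% matrix(stats::rnorm(n * t_), n, t_) %*% t(Lu)
  E <- matrix(stats::rnorm(n * t_), n, t_) %*% t(Le)
  Y <- Xb + qtl_effect + U_bv + E
  colnames(Y) <- paste0("T", seq_len(t_))
  ph <- data.frame(sample_id = g$sample_ids, sex = sex, house = house, Y,
                   stringsAsFactors = FALSE)
  attr(ph, "breeding_values") <- U_bv
  attr(ph, "qtl_beta") <- qtl_beta
  attr(ph, "grm") <- K
  ph
}

# symmetric PSD square root
.mat_sqrt <- function(S) {
  e <- eigen(as.matrix(S), symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

#' Simulate low-coverage sequencing dosages
#'
#' An idealized genotype-likelihood imputer: per cell, the read count is
#' `Poisson(depth)` and alternate-supporting reads are
#' `Binomial(reads, f)` with `f = (d/2)(1 - e) + (1 - d/2) e` for true
#' dose `d` and base error `e`. The genotype posterior combines the read
#' likelihood with a Hardy-Weinberg prior at the site's empirical allele
#' frequency, and the dosage is the posterior mean. Cells with zero reads
#' return the prior mean and are flagged missing in the `n_reads`
#' attribute.
#'
#' @param g a `geno_matrix` of true genotypes.
#' @param depth mean reads per site.
#' @param base_error per-read miscall probability.
#' @param seed RNG seed.
#' @return a [dosage_matrix()] with genotype-probability triples;
#'   attributes `n_reads` (read counts) and `prior_freq`.
#' @export
simulate_lcs_dosages <- function(g, depth, base_error = 0.01, seed = 1) {
  stopifnot(depth >= 0, base_error >= 0, base_error < 0.5)
  set.seed(seed)
  n <- n_samples(g); m <- n_variants(g)
  truth <- g$calls
  pfrq <- pmin(pmax(colMeans(truth, na.rm = TRUE) / 2, 1e-4), 1 - 1e-4)
  reads <- matrix(stats::rpois(n * m, depth), n, m)
  f_true <- (truth / 2) * (1 - base_error) + (1 - truth / 2) * base_error
  alt <- matrix(stats::rbinom(n * m, as.vector(reads), as.vector(f_true)),
                n, m)
  # genotype posterior under HWE prior at the site frequency
  f_g <- c(base_error, 0.5, 1 - base_error)
  prior <- rbind((1 - pfrq)^2, 2 * pfrq * (1 - pfrq), pfrq^2)   # 3 x m
  ll <- lapply(1:3, function(k)
    matrix(stats::dbinom(as.vector(alt), as.vector(reads), f_g[k],
                         log = TRUE), n, m))
  mx <- pmax(ll[[1]], ll[[2]], ll[[3]])
  post <- lapply(1:3, function(k)
    exp(ll[[k]] - mx) * matrix(prior[k, ], n, m, byrow = TRUE))
  tot <- post[[1]] + post[[2]] + post[[3]]
  gp <- lapply(post, function(x) x / tot)
  ds <- gp[[2]] + 2 * gp[[3]]
  out <- dosage_matrix(ds, g$variants, g$sample_ids, gp = gp)
  attr(out, "n_reads") <- reads
  attr(out, "prior_freq") <- pfrq
  out
}

#' Write a simulated dataset to disk
#'
#' Writes the truth genotypes as a GT VCF, the low-coverage dosages as a
#' DS/GP VCF, the phenotypes as TSV, and the configuration as YAML-like
#' key: value text.
#'
#' @param g truth `geno_matrix`.
#' @param dos `dosage_matrix`.
#' @param ph phenotype data.frame.
#' @param cfg the `"sim_config"`.
#' @param dir output directory (created if absent).
#' @export
write_sim_dataset <- function(g, dos, ph, cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_genotypes(g, file.path(dir, "truth.vcf"))
  write_genotypes(dos, file.path(dir, "imputed.vcf"))
  utils::write.table(ph, file.path(dir, "phenotypes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  scal <- cfg[!vapply(cfg, function(x) is.matrix(x) || is.list(x),
                      logical(1))]
  writeLines(paste0(names(scal), ": ",
                    vapply(scal, function(x) paste(x, collapse = ","),
                           character(1))),
             file.path(dir, "config.yaml"))
  invisible(dir)
}
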