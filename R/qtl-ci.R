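#' Simulation-based drop-log(P) confidence interval for a QTL
#'
#' Estimates a 95% confidence interval for a QTL's location by the
#' drop-log(P) method, extended to the multivariate mixed model. The
#' candidate region is the QTL bounds padded by `region_pad_bp`. The lead
#' SNP's estimated effect vector is removed from the phenotypes; then, for
#' each of `n_sims` simulations, one region SNP is selected (without
#' replacement while the region holds at least `n_sims` SNPs, else with
#' replacement), the lead effect is assigned to it, a local multivariate
#' scan of the region is run with variance components fixed at the null
#' estimates (fixed effects are refit within each scan), and the drop
#' `Delta = -log10(p) of the scan's best SNP minus -log10(p) of the
#' simulated causal SNP` is recorded. The 95th percentile `D` of the drops
#' defines the interval: the span of region SNPs whose observed `-log10(p)`
#' is within `D` of the observed lead.
#'
#' @param fit an `"mtlmm"` null fit.
#' @param genotypes genotype container holding the region SNPs.
#' @param qtl one row of a `"qtl_set"` (or a list with `chrom`, `start`,
#'   `end`, `lead_variant`).
#' @param region_pad_bp padding added to each side of the QTL bounds.
#' @param n_sims number of simulated datasets.
#' @param seed RNG seed; the whole result is reproducible under it.
#' @param percentile percentile of the drop distribution (default 0.95).
#' @return object of class `"drop_logp_ci"`: list with `drops`, `D`,
#'   `ci_start`, `ci_end`, `width` (`end - start + 1`), `lead_variant`,
#'   `lead_pos`, `n_region_snps`, `n_sims`, `seed`, `scan` (the observed
#'   regional scan).
#' @export
drop_logp_ci <- function(fit, genotypes, qtl, region_pad_bp = 1e6,
                         n_sims = 1000, seed = 1, percentile = 0.95) {
  set.seed(seed)
  v <- genotypes$variants
  region <- which(v$chrom == qtl$chrom &
                    v$pos >= qtl$start - region_pad_bp &
                    v$pos <= qtl$end + region_pad_bp)
  lead_local <- match(qtl$lead_variant, region)
  if (is.na(lead_local)) stop("lead SNP is not inside the candidate region")
  if (length(region) < 2L) {
    warning("candidate region has fewer than 2 SNPs; degenerate interval")
    pos <- v$pos[qtl$lead_variant]
    return(structure(list(drops = numeric(0), D = 0,
                          ci_start = pos, ci_end = pos, width = 1L,
                          lead_variant = qtl$lead_variant, lead_pos = pos,
                          n_region_snps = length(region), n_sims = 0L,
                          seed = seed, scan = NULL),
                     class = "drop_logp_ci"))
  }

  idx <- match(fit$frame$sample_ids, genotypes$sample_ids)
  vals <- geno_values(genotypes)[idx, region, drop = FALSE]
  pfrq <- colMeans(vals, na.rm = TRUE) / 2
  nas <- which(is.na(vals))
  if (length(nas)) vals[nas] <- (2 * pfrq)[col(vals)[nas]]

  # observed regional scan and lead effect
  obs <- multivariate_gwas(fit, genotypes, snps = region)
  obs_row <- match(qtl$lead_variant, obs$variant)
  if (is.na(obs_row)) stop("lead SNP was skipped in the regional scan")
  t_ <- ncol(fit$frame$Y)
  alpha_lead <- as.numeric(obs[obs_row, paste0("beta_",
                                               fit$frame$trait_names)])
  # -log10 p via the log-scale tail to survive p-value underflow
  obs_logp <- -stats::pchisq(obs$wald, t_, lower.tail = FALSE,
                             log.p = TRUE) / log(10)
  lead_logp <- obs_logp[obs_row]

  # residual phenotypes: lead effect removed
  w_lead <- vals[, lead_local]
  Y_res <- fit$frame$Y - outer(w_lead, alpha_lead)

  # simulated causal SNPs
  scan_idx <- match(region, obs$variant)        # NA where SNP was skipped
  eligible <- which(!is.na(scan_idx))
  causal <- if (length(eligible) >= n_sims)
    sample(eligible, n_sims, replace = FALSE)
  else sample(eligible, n_sims, replace = TRUE)

  # one rotated scan context; phenotype columns vary per simulation, so all
  # simulated scans share the residualized genotype projections
  ctx <- .scan_context(fit)
  Wtil <- crossprod(ctx$U, vals)
  Yres_til <- crossprod(ctx$U, Y_res)
  alpha_t_lead <- as.numeric(crossprod(ctx$rot$T, alpha_lead)) # T' alpha
  m <- length(region)
  num_base <- den <- matrix(0, m, t_)
  gram <- vector("list", t_)
  for (k in seq_len(t_)) {
    wk <- ctx$rot$W[, k]
    XtW <- crossprod(ctx$Xtil * wk, Wtil)
    Wperp <- Wtil - ctx$Xtil %*% (ctx$rot$Cinv[[k]] %*% XtW)
    den[, k] <- colSums(Wperp^2 * wk)
    yk <- (Yres_til %*% ctx$rot$T)[, k]
    num_base[, k] <- colSums(Wperp * (wk * yk))
    gram[[k]] <- crossprod(Wperp * wk, Wtil)    # m x m
  }
  ok <- rowSums(den <= 1e-12) == 0
  drops <- vapply(seq_len(n_sims), function(s) {
    j <- causal[s]
    wald <- numeric(m)
    for (k in seq_len(t_)) {
      nk <- num_base[, k] + alpha_t_lead[k] * gram[[k]][, j]
      wald <- wald + nk^2 / den[, k]
    }
    wald[!ok] <- NA
    logp <- -stats::pchisq(wald, t_, lower.tail = FALSE, log.p = TRUE) /
      log(10)
    max(logp, na.rm = TRUE) - logp[j]
  }, numeric(1))

  D <- as.numeric(stats::quantile(drops, percentile))
  in_ci <- obs_logp >= lead_logp - D
  ci_start <- min(obs$pos[in_ci]); ci_end <- max(obs$pos[in_ci])
  structure(list(drops = drops, D = D, ci_start = ci_start, ci_end = ci_end,
                 width = ci_end - ci_start + 1L,
                 lead_variant = qtl$lead_variant,
                 lead_pos = v$pos[qtl$lead_variant],
                 n_region_snps = m, n_sims = n_sims, seed = seed,
                 scan = obs),
            class = "drop_logp_ci")
}

#' @export
print.drop_logp_ci <- function(x, ...) {
  cat("drop-log(P) confidence interval\n")
  cat(sprintf("  lead SNP at %s (variant %d)\n",
              format(x$lead_pos, big.mark = ","), x$lead_variant))
  cat(sprintf("  D (%s drops, 95th pct) = %.3f\n", length(x$drops), x$D))
  cat(sprintf("  CI: [%s, %s], width %s bp\n",
              format(x$ci_start, big.mark = ","),
              format(x$ci_end, big.mark = ","),
              format(x$width, big.mark = ",")))
  invisible(x)
}

#' QTL heritability by lead-SNP adjustment
#'
#' Refits the null multi-trait REML model with the lead SNP's genotype as
#' an extra fixed covariate (one coefficient per trait) and reports, per
#' trait, the drop in SNP-based heritability
#' `h2_QTL = h2 - h2_adjusted`, clamped at 0 (a negative drop can arise
#' from sampling noise and is reported as 0 with a warning).
#'
#' @param fit the unadjusted `"mtlmm"` fit.
#' @param genotypes genotype container with the lead SNP.
#' @param lead_snp variant index of the lead SNP.
#' @return list with `h2_qtl` (per trait), `h2` (unadjusted),
#'   `h2_adjusted`, and `fit_adjusted`.
#' @export
qtl_heritability <- function(fit, genotypes, lead_snp) {
  idx <- match(fit$frame$sample_ids, genotypes$sample_ids)
  w <- geno_values(genotypes)[idx, lead_snp]
  if (anyNA(w)) w[is.na(w)] <- mean(w, na.rm = TRUE)
  fit2 <- fit_mtlmm(fit$frame, extra_covariates = cbind(lead = w),
                    start = list(Sigma_u = fit$Sigma_u,
                                 Sigma_e = fit$Sigma_e),
                    max_iter = 1000)
  if (!fit2$converged)
    stop(sprintf(paste0("adjusted REML refit did not converge ",
                        "(logL %.4f vs null %.4f)"), fit2$loglik, fit$loglik))
  h2 <- heritability_from_vc(fit)
  h2a <- heritability_from_vc(fit2)
  h2q <- h2 - h2a
  if (any(h2q < 0)) {
    warning("negative QTL heritability clamped to 0")
    h2q <- pmax(h2q, 0)
  }
  list(h2_qtl = h2q, h2 = h2, h2_adjusted = h2a, fit_adjusted = fit2)
}
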