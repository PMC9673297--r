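#' Wald chi-square test for a multi-trait SNP effect
#'
#' `W = alpha' cov^{-1} alpha`, compared to a chi-square distribution with
#' `df = length(alpha)` degrees of freedom.
#'
#' @param alpha_hat estimated per-trait effect vector.
#' @param cov_alpha its covariance matrix (symmetric positive definite).
#' @return list with `statistic`, `df`, `p`.
#' @export
wald_test <- function(alpha_hat, cov_alpha) {
  cov_alpha <- as.matrix(cov_alpha)
  R <- tryCatch(chol(cov_alpha), error = function(e)
    stop("covariance of the effect vector is not positive definite"))
  z <- backsolve(R, alpha_hat, transpose = TRUE)
  W <- sum(z^2)
  df <- length(alpha_hat)
  list(statistic = W, df = df, p = stats::pchisq(W, df, lower.tail = FALSE))
}

# scan context: per-trait weighted projections at fixed variance components,
# optionally with extra fixed covariates appended to the design
.scan_context <- function(fit, extra = NULL) {
  X <- fit$X
  if (!is.null(extra)) X <- cbind(X, as.matrix(extra))
  Xtil <- crossprod(fit$U, X)
  rot <- .rotated_fit(fit$Ytil, Xtil, fit$lambda, fit$Sigma_u, fit$Sigma_e)
  list(rot = rot, Xtil = Xtil, U = fit$U, lambda = fit$lambda,
       Tinv = solve(rot$T), t_ = ncol(fit$frame$Y),
       trait_names = fit$frame$trait_names)
}

# core GLS scan of rotated genotype columns Wtil (n x m) under a context.
# Returns per-SNP transformed effects/variances and Wald statistics.
.scan_rotated <- function(ctx, Wtil) {
  t_ <- ctx$t_; m <- ncol(Wtil)
  num <- den <- matrix(0, m, t_)
  for (k in seq_len(t_)) {
    wk <- ctx$rot$W[, k]
    XtW <- crossprod(ctx$Xtil * wk, Wtil)            # p x m
    Wperp <- Wtil - ctx$Xtil %*% (ctx$rot$Cinv[[k]] %*% XtW)
    den[, k] <- colSums(Wperp^2 * wk)
    num[, k] <- colSums(Wperp * (wk * ctx$rot$Yhat[, k]))
  }
  ok <- rowSums(den <= 1e-12) == 0
  alpha_t <- num / den
  wald <- rowSums(num^2 / den)
  list(alpha_t = alpha_t, var_t = 1 / den, wald = wald, ok = ok)
}

#' Multivariate mixed-model association scan
#'
#' Tests every SNP for association with all traits jointly: the SNP enters
#' the fitted null model as `t` fixed effects (one per trait), its effect
#' vector is estimated by generalized least squares with the variance
#' components held at the null REML estimates, and significance is the Wald
#' chi-square test on `t` degrees of freedom. Missing genotypes are
#' mean-imputed per SNP; monomorphic SNPs (MAF < 1e-6 among tested samples)
#' and SNPs with a singular effect covariance are skipped and counted.
#'
#' @param fit an `"mtlmm"` null-model fit on the same individuals.
#' @param genotypes a `geno_matrix` or `dosage_matrix`; samples must
#'   include all individuals of the model frame.
#' @param snps optional variant indices to test (default all).
#' @param extra_covariates optional extra fixed covariates (see
#'   [conditional_gwas()]).
#' @return data.frame of class `"assoc_scan"`: `variant`, `chrom`, `pos`,
#'   `ref`, `alt`, `maf`, one `beta_<trait>` column per trait, `wald`,
#'   `df`, `p`. Attribute `n_skipped` counts skipped SNPs; attribute
#'   `alpha_cov` is a `t x t x m` array of effect covariances.
#' @export
multivariate_gwas <- function(fit, genotypes, snps = NULL,
                              extra_covariates = NULL) {
  stopifnot(inherits(fit, "mtlmm"))
  idx <- match(fit$frame$sample_ids, genotypes$sample_ids)
  if (anyNA(idx)) stop("model-frame individuals missing from the genotypes")
  if (is.null(snps)) snps <- seq_len(n_variants(genotypes))
  vals <- geno_values(genotypes)[idx, snps, drop = FALSE]
  p <- colMeans(vals, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  # mean-impute missing genotypes per SNP
  nas <- which(is.na(vals))
  if (length(nas)) vals[nas] <- (2 * p)[col(vals)[nas]]
  testable <- maf >= 1e-6

  ctx <- .scan_context(fit, extra = extra_covariates)
  Wtil <- crossprod(ctx$U, vals)
  sc <- .scan_rotated(ctx, Wtil)
  keep <- testable & sc$ok

  t_ <- ctx$t_
  alpha <- sc$alpha_t %*% ctx$Tinv                  # original trait scale
  colnames(alpha) <- paste0("beta_", ctx$trait_names)
  pval <- stats::pchisq(sc$wald, t_, lower.tail = FALSE)
  out <- data.frame(variant = snps,
                    genotypes$variants[snps, c("chrom", "pos", "ref", "alt")],
                    maf = maf, alpha,
                    wald = sc$wald, df = t_, p = pval,
                    stringsAsFactors = FALSE)
  out[!keep, c(colnames(alpha), "wald", "p")] <- NA
  rownames(out) <- NULL
  cov_arr <- array(NA_real_, c(t_, t_, length(snps)))
  for (j in which(keep))
    cov_arr[, , j] <- crossprod(ctx$Tinv, sc$var_t[j, ] * ctx$Tinv)
  out <- out[keep, , drop = FALSE]
  cov_arr <- cov_arr[, , keep, drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("assoc_scan", "data.frame"),
            n_skipped = sum(!keep), alpha_cov = cov_arr,
            trait_names = ctx$trait_names)
}

#' Conditional association scan given a lead SNP
#'
#' Re-tests every SNP with the lead SNP's genotype included as `t` fixed
#' covariates (one coefficient per trait), to separate signals in LD with
#' the lead from independent ones. The lead SNP itself and SNPs essentially
#' collinear with it (|correlation| > 0.9999) are excluded.
#'
#' @inheritParams multivariate_gwas
#' @param lead_snp variant index of the lead SNP in `genotypes`.
#' @return an `"assoc_scan"` data.frame (see [multivariate_gwas()]);
#'   attribute `n_collinear` counts SNPs dropped for collinearity.
#' @export
conditional_gwas <- function(fit, genotypes, lead_snp, snps = NULL) {
  idx <- match(fit$frame$sample_ids, genotypes$sample_ids)
  if (anyNA(idx)) stop("model-frame individuals missing from the genotypes")
  w_lead <- geno_values(genotypes)[idx, lead_snp]
  if (anyNA(w_lead)) w_lead[is.na(w_lead)] <- mean(w_lead, na.rm = TRUE)
  if (is.null(snps)) snps <- seq_len(n_variants(genotypes))
  snps <- setdiff(snps, lead_snp)
  vals <- geno_values(genotypes)[idx, snps, drop = FALSE]
  cc <- suppressWarnings(as.vector(stats::cor(w_lead, vals,
                                              use = "pairwise.complete.obs")))
  collinear <- !is.na(cc) & abs(cc) > 0.9999
  res <- multivariate_gwas(fit, genotypes, snps = snps[!collinear],
                           extra_covariates = cbind(lead = w_lead))
  attr(res, "n_collinear") <- sum(collinear)
  res
}

#' Cluster significant SNPs into QTL regions
#'
#' Significant SNPs (`p < threshold`) on the same chromosome are merged
#' into one QTL while each lies within `merge_dist_bp` of the running
#' cluster; the lead SNP is the minimum-p member and the region bounds span
#' all members.
#'
#' @param records an `"assoc_scan"` data.frame.
#' @param threshold significance threshold on p.
#' @param merge_dist_bp maximum gap between a significant SNP and the
#'   current cluster.
#' @return data.frame of class `"qtl_set"`: `qtl`, `chrom`, `start`, `end`,
#'   `n_snps`, `lead_variant`, `lead_pos`, `lead_p`; attribute `members`
#'   lists each QTL's member rows of `records`.
#' @export
cluster_qtl <- function(records, threshold, merge_dist_bp = 1e6) {
  sig <- records[!is.na(records$p) & records$p < threshold, , drop = FALSE]
  sig <- sig[order(sig$chrom, sig$pos), , drop = FALSE]
  out <- list(); members <- list()
  if (nrow(sig)) {
    cur <- sig[1, , drop = FALSE]
    flush <- function(cl) {
      lead <- cl[which.min(cl$p), ]
      data.frame(chrom = lead$chrom, start = min(cl$pos), end = max(cl$pos),
                 n_snps = nrow(cl), lead_variant = lead$variant,
                 lead_pos = lead$pos, lead_p = lead$p,
                 stringsAsFactors = FALSE)
    }
    for (i in seq_len(nrow(sig))[-1]) {
      row <- sig[i, , drop = FALSE]
      if (row$chrom == cur$chrom[1] &&
          row$pos - max(cur$pos) <= merge_dist_bp) {
        cur <- rbind(cur, row)
      } else {
        out[[length(out) + 1L]] <- flush(cur)
        members[[length(members) + 1L]] <- cur
        cur <- row
      }
    }
    out[[length(out) + 1L]] <- flush(cur)
    members[[length(members) + 1L]] <- cur
  }
  res <- if (length(out)) cbind(qtl = seq_along(out), do.call(rbind, out))
    else data.frame(qtl = integer(0), chrom = character(0),
                    start = integer(0), end = integer(0), n_snps = integer(0),
                    lead_variant = integer(0), lead_pos = integer(0),
                    lead_p = numeric(0))
  structure(res, class = c("qtl_set", "data.frame"), members = members)
}

#' Manhattan-style plot of an association scan
#' @param x an `"assoc_scan"` data.frame.
#' @param threshold optional genome-wide threshold drawn as a line.
#' @param ... passed to [graphics::plot()].
#' @export
plot.assoc_scan <- function(x, threshold = NULL, ...) {
  chr <- factor(x$chrom, levels = unique(x$chrom))
  offs <- c(0, cumsum(tapply(x$pos, chr, max)))[as.integer(chr)]
  gx <- offs + x$pos
  graphics::plot(gx, -log10(x$p), pch = 20, cex = 0.5,
                 col = c("grey30", "steelblue")[1 + as.integer(chr) %% 2],
                 xlab = "genome position", ylab = expression(-log[10](p)), ...)
  if (!is.null(threshold))
    graphics::abline(h = -log10(threshold), col = "red", lty = 2)
  invisible(x)
}
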