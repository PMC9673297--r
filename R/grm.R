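#' VanRaden genomic relationship matrix
#'
#' Computes `K = W W' / sum(2 p_j (1 - p_j))` where `W` is the centered
#' genotype matrix, `w_ij = m_ij - 2 p_j`. Under the default convention
#' `freq_convention = "alt"`, `p_j` is the alternate-allele frequency
#' (standard VanRaden centering). With `"maf"`, `p_j` is the minor-allele
#' frequency, i.e. the literal `min(p, 1 - p)`; the two only differ at sites
#' where the alternate allele is the major one. The denominator is invariant
#' to the convention; the centering is not.
#'
#' Monomorphic SNPs are excluded (they contribute nothing to `W` and would
#' shrink the denominator spuriously). Missing calls are mean-imputed per
#' SNP (`2 p_j`) before centering, so they contribute exactly 0 to `W`.
#'
#' @param g a `geno_matrix` or `dosage_matrix`.
#' @param freq_convention `"alt"` (default) or `"maf"`.
#' @return object of class `"grm"`: list with `K` (n x n symmetric),
#'   `denominator`, `n_snps_used`, `sample_ids`, `freq_convention`.
#' @export
vanraden_grm <- function(g, freq_convention = c("alt", "maf")) {
  freq_convention <- match.arg(freq_convention)
  vals <- geno_values(g)
  p <- colMeans(vals, na.rm = TRUE) / 2
  poly <- !is.na(p) & p > 0 & p < 1
  if (!any(poly)) stop("all SNPs monomorphic: GRM denominator is zero")
  vals <- vals[, poly, drop = FALSE]
  p <- p[poly]
  ctr <- if (freq_convention == "alt") p else pmin(p, 1 - p)
  W <- sweep(vals, 2, 2 * ctr)
  # mean imputation: missing cells contribute 0 after centering by 2p
  miss <- is.na(W)
  if (any(miss)) {
    if (freq_convention == "alt") W[miss] <- 0
    else W[miss] <- (2 * p - 2 * ctr)[col(W)[miss]]
  }
  denom <- sum(2 * p * (1 - p))
  K <- tcrossprod(W) / denom
  K <- (K + t(K)) / 2
  structure(list(K = K, denominator = denom, n_snps_used = sum(poly),
                 sample_ids = g$sample_ids, freq_convention = freq_convention),
            class = "grm")
}

#' @export
print.grm <- function(x, ...) {
  cat("VanRaden GRM:", nrow(x$K), "individuals,", x$n_snps_used,
      "SNPs used\n")
  cat(sprintf("  denominator sum(2p(1-p)) = %.4f; mean diagonal = %.4f\n",
              x$denominator, mean(diag(x$K))))
  cat("  centering convention:", x$freq_convention, "\n")
  invisible(x)
}

#' Principal components of a GRM
#'
#' Eigendecomposition of the relationship matrix; component scores are
#' eigenvectors scaled by the square root of their eigenvalues, and each
#' component's variance fraction is its eigenvalue over the trace.
#'
#' @param K a `"grm"` object (or bare symmetric matrix).
#' @param n_components number of leading components to return.
#' @return list with `values` (all eigenvalues, descending), `scores`
#'   (n x n_components), `var_fraction` (length `n_components`).
#' @export
grm_pca <- function(K, n_components = 5) {
  M <- if (inherits(K, "grm")) K$K else K
  if (n_components > nrow(M)) stop("more components requested than individuals")
  e <- eigen(M, symmetric = TRUE)
  scores <- e$vectors[, seq_len(n_components), drop = FALSE] %*%
    diag(sqrt(pmax(e$values[seq_len(n_components)], 0)), n_components)
  colnames(scores) <- paste0("PC", seq_len(n_components))
  list(values = e$values, scores = scores,
       var_fraction = e$values[seq_len(n_components)] / sum(e$values))
}
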