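#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of genotype-count vectors over samples that
#' are non-missing at both variants (composite LD; no phase required).
#'
#' @param g a `geno_matrix` or `dosage_matrix`.
#' @param i,j variant column indices.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(g, i, j) {
  v <- geno_values(g)
  ok <- !is.na(v[, i]) & !is.na(v[, j])
  x <- v[ok, i]; y <- v[ok, j]
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("r2 undefined: monomorphic variant among jointly non-missing samples")
  stats::cor(x, y)^2
}

#' Greedy sliding-window LD pruning
#'
#' Deterministic re-statement of PLINK-style `--indep-pairwise` pruning,
#' counted in SNPs: per chromosome, a window of `window_snps` retained
#' variants is examined; while any retained pair within the window has
#' r-squared above `r2_max`, the pair member with the smaller MAF is removed
#' (ties: the one at the larger position); the window then advances by
#' `step_snps`. The removal rule approximates, but does not bit-match, the
#' reference tool, whose tie-breaking is unspecified.
#'
#' Missing calls are excluded pairwise when computing r-squared. Monomorphic
#' variants are removed up front.
#'
#' @param g a `geno_matrix` or `dosage_matrix`.
#' @param window_snps,step_snps window size and step, in SNPs.
#' @param r2_max maximum tolerated pairwise r-squared.
#' @return sorted integer vector of retained variant indices.
#' @export
ld_prune <- function(g, window_snps = 50, step_snps = 5, r2_max = 0.2) {
  stopifnot(window_snps > step_snps, step_snps >= 1)
  vals <- geno_values(g)
  p <- colMeans(vals, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  keep_all <- integer(0)
  for (chr in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chr)
    idx <- idx[maf[idx] > 0]               # monomorphic never retained
    if (!length(idx)) next
    retained <- rep(TRUE, length(idx))
    start <- 1L
    repeat {
      win <- which(retained)
      win <- win[win >= start & win < start + window_snps]
      if (length(win) >= 2L) {
        repeat {
          r2 <- .pair_r2(vals[, idx[win], drop = FALSE])
          worst <- which(r2 > r2_max, arr.ind = TRUE)
          worst <- worst[worst[, 1] < worst[, 2], , drop = FALSE]
          if (!nrow(worst)) break
          # remove the smaller-MAF member of the first offending pair
          # (scan order keeps this deterministic)
          a <- win[worst[1, 1]]; b <- win[worst[1, 2]]
          drop_local <- if (maf[idx[a]] < maf[idx[b]]) a
            else if (maf[idx[b]] < maf[idx[a]]) b
            else if (g$variants$pos[idx[a]] > g$variants$pos[idx[b]]) a else b
          retained[drop_local] <- FALSE
          win <- setdiff(win, drop_local)
          if (length(win) < 2L) break
        }
      }
      start <- start + step_snps
      if (start > length(idx) - 1L) break
    }
    keep_all <- c(keep_all, idx[retained])
  }
  sort(keep_all)
}

# all pairwise r2 of columns, pairwise-complete; diagonal NA
.pair_r2 <- function(m) {
  suppressWarnings(r <- stats::cor(m, use = "pairwise.complete.obs"))
  r2 <- r^2
  diag(r2) <- NA
  r2[is.na(r2)] <- 0
  diag(r2) <- NA
  r2
}

#' Bonferroni genome-wide significance threshold
#'
#' `alpha / n_effective`, with the effective number of tests taken as the
#' number of variants retained by LD pruning.
#'
#' @param alpha family-wise error rate.
#' @param n_effective number of effective (approximately independent) SNPs.
#' @return the per-test significance threshold.
#' @export
bonferroni_threshold <- function(alpha = 0.05, n_effective) {
  stopifnot(alpha > 0, alpha < 1, n_effective >= 1)
  alpha / n_effective
}

#' LD decay curve
#'
#' Mean r-squared of intra-chromosome variant pairs, binned by base-pair
#' distance. Pairs farther apart than `max_dist_bp` are ignored; when a
#' chromosome has more eligible pairs than `max_pairs_per_chrom`, a
#' seed-reproducible subsample is used.
#'
#' @param g a `geno_matrix` or `dosage_matrix`.
#' @param max_dist_bp maximum pair distance considered.
#' @param bin_bp distance bin width.
#' @param max_pairs_per_chrom cap on pairs per chromosome.
#' @param seed RNG seed for pair subsampling.
#' @return data.frame (class `"ld_decay_curve"`) with columns `bin_start`,
#'   `bin_end`, `n_pairs`, `mean_r2`; only non-empty bins are reported.
#' @export
ld_decay_curve <- function(g, max_dist_bp = 1e6, bin_bp = 1000,
                           max_pairs_per_chrom = 50000, seed = 1) {
  vals <- geno_values(g)
  dist_all <- numeric(0); r2_all <- numeric(0)
  if (!is.null(seed)) set.seed(seed)
  for (chr in unique(g$variants$chrom)) {
    idx <- which(g$variants$chrom == chr)
    if (length(idx) < 2L) next
    pos <- g$variants$pos[idx]
    pr <- which(outer(pos, pos, function(a, b) b - a) > 0 &
                outer(pos, pos, function(a, b) b - a) <= max_dist_bp,
                arr.ind = TRUE)
    if (!nrow(pr)) next
    if (nrow(pr) > max_pairs_per_chrom)
      pr <- pr[sample.int(nrow(pr), max_pairs_per_chrom), , drop = FALSE]
    d <- pos[pr[, 2]] - pos[pr[, 1]]
    r2 <- vapply(seq_len(nrow(pr)), function(k) {
      x <- vals[, idx[pr[k, 1]]]; y <- vals[, idx[pr[k, 2]]]
      ok <- !is.na(x) & !is.na(y)
      if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0) return(NA_real_)
      stats::cor(x[ok], y[ok])^2
    }, numeric(1))
    ok <- !is.na(r2)
    dist_all <- c(dist_all, d[ok]); r2_all <- c(r2_all, r2[ok])
  }
  if (!length(dist_all)) {
    warning("no eligible variant pair for the LD decay curve")
    out <- data.frame(bin_start = integer(0), bin_end = integer(0),
                      n_pairs = integer(0), mean_r2 = numeric(0))
  } else {
    bin <- pmin(ceiling(dist_all / bin_bp), ceiling(max_dist_bp / bin_bp))
    agg_n <- tapply(r2_all, bin, length)
    agg_m <- tapply(r2_all, bin, mean)
    b <- as.integer(names(agg_n))
    out <- data.frame(bin_start = (b - 1L) * bin_bp + 1L,
                      bin_end = b * bin_bp,
                      n_pairs = as.integer(agg_n),
                      mean_r2 = as.numeric(agg_m))
    out <- out[order(out$bin_start), ]
    rownames(out) <- NULL
  }
  class(out) <- c("ld_decay_curve", "data.frame")
  out
}
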