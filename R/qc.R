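#' Exact Hardy-Weinberg equilibrium test
#'
#' Exact test of HWE genotype proportions for one biallelic SNP, conditional
#' on the observed allele counts. The p-value is the sum of the conditional
#' probabilities of all heterozygote counts whose probability does not exceed
#' that of the observed count (full enumeration, no mid-p correction) —
#' the convention standard in GWAS quality control.
#'
#' @param n_homref,n_het,n_homalt non-negative genotype counts.
#' @return p-value in `[0, 1]`; monomorphic sites give 1.
#' @export
hwe_exact_test <- function(n_homref, n_het, n_homalt) {
  stopifnot(n_homref >= 0, n_het >= 0, n_homalt >= 0)
  n <- n_homref + n_het + n_homalt
  if (n < 1) stop("need at least one genotyped individual")
  n_a <- 2L * n_homalt + n_het        # minor-agnostic: use rarer allele count
  n_b <- 2L * n_homref + n_het
  n_rare <- min(n_a, n_b)
  if (n_rare == 0L) return(1)
  # enumerate all heterozygote counts with the parity of n_rare
  hets <- seq.int(n_rare %% 2L, n_rare, by = 2L)
  # log P(het = h | allele counts) up to a shared constant:
  #   P(h) ∝ n! / (n_aa! n_ab! n_bb!) * 2^h, with n_ab = h,
  #   n_aa = (n_rare - h)/2, n_bb = n - n_ab - n_aa
  n_aa <- (n_rare - hets) / 2
  n_bb <- n - hets - n_aa
  logp <- hets * log(2) - lfactorial(n_aa) - lfactorial(hets) - lfactorial(n_bb)
  logp <- logp - max(logp)
  prob <- exp(logp) / sum(exp(logp))
  obs <- prob[match(n_het, hets)]
  if (is.na(obs)) stop("observed heterozygote count inconsistent with allele counts")
  min(1, sum(prob[prob <= obs * (1 + 1e-12)]))
}

#' Variant quality control
#'
#' Applies the standard post-imputation variant filters: a variant survives
#' iff MAF > `maf_min`, missing rate < `miss_max`, exact HWE p > `hwe_min`,
#' and (info score absent OR info score > `info_min`). All comparisons are
#' strict. Removal counts attribute each removed variant to its first
#' failing rule in the fixed order MAF, missingness, HWE, info score, so
#' counts are reproducible; which variants survive does not depend on the
#' order.
#'
#' For a `dosage_matrix`, MAF comes from mean dosage and HWE is computed on
#' hard calls obtained by rounding.
#'
#' @param g a `geno_matrix` or `dosage_matrix`.
#' @param maf_min,miss_max,hwe_min,info_min filter thresholds.
#' @return list with `data` (the filtered container), `removed` (named
#'   per-rule counts), `n_removed`, and `report` (data.frame of removed
#'   variants and the rule each failed).
#' @export
qc_filter <- function(g, maf_min = 0.05, miss_max = 0.1, hwe_min = 1e-6,
                      info_min = 0.4) {
  stopifnot(maf_min >= 0, maf_min < 0.5, miss_max >= 0, miss_max <= 1,
            hwe_min >= 0, hwe_min <= 1, info_min >= 0, info_min <= 1)
  vals <- geno_values(g)
  m <- n_variants(g)
  p <- colMeans(vals, na.rm = TRUE) / 2
  maf <- pmin(p, 1 - p)
  miss <- colMeans(is.na(vals))
  hard <- round(vals)
  hwe_p <- vapply(seq_len(m), function(j) {
    h <- hard[, j]; h <- h[!is.na(h)]
    if (!length(h)) return(1)
    hwe_exact_test(sum(h == 0), sum(h == 1), sum(h == 2))
  }, numeric(1))
  info <- g$variants$info_score

  fail_maf <- !(maf > maf_min) | is.na(maf)
  fail_miss <- !(miss < miss_max)
  fail_hwe <- !(hwe_p > hwe_min)
  fail_info <- !is.na(info) & !(info > info_min)

  rule <- rep(NA_character_, m)
  rule[fail_info] <- "info"
  rule[fail_hwe] <- "hwe"
  rule[fail_miss] <- "missing"
  rule[fail_maf] <- "maf"       # earlier rules overwrite: first-failing wins

  keep <- is.na(rule)
  removed <- c(maf = sum(rule == "maf", na.rm = TRUE),
               missing = sum(rule == "missing", na.rm = TRUE),
               hwe = sum(rule == "hwe", na.rm = TRUE),
               info = sum(rule == "info", na.rm = TRUE))
  if (!any(keep)) warning("all variants removed by QC")
  report <- data.frame(g$variants[!keep, c("chrom", "pos", "ref", "alt")],
                       rule_failed = rule[!keep], stringsAsFactors = FALSE)
  rownames(report) <- NULL
  list(data = subset_variants(g, keep), removed = removed,
       n_removed = sum(!keep), report = report)
}

#' Write a QC report (variant, rule failed) as TSV
#' @param qc result of [qc_filter()].
#' @param path output TSV path.
#' @export
write_qc_report <- function(qc, path) {
  utils::write.table(qc$report, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
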