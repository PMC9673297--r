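#' Genotype and dosage containers
#'
#' `geno_matrix()` holds hard diploid calls coded as the number of alternate
#' alleles (0, 1, 2) with `NA` as the missing sentinel; `dosage_matrix()`
#' holds continuous expected alternate-allele counts in `[0, 2]`, optionally
#' with per-cell genotype-probability triples. Both store samples in rows and
#' variants in columns, alongside a variant metadata table.
#'
#' Only biallelic SNPs are representable: `ref` and `alt` are single bases
#' and differ, and positions are 1-based and strictly increasing within each
#' chromosome.
#'
#' @param calls integer matrix `[n x m]`, values in `{0, 1, 2, NA}`.
#' @param variants data.frame with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `info_score` (`NA` where absent).
#' @param sample_ids character vector of length `n`.
#' @return An object of class `"geno_matrix"` (or `"dosage_matrix"`).
#' @export
geno_matrix <- function(calls, variants, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(calls)))
  variants <- .check_variants(variants, ncol(calls))
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("genotype calls must be 0, 1, 2 or NA")
  structure(
    list(calls = calls, variants = variants,
         sample_ids = as.character(sample_ids)),
    class = "geno_matrix"
  )
}

#' @rdname geno_matrix
#' @param dosages numeric matrix `[n x m]`, values in `[0, 2]` or `NA`.
#' @param gp optional list of three `[n x m]` matrices `P(hom-ref)`,
#'   `P(het)`, `P(hom-alt)`; triples must sum to 1 and be consistent with
#'   the dosage within `1e-6`.
#' @export
dosage_matrix <- function(dosages, variants, sample_ids = rownames(dosages),
                          gp = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(nrow(dosages)))
  variants <- .check_variants(variants, ncol(dosages))
  rng <- range(dosages, na.rm = TRUE)
  if (is.finite(rng[1]) && (rng[1] < -1e-9 || rng[2] > 2 + 1e-9))
    stop("dosages must lie in [0, 2]")
  if (!is.null(gp)) {
    stopifnot(is.list(gp), length(gp) == 3L)
    s <- gp[[1]] + gp[[2]] + gp[[3]]
    ok <- is.na(s) | abs(s - 1) < 1e-6
    if (!all(ok)) stop("genotype probability triples must sum to 1")
    d <- gp[[2]] + 2 * gp[[3]]
    ok <- is.na(d) | is.na(dosages) | abs(d - dosages) < 1e-6
    if (!all(ok)) stop("dosage must equal P(het) + 2 P(hom-alt)")
  }
  structure(
    list(dosages = dosages, variants = variants,
         sample_ids = as.character(sample_ids), gp = gp),
    class = "dosage_matrix"
  )
}

.check_variants <- function(variants, m) {
  variants <- as.data.frame(variants, stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt")
  if (!all(need %in% names(variants)))
    stop("variants needs columns chrom, pos, ref, alt")
  if (nrow(variants) != m)
    stop("variant table and genotype matrix disagree on the number of variants")
  if (!"info_score" %in% names(variants)) variants$info_score <- NA_real_
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  if (any(variants$pos < 1L)) stop("positions are 1-based (pos >= 1)")
  if (any(variants$ref == variants$alt)) stop("ref and alt must differ")
  for (chr in unique(variants$chrom)) {
    p <- variants$pos[variants$chrom == chr]
    if (any(diff(p) <= 0L))
      stop("positions must be strictly increasing within chromosome ", chr)
  }
  variants
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat("geno_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "biallelic SNPs\n")
  cat("  chromosomes:", paste(unique(x$variants$chrom), collapse = ", "), "\n")
  miss <- mean(is.na(x$calls))
  cat(sprintf("  missing calls: %.2f%%\n", 100 * miss))
  invisible(x)
}

#' @export
print.dosage_matrix <- function(x, ...) {
  cat("dosage_matrix:", length(x$sample_ids), "samples x",
      nrow(x$variants), "biallelic SNPs\n")
  cat("  genotype probabilities:", if (is.null(x$gp)) "absent" else "present", "\n")
  invisible(x)
}

n_samples <- function(x) length(x$sample_ids)
n_variants <- function(x) nrow(x$variants)

#' Numeric genotype values of a container
#'
#' Returns the `[n x m]` numeric matrix underlying either container: hard
#' calls for a `geno_matrix`, dosages for a `dosage_matrix`.
#' @param x a `geno_matrix` or `dosage_matrix`.
#' @keywords internal
geno_values <- function(x) {
  if (inherits(x, "geno_matrix")) {
    m <- x$calls
    storage.mode(m) <- "double"
    m
  } else if (inherits(x, "dosage_matrix")) {
    x$dosages
  } else stop("not a genotype container")
}

#' Subset a genotype container by variant and/or sample index
#' @param x a `geno_matrix` or `dosage_matrix`.
#' @param variant_idx,sample_idx integer/logical indices; `NULL` keeps all.
#' @export
subset_variants <- function(x, variant_idx = NULL, sample_idx = NULL) {
  if (is.null(variant_idx)) variant_idx <- seq_len(n_variants(x))
  if (is.null(sample_idx)) sample_idx <- seq_len(n_samples(x))
  v <- x$variants[variant_idx, , drop = FALSE]
  rownames(v) <- NULL
  if (inherits(x, "geno_matrix")) {
    geno_matrix(x$calls[sample_idx, variant_idx, drop = FALSE], v,
                x$sample_ids[sample_idx])
  } else {
    gp <- if (!is.null(x$gp))
      lapply(x$gp, function(p) p[sample_idx, variant_idx, drop = FALSE])
    dosage_matrix(x$dosages[sample_idx, variant_idx, drop = FALSE], v,
                  x$sample_ids[sample_idx], gp = gp)
  }
}

#' Alternate-allele frequency and MAF of one variant
#'
#' Frequencies are computed over non-missing calls only. For dosages the
#' frequency is `mean(dosage) / 2`.
#'
#' @param g a `geno_matrix` or `dosage_matrix`.
#' @param variant_index column index of the variant.
#' @return `allele_frequency()`: the alternate-allele frequency in `[0, 1]`;
#'   `variant_maf()`: `min(p, 1 - p)` in `[0, 0.5]`.
#' @export
allele_frequency <- function(g, variant_index) {
  v <- geno_values(g)[, variant_index]
  v <- v[!is.na(v)]
  if (!length(v)) stop("all calls missing at variant ", variant_index)
  mean(v) / 2
}

#' @rdname allele_frequency
#' @export
variant_maf <- function(g, variant_index) {
  p <- allele_frequency(g, variant_index)
  pmin(p, 1 - p)
}

#' Column-wise alternate-allele frequencies (non-missing denominator)
#' @keywords internal
.col_freqs <- function(g) {
  v <- geno_values(g)
  colMeans(v, na.rm = TRUE) / 2
}
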