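#' Read genotypes or dosages from a VCF file
#'
#' Ingests a (plain or bgzipped) VCF and returns a [geno_matrix()] when
#' `field = "GT"` or a [dosage_matrix()] when `field = "DS"` or `"GP"`.
#' Multiallelic records and non-SNP records (indels, symbolic alleles) are
#' dropped and counted in the `"n_dropped"` attribute. Coordinates stay
#' 1-based as in the VCF.
#'
#' The per-variant imputation info score is looked up in the INFO column
#' under `info_key` first, then under `"INFO"`; variants without either get
#' `NA` (treated as "score absent" downstream).
#'
#' @param path VCF file path.
#' @param field `"GT"`, `"DS"` or `"GP"`.
#' @param info_key INFO tag carrying the imputation info score.
#' @return a `geno_matrix` or `dosage_matrix` with attribute `n_dropped`.
#' @export
read_genotypes <- function(path, field = c("GT", "DS", "GP"),
                           info_key = "INFO_SCORE") {
  field <- match.arg(field)
  if (!file.exists(path)) stop("cannot read VCF: ", path)
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  is_snp <- !is.na(alt) & !grepl(",", alt, fixed = TRUE) &
    nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_dropped <- sum(!is_snp)
  if (!any(is_snp)) stop("no biallelic SNP records in ", path)

  info_score <- .extract_info_score(vcf, info_key)
  variants <- data.frame(
    chrom = fix[is_snp, "CHROM"],
    pos = as.integer(fix[is_snp, "POS"]),
    ref = ref[is_snp], alt = alt[is_snp],
    info_score = info_score[is_snp],
    stringsAsFactors = FALSE
  )

  gt_raw <- vcfR::extract.gt(vcf, element = field)
  if (all(is.na(gt_raw))) stop("field ", field, " absent from all records")
  gt_raw <- gt_raw[is_snp, , drop = FALSE]
  samples <- colnames(gt_raw)

  if (field == "GT") {
    calls <- t(matrix(.parse_gt(as.vector(gt_raw)), nrow = nrow(gt_raw)))
    out <- geno_matrix(calls, variants, samples)
  } else if (field == "DS") {
    ds <- t(matrix(suppressWarnings(as.numeric(gt_raw)), nrow = nrow(gt_raw)))
    out <- dosage_matrix(ds, variants, samples)
  } else {
    gp <- .parse_gp(gt_raw)
    ds <- gp[[2]] + 2 * gp[[3]]
    out <- dosage_matrix(ds, variants, samples, gp = gp)
  }
  attr(out, "n_dropped") <- n_dropped
  out
}

.extract_info_score <- function(vcf, info_key) {
  for (key in unique(c(info_key, "INFO"))) {
    val <- suppressWarnings(vcfR::extract.info(vcf, element = key,
                                               as.numeric = TRUE))
    if (!is.null(val) && !all(is.na(val))) return(as.numeric(val))
  }
  rep(NA_real_, nrow(vcf@fix))
}

.parse_gt <- function(x) {
  a <- sub(":.*", "", x)
  al <- strsplit(a, "[/|]")
  vapply(al, function(g) {
    g <- suppressWarnings(as.integer(g))
    if (length(g) != 2L || anyNA(g)) return(NA_integer_)
    sum(g != 0L)
  }, integer(1))
}

.parse_gp <- function(gt_raw) {
  n <- ncol(gt_raw); m <- nrow(gt_raw)
  split3 <- function(k) {
    v <- vapply(strsplit(gt_raw, ",", fixed = TRUE), function(p) {
      if (length(p) == 3L) suppressWarnings(as.numeric(p[k])) else NA_real_
    }, numeric(1))
    t(matrix(v, nrow = m))
  }
  list(split3(1L), split3(2L), split3(3L))
}

#' Write a genotype container to a plain-text VCF
#'
#' Emits a minimal VCFv4.2: GT for a `geno_matrix`; DS (and GP when present)
#' for a `dosage_matrix`. The info score, where present, is written as an
#' `INFO_SCORE` INFO tag, so a written file round-trips through
#' [read_genotypes()].
#'
#' @param g a `geno_matrix` or `dosage_matrix`.
#' @param path output file path (plain text).
#' @export
write_genotypes <- function(g, path) {
  v <- g$variants
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=lcsgwas",
    "##INFO=<ID=INFO_SCORE,Number=1,Type=Float,Description=\"Imputation info score\">"
  )
  if (inherits(g, "geno_matrix")) {
    hdr <- c(hdr, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
    fmt <- "GT"
    body <- matrix(c("0/0", "0/1", "1/1")[t(g$calls) + 1L],
                   nrow = nrow(v))
    body[is.na(body)] <- "./."
  } else {
    hdr <- c(hdr,
      "##FORMAT=<ID=DS,Number=1,Type=Float,Description=\"Alternate allele dosage\">",
      "##FORMAT=<ID=GP,Number=G,Type=Float,Description=\"Genotype probabilities\">")
    ds <- format(round(t(g$dosages), 6), trim = TRUE, scientific = FALSE)
    if (!is.null(g$gp)) {
      fmt <- "DS:GP"
      gp <- lapply(g$gp, function(p) format(round(t(p), 6), trim = TRUE,
                                            scientific = FALSE))
      body <- matrix(paste0(ds, ":", gp[[1]], ",", gp[[2]], ",", gp[[3]]),
                     nrow = nrow(ds))
    } else {
      fmt <- "DS"
      body <- ds
    }
    body[is.na(t(g$dosages))] <- "."
  }
  info <- ifelse(is.na(v$info_score), ".",
                 paste0("INFO_SCORE=", format(v$info_score, trim = TRUE,
                                              scientific = FALSE)))
  lines <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", info, fmt,
                 apply(body, 1, paste, collapse = "\t"), sep = "\t")
  col_hdr <- paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                     "INFO", "FORMAT", g$sample_ids), collapse = "\t")
  writeLines(c(hdr, col_hdr, lines), path)
  invisible(path)
}
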