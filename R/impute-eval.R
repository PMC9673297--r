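#' Match variant sites between a truth set and a test set
#'
#' Two sites are the same iff chromosome, position, reference allele and
#' alternate allele are all identical (so `A/G` and `G/A` at one position do
#' not match). Duplicate keys within a list keep their first occurrence;
#' the rest are flagged.
#'
#' @param truth_variants,test_variants variant data.frames
#'   (`chrom`, `pos`, `ref`, `alt`).
#' @return list with `pairs` (two-column matrix of truth/test indices),
#'   `n_truth_only`, `n_test_only`, `n_dup_truth`, `n_dup_test`.
#' @export
match_sites <- function(truth_variants, test_variants) {
  key <- function(v) paste(v$chrom, v$pos, v$ref, v$alt, sep = ":")
  kt <- key(truth_variants); ks <- key(test_variants)
  dup_t <- duplicated(kt); dup_s <- duplicated(ks)
  it <- which(!dup_t); is <- which(!dup_s)
  m <- match(kt[it], ks[is])
  hit <- !is.na(m)
  pairs <- cbind(truth = it[hit], test = is[m[hit]])
  list(pairs = pairs,
       n_truth_only = sum(!hit),
       n_test_only = length(is) - sum(hit),
       n_dup_truth = sum(dup_t), n_dup_test = sum(dup_s))
}

# hard-call a test container: GP argmax (tie -> het), else dosage rounded
# to the nearest integer with exact .5 going up
.hard_calls <- function(x) {
  if (inherits(x, "geno_matrix")) return(x$calls)
  if (!is.null(x$gp)) {
    p0 <- x$gp[[1]]; p1 <- x$gp[[2]]; p2 <- x$gp[[3]]
    out <- ifelse(p1 >= p0 & p1 >= p2, 1L, ifelse(p2 > p0, 2L, 0L))
    out[is.na(p0) | is.na(p1) | is.na(p2)] <- NA_integer_
    out
  } else {
    out <- pmin(pmax(floor(x$dosages + 0.5), 0), 2)
    storage.mode(out) <- "integer"
    out
  }
}

#' Genotype concordance (GC) of imputed against truth genotypes
#'
#' Per cell, concordance is 1 when the hard-called test genotype equals the
#' truth genotype, else 0. The GC of a site is the average over samples with
#' both calls non-missing, and the aggregate GC is the unweighted mean over
#' evaluable sites.
#'
#' @param truth a `geno_matrix` of high-confidence calls.
#' @param test a `geno_matrix` or `dosage_matrix` of imputed genotypes.
#' @param match a site match from [match_sites()]; defaults to matching the
#'   two containers' variant tables.
#' @return list with `per_site` (data.frame: truth/test index, gc, n_eval),
#'   `mean_gc`, `n_sites_skipped`.
#' @export
genotype_concordance <- function(truth, test,
                                 match = match_sites(truth$variants,
                                                     test$variants)) {
  stopifnot(inherits(truth, "geno_matrix"))
  pr <- match$pairs
  tv <- truth$calls[, pr[, "truth"], drop = FALSE]
  sv <- .hard_calls(test)[, pr[, "test"], drop = FALSE]
  ok <- !is.na(tv) & !is.na(sv)
  eq <- (tv == sv) & ok
  n_eval <- colSums(ok)
  gc <- ifelse(n_eval > 0, colSums(eq) / n_eval, NA_real_)
  per_site <- data.frame(truth_idx = pr[, "truth"], test_idx = pr[, "test"],
                         gc = gc, n_eval = n_eval)
  list(per_site = per_site,
       mean_gc = mean(gc, na.rm = TRUE),
       n_sites_skipped = sum(n_eval == 0))
}

#' Genotype accuracy (GA): per-site dosage-truth correlation
#'
#' GA of a site is the Pearson correlation, across samples, between the
#' imputed dosage and the truth genotype code. Sites with fewer than 3
#' paired observations or zero variance on either side are skipped and
#' counted. The aggregate GA is the unweighted mean over evaluable sites; a
#' pooled all-cells correlation is also reported.
#'
#' @inheritParams genotype_concordance
#' @param test a `dosage_matrix` (or `geno_matrix`, whose calls are used as
#'   exact dosages).
#' @return list with `per_site`, `mean_ga`, `pooled_ga`, `n_sites_skipped`.
#' @export
genotype_accuracy <- function(truth, test,
                              match = match_sites(truth$variants,
                                                  test$variants)) {
  stopifnot(inherits(truth, "geno_matrix"))
  pr <- match$pairs
  tv <- truth$calls[, pr[, "truth"], drop = FALSE]
  storage.mode(tv) <- "double"
  sv <- geno_values(test)[, pr[, "test"], drop = FALSE]
  ga <- numeric(nrow(pr)); n_eval <- integer(nrow(pr))
  for (k in seq_len(nrow(pr))) {
    ok <- !is.na(tv[, k]) & !is.na(sv[, k])
    n_eval[k] <- sum(ok)
    ga[k] <- if (n_eval[k] < 3L || stats::sd(tv[ok, k]) == 0 ||
                 stats::sd(sv[ok, k]) == 0) NA_real_
      else stats::cor(tv[ok, k], sv[ok, k])
  }
  ok_all <- !is.na(tv) & !is.na(sv)
  pooled <- if (sum(ok_all) >= 3 && stats::sd(tv[ok_all]) > 0 &&
                stats::sd(sv[ok_all]) > 0)
    stats::cor(tv[ok_all], sv[ok_all]) else NA_real_
  per_site <- data.frame(truth_idx = pr[, "truth"], test_idx = pr[, "test"],
                         ga = ga, n_eval = n_eval)
  list(per_site = per_site, mean_ga = mean(ga, na.rm = TRUE),
       pooled_ga = pooled, n_sites_skipped = sum(is.na(ga)))
}

#' MAF-binned imputation metrics
#'
#' Assigns matched sites to half-open MAF bins `[lo, hi)` (the last bin is
#' closed at 0.5) by the truth-set MAF and reports per-bin unweighted mean
#' GC and GA with counts.
#'
#' @param truth truth `geno_matrix` (source of the binning MAF).
#' @param gc,ga results of [genotype_concordance()] and
#'   [genotype_accuracy()] on the same match (either may be `NULL`).
#' @param bin_edges increasing vector of bin edges over `[0, 0.5]`.
#' @return data.frame: `bin_lo`, `bin_hi`, `n_sites`, `mean_gc`, `mean_ga`.
#' @export
binned_metrics <- function(truth, gc = NULL, ga = NULL,
                           bin_edges = seq(0, 0.5, by = 0.05)) {
  per <- if (!is.null(gc)) gc$per_site else ga$per_site
  maf <- vapply(per$truth_idx, function(j) variant_maf(truth, j), numeric(1))
  bin <- findInterval(maf, bin_edges, rightmost.closed = TRUE)
  bin[bin < 1] <- 1L
  nb <- length(bin_edges) - 1L
  out <- data.frame(bin_lo = bin_edges[-length(bin_edges)],
                    bin_hi = bin_edges[-1])
  out$n_sites <- vapply(seq_len(nb), function(b) sum(bin == b), integer(1))
  pick <- function(res, col) {
    if (is.null(res)) return(rep(NA_real_, nb))
    vapply(seq_len(nb), function(b) {
      v <- res$per_site[[col]][bin == b]
      if (!length(v) || all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
    }, numeric(1))
  }
  out$mean_gc <- pick(gc, "gc")
  out$mean_ga <- pick(ga, "ga")
  out
}

#' Imputation metrics over a (sample size, depth) design grid
#'
#' Evaluates mean GC and GA of each cell's imputed data against the shared
#' truth set, one row per cell.
#'
#' @param truth truth `geno_matrix`.
#' @param cells list of lists with elements `sample_size`, `depth`, and
#'   `data` (a `dosage_matrix` or `geno_matrix` for that cell, whose
#'   samples are a subset of the truth samples).
#' @return long-format data.frame: `sample_size`, `depth`, `mean_gc`,
#'   `mean_ga`, `n_sites`.
#' @export
evaluate_design_grid <- function(truth, cells) {
  rows <- lapply(cells, function(cell) {
    sub <- match(cell$data$sample_ids, truth$sample_ids)
    stopifnot(!anyNA(sub))
    tr <- subset_variants(truth, sample_idx = sub)
    mt <- match_sites(tr$variants, cell$data$variants)
    gc <- genotype_concordance(tr, cell$data, mt)
    ga <- genotype_accuracy(tr, cell$data, mt)
    data.frame(sample_size = cell$sample_size, depth = cell$depth,
               mean_gc = gc$mean_gc, mean_ga = ga$mean_ga,
               n_sites = nrow(mt$pairs))
  })
  if (!length(rows))
    return(data.frame(sample_size = numeric(0), depth = numeric(0),
                      mean_gc = numeric(0), mean_ga = numeric(0),
                      n_sites = integer(0)))
  do.call(rbind, rows)
}
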