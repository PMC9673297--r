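#' Sliding-window nucleotide diversity
#'
#' Per site, diversity is the unbiased expected heterozygosity
#' `pi = 2 a b / (N (N - 1))` with `a` the alternate allele count, `b` the
#' reference allele count and `N = a + b` the number of non-missing alleles
#' (2 per genotyped diploid). A window's value is the sum of its site
#' values divided by the nominal window length in bp (per-bp diversity), so
#' doubling `window_bp` halves the value of a single-site window.
#'
#' Windows are anchored at position 1 on each chromosome and advance by
#' `step_bp`; trailing windows that extend beyond the last variant are kept
#' and flagged `partial`.
#'
#' @param g a `geno_matrix` of hard diploid calls.
#' @param window_bp,step_bp window and step size in bp.
#' @return data.frame of class `"window_stats"`: `chrom`, `start`, `end`
#'   (1-based inclusive), `value`, `n_variants`, `partial`.
#' @export
windowed_pi <- function(g, window_bp = 50000, step_bp = 10000) {
  calls <- g$calls
  a <- colSums(calls, na.rm = TRUE)
  N <- 2 * colSums(!is.na(calls))
  site_pi <- ifelse(N >= 2, 2 * a * (N - a) / (N * (N - 1)), 0)
  .window_apply(g$variants, site_pi, window_bp, step_bp,
                function(v) sum(v) / window_bp)
}

# Weir & Cockerham (1984) per-site variance components for two populations
# from genotype counts; returns the numerator a and denominator a + b + c
.wc_site_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / 2
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) /
                      (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  c(a = a, d = a + b + c_)
}

#' Sliding-window Weir-Cockerham FST between two populations
#'
#' Per-site Weir & Cockerham (1984) variance components are computed from
#' genotype counts; a window's FST is the ratio of summed numerators to
#' summed denominators over its sites (the weighted, ratio-of-sums
#' estimator). Negative window values are possible and kept. Sites with
#' fewer than 2 genotyped individuals in either population are skipped;
#' windows whose summed denominator is zero get `NA` and are flagged.
#'
#' @param g1,g2 `geno_matrix` objects for the two populations, with an
#'   identical variant set.
#' @param window_bp,step_bp window and step size in bp.
#' @return a `"window_stats"` data.frame (see [windowed_pi()]) with an
#'   extra logical column `undefined`.
#' @export
windowed_fst <- function(g1, g2, window_bp = 50000, step_bp = 10000) {
  if (!identical(g1$variants[c("chrom", "pos", "ref", "alt")],
                 g2$variants[c("chrom", "pos", "ref", "alt")]))
    stop("the two populations must share one variant set")
  comp <- function(g) {
    calls <- g$calls
    n <- colSums(!is.na(calls))
    p <- ifelse(n > 0, colSums(calls, na.rm = TRUE) / (2 * n), NA)
    h <- ifelse(n > 0, colSums(calls == 1, na.rm = TRUE) / n, NA)
    list(n = n, p = p, h = h)
  }
  c1 <- comp(g1); c2 <- comp(g2)
  usable <- c1$n >= 2 & c2$n >= 2
  m <- n_variants(g1)
  a <- d <- rep(0, m)
  for (j in which(usable)) {
    ad <- .wc_site_components(c1$n[j], c1$p[j], c1$h[j],
                              c2$n[j], c2$p[j], c2$h[j])
    a[j] <- ad["a"]; d[j] <- ad["d"]
  }
  site_ok <- usable
  num <- .window_apply(g1$variants, ifelse(site_ok, a, 0), window_bp, step_bp,
                       sum)
  den <- .window_apply(g1$variants, ifelse(site_ok, d, 0), window_bp, step_bp,
                       sum)
  out <- num
  out$undefined <- den$value == 0
  out$value <- ifelse(out$undefined, NA_real_, num$value / den$value)
  # count only usable sites
  cnt <- .window_apply(g1$variants, as.numeric(site_ok), window_bp, step_bp,
                       sum)
  out$n_variants <- as.integer(cnt$value)
  class(out) <- c("window_stats", "data.frame")
  out
}

# tile [1, max pos] per chromosome with sliding windows and reduce the
# per-site statistic within each window
.window_apply <- function(variants, site_stat, window_bp, step_bp, reduce) {
  rows <- list()
  for (chr in unique(variants$chrom)) {
    sel <- variants$chrom == chr
    pos <- variants$pos[sel]
    vals <- site_stat[sel]
    maxpos <- max(pos)
    starts <- seq.int(1L, maxpos, by = step_bp)
    ends <- starts + window_bp - 1L
    n_win <- length(starts)
    value <- numeric(n_win); nv <- integer(n_win)
    for (w in seq_len(n_win)) {
      in_w <- pos >= starts[w] & pos <= ends[w]
      nv[w] <- sum(in_w)
      value[w] <- reduce(vals[in_w])
    }
    rows[[chr]] <- data.frame(chrom = chr, start = starts, end = ends,
                              value = value, n_variants = nv,
                              partial = ends > maxpos,
                              stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("window_stats", "data.frame")
  out
}

#' Select and merge outlier windows
#'
#' Optionally z-transforms the window statistic across all defined windows
#' (`(x - mean) / sd`), selects windows at or above the `quantile` cutoff
#' of the (possibly transformed) values, and merges overlapping or
#' bookended selected windows into regions.
#'
#' @param stats a `"window_stats"` data.frame.
#' @param quantile top quantile defining outliers (e.g. 0.95 for the top
#'   5%); a parameter, since different analyses use different tails.
#' @param zscore if `TRUE`, standardize values before thresholding (the
#'   cutoff is then on the z scale).
#' @return list with `regions` (data.frame `chrom`, `start`, `end`,
#'   `n_windows`), `selected` (the outlier windows, with `z` column if
#'   requested), `cutoff`.
#' @export
select_outlier_windows <- function(stats, quantile = 0.95, zscore = FALSE) {
  ok <- !is.na(stats$value)
  if (!any(ok)) stop("no window with a defined value")
  x <- stats$value
  if (zscore) {
    mu <- mean(x[ok]); sdv <- stats::sd(x[ok])
    x <- (x - mu) / sdv
    stats$z <- x
  }
  cutoff <- stats::quantile(x[ok], quantile, names = FALSE)
  sel <- which(ok & x >= cutoff)
  selected <- stats[sel, , drop = FALSE]
  regions <- list()
  if (length(sel)) {
    selected <- selected[order(selected$chrom, selected$start), , drop = FALSE]
    cur <- selected[1, , drop = FALSE]; cnt <- 1L
    for (i in seq_len(nrow(selected))[-1]) {
      row <- selected[i, , drop = FALSE]
      if (row$chrom == cur$chrom && row$start <= cur$end + 1L) {
        cur$end <- max(cur$end, row$end); cnt <- cnt + 1L
      } else {
        regions[[length(regions) + 1L]] <-
          data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
                     n_windows = cnt)
        cur <- row; cnt <- 1L
      }
    }
    regions[[length(regions) + 1L]] <-
      data.frame(chrom = cur$chrom, start = cur$start, end = cur$end,
                 n_windows = cnt)
  }
  regions <- if (length(regions)) do.call(rbind, regions)
    else data.frame(chrom = character(0), start = integer(0),
                    end = integer(0), n_windows = integer(0))
  rownames(regions) <- NULL; rownames(selected) <- NULL
  list(regions = regions, selected = selected, cutoff = cutoff)
}

#' Write window statistics as BED-like TSV
#'
#' Writes both a BED-style file (0-based half-open `start`) and, when
#' `one_based = TRUE`, keeps the 1-based inclusive coordinates instead.
#'
#' @param stats a `"window_stats"` data.frame.
#' @param path output path.
#' @param one_based write 1-based inclusive coordinates instead of BED.
#' @export
write_window_stats <- function(stats, path, one_based = FALSE) {
  df <- data.frame(chrom = stats$chrom,
                   start = if (one_based) stats$start else stats$start - 1L,
                   end = stats$end, value = stats$value,
                   n_variants = stats$n_variants)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
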