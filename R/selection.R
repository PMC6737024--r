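#' Sliding-window grid over chromosomes
#'
#' Windows anchored at position 0 of each chromosome, advancing by `step`;
#' trailing partial windows are included with their true span.
#'
#' @param chrom_lengths named vector of chromosome lengths in bp.
#' @param window window size in bp.
#' @param step step size in bp.
#' @return data.frame `chrom`, `start`, `end` (0-based half-open).
#' @export
make_windows <- function(chrom_lengths, window = 1e5, step = 1e4) {
  stopifnot(window > 0, step > 0)
  out <- lapply(names(chrom_lengths), function(ch) {
    L <- chrom_lengths[[ch]]
    starts <- seq.int(0L, max(0L, L - 1L), by = step)
    data.frame(chrom = ch, start = as.integer(starts),
               end = as.integer(pmin(starts + window, L)))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# windowed sums of a per-site statistic via cumulative sums on the sorted
# position vector; returns value and n per window
window_sums <- function(sites_chrom, sites_pos, values, windows) {
  val <- numeric(nrow(windows)); n <- integer(nrow(windows))
  for (ch in unique(windows$chrom)) {
    wi <- which(windows$chrom == ch)
    si <- which(sites_chrom == ch)
    if (length(si) == 0L) next
    pos <- sites_pos[si]; v <- values[si]
    keep <- !is.na(v)
    pos <- pos[keep]; v <- v[keep]
    if (length(pos) == 0L) next
    cs <- c(0, cumsum(v))
    lo <- findInterval(windows$start[wi] - 0.5, pos)    # sites with pos < start
    hi <- findInterval(windows$end[wi] - 0.5, pos)      # sites with pos < end
    val[wi] <- cs[hi + 1L] - cs[lo + 1L]
    n[wi] <- hi - lo
  }
  list(sum = val, n = n)
}

#' Windowed nucleotide diversity
#'
#' Per window, the sum over sites of per-site heterozygosity
#' `2*p*(1-p) * n/(n-1)` (with `n` the called allele count at the site),
#' divided by the window span in bp. This equals the mean pairwise
#' difference per bp among the group's haplotypes. Windows containing no
#' usable site are reported as missing.
#'
#' @param x a [genotype_matrix()].
#' @param group group label.
#' @param window,step window grid in bp (defaults 100 kb / 10 kb).
#' @return data.frame `chrom`, `start`, `end`, `n_sites`, `value`.
#' @export
windowed_pi <- function(x, group, window = 1e5, step = 1e4) {
  idx <- group_index(x, group)
  g <- x$geno[idx, , drop = FALSE]
  called <- colSums(!is.na(g))
  n <- 2 * called
  alt <- colSums(g == 2L, na.rm = TRUE) * 2 + colSums(g == 1L, na.rm = TRUE)
  p <- ifelse(n > 0, alt / n, NA_real_)
  h <- ifelse(n >= 2, 2 * p * (1 - p) * n / (n - 1), NA_real_)
  win <- make_windows(x$chrom_lengths, window, step)
  ws <- window_sums(x$sites$chrom, x$sites$pos, h, win)
  win$n_sites <- ws$n
  win$value <- ifelse(ws$n > 0, ws$sum / (win$end - win$start), NA_real_)
  win
}

# Weir & Cockerham (1984) per-site variance components for two populations.
# Inputs are vectors over sites: called sample sizes, alt-allele frequencies
# and observed heterozygote frequencies per group. Returns the a component
# and the a+b+c denominator.
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  ok <- n1 >= 2 & n2 >= 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  a[!ok] <- NA_real_
  d <- a + b + cc
  d[!ok] <- NA_real_
  list(a = a, d = d)
}

#' Windowed Weir-Cockerham FST between two groups
#'
#' Per-site variance components of the Weir & Cockerham (1984) estimator are
#' summed over the sites in each window ("ratio of averages"), matching the
#' windowed-FST convention of standard VCF toolchains. Raw window values are
#' reported and may be negative; windows where no site has at least two
#' called samples in both groups are missing.
#'
#' @param x a [genotype_matrix()].
#' @param group_a,group_b group labels.
#' @param window,step window grid in bp (defaults 100 kb / 10 kb).
#' @return data.frame `chrom`, `start`, `end`, `n_sites`, `value`.
#' @export
windowed_fst <- function(x, group_a, group_b, window = 1e5, step = 1e4) {
  ia <- group_index(x, group_a); ib <- group_index(x, group_b)
  ga <- x$geno[ia, , drop = FALSE]; gb <- x$geno[ib, , drop = FALSE]
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- ifelse(n1 > 0, (2 * colSums(ga == 2L, na.rm = TRUE) +
                          colSums(ga == 1L, na.rm = TRUE)) / (2 * n1), NA_real_)
  p2 <- ifelse(n2 > 0, (2 * colSums(gb == 2L, na.rm = TRUE) +
                          colSums(gb == 1L, na.rm = TRUE)) / (2 * n2), NA_real_)
  h1 <- ifelse(n1 > 0, colSums(ga == 1L, na.rm = TRUE) / n1, NA_real_)
  h2 <- ifelse(n2 > 0, colSums(gb == 1L, na.rm = TRUE) / n2, NA_real_)
  wc <- wc_components(n1, p1, h1, n2, p2, h2)
  win <- make_windows(x$chrom_lengths, window, step)
  sa <- window_sums(x$sites$chrom, x$sites$pos, wc$a, win)
  sd_ <- window_sums(x$sites$chrom, x$sites$pos, wc$d, win)
  win$n_sites <- sd_$n
  win$value <- ifelse(sd_$n > 0 & sd_$sum != 0, sa$sum / sd_$sum, NA_real_)
  win
}

#' Per-site Weir-Cockerham FST
#'
#' @inheritParams windowed_fst
#' @return numeric vector of per-site FST (`a / (a+b+c)`), `NA` where
#'   undefined.
#' @export
site_fst <- function(x, group_a, group_b) {
  ia <- group_index(x, group_a); ib <- group_index(x, group_b)
  ga <- x$geno[ia, , drop = FALSE]; gb <- x$geno[ib, , drop = FALSE]
  n1 <- colSums(!is.na(ga)); n2 <- colSums(!is.na(gb))
  p1 <- (2 * colSums(ga == 2L, na.rm = TRUE) + colSums(ga == 1L, na.rm = TRUE)) /
    pmax(2 * n1, 1)
  p2 <- (2 * colSums(gb == 2L, na.rm = TRUE) + colSums(gb == 1L, na.rm = TRUE)) /
    pmax(2 * n2, 1)
  h1 <- colSums(ga == 1L, na.rm = TRUE) / pmax(n1, 1)
  h2 <- colSums(gb == 1L, na.rm = TRUE) / pmax(n2, 1)
  wc <- wc_components(n1, p1, h1, n2, p2, h2)
  ifelse(!is.na(wc$d) & wc$d != 0, wc$a / wc$d, NA_real_)
}

#' Z-transform window statistics
#'
#' Centers and scales to unit variance over the non-missing values
#' (sample standard deviation); missing values stay missing. Zero variance
#' or fewer than two non-missing values is an error rather than a silent
#' NaN.
#'
#' @param values numeric vector (window statistics, genome-wide).
#' @return numeric vector of Z scores.
#' @export
z_transform <- function(values) {
  ok <- !is.na(values)
  if (sum(ok) < 2L) stop("need at least two non-missing values")
  s <- sd(values[ok])
  if (s == 0) stop("zero variance: Z-transformation undefined")
  out <- rep(NA_real_, length(values))
  out[ok] <- (values[ok] - mean(values[ok])) / s
  out
}

#' Call divergent regions from Z-transformed window statistics
#'
#' Windows exceeding the threshold (strictly) are flagged and flagged
#' windows that overlap or abut on the grid are merged into maximal
#' regions.
#'
#' @param windows data.frame with `chrom`, `start`, `end` and a `z` column
#'   (or pass Z scores via `z`).
#' @param threshold Z threshold (default 3 standard deviations).
#' @param z optional numeric vector overriding `windows$z`.
#' @return data.frame `chrom`, `start`, `end`, `peak_z`, `n_windows` with
#'   attributes `n_flagged` (flagged window count) and `total_bp`
#'   (merged bp).
#' @export
call_divergent_regions <- function(windows, threshold = 3, z = NULL) {
  if (is.null(z)) z <- windows$z
  if (is.null(z)) stop("no z values supplied")
  flag <- !is.na(z) & z > threshold
  empty <- data.frame(chrom = character(), start = integer(),
                      end = integer(), peak_z = numeric(),
                      n_windows = integer())
  if (!any(flag)) {
    attr(empty, "n_flagged") <- 0L; attr(empty, "total_bp") <- 0
    return(empty)
  }
  fw <- windows[flag, , drop = FALSE]
  fz <- z[flag]
  gr <- GenomicRanges::GRanges(fw$chrom,
                               IRanges::IRanges(fw$start + 1L, fw$end))
  red <- GenomicRanges::reduce(gr)
  ov <- GenomicRanges::findOverlaps(gr, red)
  ri <- S4Vectors::subjectHits(ov)
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(red)),
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    peak_z = as.numeric(tapply(fz[S4Vectors::queryHits(ov)], ri, max)),
    n_windows = as.integer(tabulate(ri, nbins = length(red))))
  attr(out, "n_flagged") <- sum(flag)
  attr(out, "total_bp") <- sum(out$end - out$start)
  out
}

#' Intersect regions with annotated features
#'
#' A feature overlaps a region iff the intersection is at least 1 bp under
#' half-open coordinates. When a chromosome universe is supplied, features
#' on chromosomes outside it are skipped with a warning.
#'
#' @param regions data.frame `chrom`, `start`, `end` (half-open).
#' @param features data.frame `chrom`, `start`, `end`, `id`.
#' @param chromosomes optional character vector of known chromosome names.
#' @return list with `per_region` (feature id vector per region),
#'   `n_features` (deduplicated global count) and `feature_ids`.
#' @export
intersect_features <- function(regions, features, chromosomes = NULL) {
  if (!is.null(chromosomes)) {
    unknown <- !(features$chrom %in% chromosomes)
    if (any(unknown)) {
      warning(sum(unknown), " feature(s) on unknown chromosomes; skipped")
      features <- features[!unknown, , drop = FALSE]
    }
  }
  per_region <- rep(list(character(0)), nrow(regions))
  if (nrow(regions) > 0L && nrow(features) > 0L) {
    gr_r <- GenomicRanges::GRanges(regions$chrom,
                                   IRanges::IRanges(regions$start + 1L, regions$end))
    gr_f <- GenomicRanges::GRanges(features$chrom,
                                   IRanges::IRanges(features$start + 1L, features$end))
    ov <- GenomicRanges::findOverlaps(gr_r, gr_f)
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    for (i in unique(qh))
      per_region[[i]] <- features$id[sh[qh == i]]
  }
  ids <- unique(unlist(per_region))
  list(per_region = per_region, n_features = length(ids), feature_ids = ids)
}

#' Linkage-disequilibrium decay
#'
#' Genotype-correlation r-squared for all intra-chromosome site pairs within
#' `max_dist`, averaged per distance bin. Monomorphic sites are skipped;
#' bins with no pair are reported missing.
#'
#' @param x a [genotype_matrix()].
#' @param group group label.
#' @param max_dist maximum pair distance in bp.
#' @param n_bins number of equal-width distance bins.
#' @return data.frame `bin_mid`, `mean_r2`, `n_pairs`.
#' @export
ld_decay <- function(x, group, max_dist = 5e5, n_bins = 50) {
  idx <- group_index(x, group)
  g <- x$geno[idx, , drop = FALSE]
  breaks <- seq(0, max_dist, length.out = n_bins + 1)
  sums <- numeric(n_bins); counts <- integer(n_bins)
  for (ch in unique(x$sites$chrom)) {
    si <- which(x$sites$chrom == ch)
    gc <- g[, si, drop = FALSE]
    keep <- apply(gc, 2, function(v) {
      v <- v[!is.na(v)]; length(v) >= 2 && stats::var(v) > 0
    })
    gc <- gc[, keep, drop = FALSE]
    pos <- x$sites$pos[si][keep]
    if (ncol(gc) < 2L) next
    r2 <- suppressWarnings(cor(gc, use = "pairwise.complete.obs"))^2
    dm <- abs(outer(pos, pos, "-"))
    ut <- upper.tri(dm)
    d <- dm[ut]; r <- r2[ut]
    ok <- !is.na(r) & d > 0 & d <= max_dist
    if (!any(ok)) next
    bin <- findInterval(d[ok], breaks, rightmost.closed = TRUE,
                        left.open = TRUE)
    sums <- sums + vapply(seq_len(n_bins), function(b)
      sum(r[ok][bin == b]), numeric(1))
    counts <- counts + tabulate(bin, nbins = n_bins)
  }
  data.frame(bin_mid = (breaks[-1] + breaks[-length(breaks)]) / 2,
             mean_r2 = ifelse(counts > 0, sums / counts, NA_real_),
             n_pairs = counts)
}
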