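#' Construct a genotype matrix
#'
#' The central container for population genotypes: samples x biallelic sites,
#' with per-site metadata (chromosome, 0-based position, ref/alt allele,
#' subgenome tag) and per-sample group labels. Optionally carries the phased
#' haplotypes the genotypes were formed from (two rows per sample).
#'
#' @param geno integer matrix, samples x sites; entries 0 (hom-ref), 1 (het),
#'   2 (hom-alt) or `NA` (missing). May be `NULL` if `haplotypes` is given.
#' @param sites data.frame with columns `chrom`, `pos` (0-based), `ref`,
#'   `alt`; a `subgenome` column is derived from the first letter of `chrom`
#'   when absent. Positions must be strictly increasing within a chromosome.
#' @param samples data.frame with columns `sample_id`, `group`.
#' @param haplotypes optional 0/1 matrix with `2 * nrow(samples)` rows (rows
#'   `2i-1`, `2i` are the two haplotypes of sample `i`).
#' @param chrom_lengths optional named vector of chromosome lengths in bp;
#'   defaults to `max(pos) + 1` per chromosome.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(geno, sites, samples, haplotypes = NULL,
                            chrom_lengths = NULL) {
  stopifnot(is.data.frame(sites), is.data.frame(samples))
  req <- c("chrom", "pos", "ref", "alt")
  if (!all(req %in% names(sites)))
    stop("sites must have columns: ", paste(req, collapse = ", "))
  if (!all(c("sample_id", "group") %in% names(samples)))
    stop("samples must have columns sample_id, group")
  if (is.null(geno)) {
    if (is.null(haplotypes)) stop("one of geno or haplotypes is required")
    odd <- seq(1L, nrow(haplotypes), by = 2L)
    geno <- haplotypes[odd, , drop = FALSE] + haplotypes[odd + 1L, , drop = FALSE]
  }
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(samples))
    stop("nrow(geno) != number of samples")
  if (ncol(geno) != nrow(sites))
    stop("ncol(geno) != number of sites")
  if (!is.null(haplotypes) && nrow(haplotypes) != 2L * nrow(samples))
    stop("haplotypes must have two rows per sample")
  sites$chrom <- as.character(sites$chrom)
  sites$pos <- as.integer(sites$pos)
  if (is.null(sites$subgenome))
    sites$subgenome <- substr(sites$chrom, 1L, 1L)
  ord <- order(match(sites$chrom, unique(sites$chrom)), sites$pos)
  if (!identical(ord, seq_len(nrow(sites)))) {
    sites <- sites[ord, , drop = FALSE]
    geno <- geno[, ord, drop = FALSE]
    if (!is.null(haplotypes)) haplotypes <- haplotypes[, ord, drop = FALSE]
  }
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (anyDuplicated(p) || is.unsorted(p, strictly = TRUE))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  rownames(sites) <- NULL
  rownames(geno) <- samples$sample_id
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(split(sites$pos, sites$chrom), function(p)
      max(p) + 1L, integer(1))
    chrom_lengths <- chrom_lengths[unique(sites$chrom)]
  }
  structure(list(geno = geno, sites = sites,
                 samples = as.data.frame(samples, stringsAsFactors = FALSE),
                 haplotypes = haplotypes,
                 chrom_lengths = chrom_lengths),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$samples), " samples x ", nrow(x$sites),
      " sites (", paste(unique(x$samples$group), collapse = ", "), ")",
      if (!is.null(x$haplotypes)) " [phased]", "\n", sep = "")
  invisible(x)
}

#' Number of samples / sites in a genotype matrix
#' @param x a `genotype_matrix`.
#' @return integer count.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname n_samples
#' @export
n_sites <- function(x) nrow(x$sites)

#' Subset a genotype matrix by site index or sample
#'
#' @param x a `genotype_matrix`.
#' @param sites integer or logical index over sites.
#' @param samples character sample ids, or integer/logical index.
#' @return a `genotype_matrix`.
#' @export
subset_genotypes <- function(x, sites = NULL, samples = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  geno <- x$geno; hap <- x$haplotypes; sdf <- x$sites; smp <- x$samples
  if (!is.null(sites)) {
    geno <- geno[, sites, drop = FALSE]
    sdf <- sdf[sites, , drop = FALSE]
    if (!is.null(hap)) hap <- hap[, sites, drop = FALSE]
  }
  if (!is.null(samples)) {
    if (is.character(samples)) samples <- match(samples, smp$sample_id)
    geno <- geno[samples, , drop = FALSE]
    if (!is.null(hap)) {
      idx <- if (is.logical(samples)) which(samples) else samples
      hap <- hap[as.vector(rbind(2L * idx - 1L, 2L * idx)), , drop = FALSE]
    }
    smp <- smp[samples, , drop = FALSE]
    rownames(smp) <- NULL
  }
  genotype_matrix(geno, sdf, smp, haplotypes = hap,
                  chrom_lengths = x$chrom_lengths)
}

#' Combine genotype matrices sharing one site list
#'
#' @param ... `genotype_matrix` objects with identical `sites`.
#' @return a single `genotype_matrix` with all samples.
#' @export
combine_genotypes <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && is.list(gs[[1]]) && !inherits(gs[[1]], "genotype_matrix"))
    gs <- gs[[1]]
  ref <- gs[[1]]$sites[, c("chrom", "pos")]
  for (g in gs[-1])
    if (!identical(g$sites[, c("chrom", "pos")], ref))
      stop("genotype matrices do not share a site list")
  haps <- lapply(gs, function(g) g$haplotypes)
  hap <- if (all(!vapply(haps, is.null, logical(1)))) do.call(rbind, haps) else NULL
  genotype_matrix(do.call(rbind, lapply(gs, function(g) g$geno)),
                  gs[[1]]$sites,
                  do.call(rbind, lapply(gs, function(g) g$samples)),
                  haplotypes = hap,
                  chrom_lengths = gs[[1]]$chrom_lengths)
}

# indices of samples belonging to a group (error if absent)
group_index <- function(x, group) {
  idx <- which(x$samples$group == group)
  if (length(idx) == 0L) stop("group '", group, "' not present")
  idx
}

#' Per-site allele counts for a group
#'
#' Deleterious/alt allele counting rule: twice the number of homozygous-alt
#' samples plus the number of heterozygous samples, over called genotypes; the
#' denominator is twice the number of called samples.
#'
#' @param x a `genotype_matrix`.
#' @param group group label; `NULL` pools all samples.
#' @return data.frame with one row per site: `count` (alt alleles), `total`
#'   (called alleles) and `freq` (`NA` where no genotype is called).
#' @export
count_alleles <- function(x, group = NULL) {
  stopifnot(inherits(x, "genotype_matrix"))
  g <- if (is.null(group)) x$geno else x$geno[group_index(x, group), , drop = FALSE]
  called <- colSums(!is.na(g))
  count <- colSums(g == 2L, na.rm = TRUE) * 2L + colSums(g == 1L, na.rm = TRUE)
  total <- 2L * called
  freq <- ifelse(total > 0L, count / total, NA_real_)
  data.frame(chrom = x$sites$chrom, pos = x$sites$pos,
             count = as.integer(count), total = as.integer(total),
             freq = freq)
}
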