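#' Read a multi-sample VCF into a genotype matrix
#'
#' Keeps biallelic SNP records only; multiallelic and indel records are
#' dropped and counted (see `attr(,"dropped")`). VCF 1-based positions are
#' converted to the package's 0-based convention. Phased calls (`0|1`)
#' reconstruct haplotypes when every genotype is phased and called;
#' unphased calls are accepted for the genotype matrix.
#'
#' @param path VCF file (plain or gzipped).
#' @param groups optional data.frame (`sample_id`, `group`) or path to a
#'   two-column TSV; defaults to one group `"all"`.
#' @return a [genotype_matrix()] with attribute `dropped` (named counts of
#'   discarded records).
#' @export
read_vcf <- function(path, groups = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  if (!"FORMAT" %in% colnames(v@gt)) stop("VCF has no FORMAT/GT field")
  if (!any(grepl("GT", v@gt[, "FORMAT"]))) stop("VCF has no GT format")
  snp <- fix$REF %in% BASES & fix$ALT %in% BASES
  multi <- grepl(",", fix$ALT)
  keep <- snp & !multi
  dropped <- c(multiallelic = sum(multi), non_snp = sum(!snp & !multi))
  gt <- vcfR::extract.gt(v)[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  if (nrow(fix) == 0L) {
    samples <- data.frame(sample_id = colnames(v@gt)[-1], group = "all")
    gm <- genotype_matrix(matrix(integer(0), nrow = nrow(samples), ncol = 0),
                          data.frame(chrom = character(), pos = integer(),
                                     ref = character(), alt = character()),
                          samples)
    attr(gm, "dropped") <- dropped
    return(gm)
  }
  phased <- grepl("|", gt, fixed = TRUE)
  norm <- gsub("|", "/", gt, fixed = TRUE)
  a1 <- suppressWarnings(as.integer(substr(norm, 1, 1)))
  a2 <- suppressWarnings(as.integer(substr(norm, 3, 3)))
  geno <- matrix(a1 + a2, nrow = nrow(gt))
  geno <- t(geno)  # samples x sites
  hap <- NULL
  if (length(gt) > 0 && all(phased) && !anyNA(a1) && !anyNA(a2)) {
    ns <- ncol(gt)
    hap <- matrix(0L, nrow = 2L * ns, ncol = nrow(gt))
    hap[seq(1, 2 * ns, 2), ] <- t(matrix(a1, nrow = nrow(gt)))
    hap[seq(2, 2 * ns, 2), ] <- t(matrix(a2, nrow = nrow(gt)))
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS) - 1L,
                      ref = fix$REF, alt = fix$ALT)
  samples <- data.frame(sample_id = colnames(gt), group = "all")
  if (!is.null(groups)) {
    if (is.character(groups)) groups <- read_groups(groups)
    samples$group <- groups$group[match(samples$sample_id, groups$sample_id)]
  }
  lens <- NULL
  contig <- grep("^##contig=", v@meta, value = TRUE)
  if (length(contig)) {
    ids <- sub('.*ID=([^,>]+).*', '\\1', contig)
    ln <- suppressWarnings(as.integer(sub('.*length=([0-9]+).*', '\\1', contig)))
    if (!anyNA(ln)) lens <- setNames(ln, ids)
  }
  gm <- genotype_matrix(geno, sites, samples, haplotypes = hap,
                        chrom_lengths = lens[unique(sites$chrom)])
  attr(gm, "dropped") <- dropped
  gm
}

#' Write a genotype matrix as VCF 4.2
#'
#' Emits one multi-sample VCF with GT only; phased bars are used when the
#' matrix carries haplotypes, otherwise unphased genotypes
#' (missing as `./.`). Contig header lines carry the chromosome lengths.
#'
#' @param x a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  stopifnot(inherits(x, "genotype_matrix"))
  lens <- x$chrom_lengths
  header <- c("##fileformat=VCFv4.2",
              "##source=polyped",
              sprintf("##contig=<ID=%s,length=%d>", names(lens), lens),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", x$samples$sample_id), collapse = "\t"))
  ns <- nrow(x$samples)
  if (nrow(x$sites) > 0) {
    if (!is.null(x$haplotypes)) {
      h1 <- x$haplotypes[seq(1, 2 * ns, 2), , drop = FALSE]
      h2 <- x$haplotypes[seq(2, 2 * ns, 2), , drop = FALSE]
      gt <- matrix(paste0(h1, "|", h2), nrow = ns)
    } else {
      gmap <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
      gt <- matrix(gmap[as.character(x$geno)], nrow = ns)
      gt[is.na(gt)] <- "./."
    }
    recs <- paste(x$sites$chrom, x$sites$pos + 1L, ".", x$sites$ref,
                  x$sites$alt, ".", "PASS", ".", "GT",
                  apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  } else recs <- character(0)
  writeLines(c(header, recs), path)
  invisible(path)
}

#' Read / write sample group files
#'
#' Two-column tab-separated `sample_id`, `group` with no header, the common
#' convention of population-genetics toolchains.
#'
#' @param path file path.
#' @return data.frame (`sample_id`, `group`).
#' @export
read_groups <- function(path) {
  g <- read.table(path, sep = "\t", header = FALSE,
                  col.names = c("sample_id", "group"),
                  stringsAsFactors = FALSE)
  g
}

#' @rdname read_groups
#' @param groups data.frame (`sample_id`, `group`).
#' @export
write_groups <- function(groups, path) {
  write.table(groups[, c("sample_id", "group")], path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BED intervals
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates pass through unchanged. Writing emits BED6
#' (`chrom start end name score strand`); reading accepts 3-6 columns.
#'
#' @param path file path.
#' @return data.frame (`chrom`, `start`, `end`, and `name` when present).
#' @export
read_bed <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  names(b)[1:3] <- c("chrom", "start", "end")
  if (ncol(b) >= 4) names(b)[4] <- "name"
  b[, seq_len(min(ncol(b), 4L)), drop = FALSE]
}

#' @rdname read_bed
#' @param x data.frame with `chrom`, `start`, `end` and optionally a name
#'   column (`name`, `origin` or `id`).
#' @export
write_bed <- function(x, path) {
  name <- x$name
  if (is.null(name)) name <- x$origin
  if (is.null(name)) name <- x$id
  if (is.null(name)) name <- rep(".", nrow(x))
  out <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = name, score = rep(0L, nrow(x)),
                    strand = rep(".", nrow(x)))
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read / write site classification tables
#'
#' Tab-separated with header: `chrom`, `pos` (0-based), `class`, `score`,
#' `context`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_site_classes <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' @rdname read_site_classes
#' @param x data.frame with at least `chrom`, `pos`, `class`.
#' @export
write_site_classes <- function(x, path) {
  cols <- intersect(c("chrom", "pos", "class", "score", "context"), names(x))
  write.table(x[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Filter sites on minor-allele frequency and call rate
#'
#' Retains sites with minor-allele frequency at least `maf` and call rate at
#' least `max_missing` (the VCFtools convention: `max-missing` is the
#' minimum fraction of called genotypes). Defaults implement the standard
#' `-maf 0.01 -max-missing 0.9` filter.
#'
#' @param x a [genotype_matrix()].
#' @param maf minimum minor-allele frequency.
#' @param max_missing minimum call-rate fraction.
#' @return the filtered `genotype_matrix`, with attribute `removed`
#'   (number of sites dropped).
#' @export
filter_sites <- function(x, maf = 0.01, max_missing = 0.9) {
  ac <- count_alleles(x)
  p <- ac$freq
  minor <- pmin(p, 1 - p)
  call_rate <- ac$total / (2 * nrow(x$samples))
  keep <- !is.na(p) & minor >= maf & call_rate >= max_missing
  out <- subset_genotypes(x, sites = keep)
  attr(out, "removed") <- sum(!keep)
  out
}
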