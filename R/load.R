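#' Classify sites as deleterious, neutral-intergenic or other
#'
#' A site with an annotation score strictly below 0.05 is deleterious; a
#' non-deleterious site in intergenic context is neutral-intergenic (the
#' reference class for load statistics); everything else is `other` and
#' excluded from load statistics. Sites with neither a score nor a context
#' fall into `other` with a warning.
#'
#' @param annotations data.frame with `chrom`, `pos` and at least one of
#'   `score` (numeric, `NA` allowed) and `context` (e.g. `"intergenic"`,
#'   `"genic"`).
#' @param score_threshold deleterious score cutoff (strict `<`).
#' @return the input with an added `class` column, ordered as given.
#' @export
classify_sites <- function(annotations, score_threshold = 0.05) {
  stopifnot(is.data.frame(annotations))
  score <- if (is.null(annotations$score)) rep(NA_real_, nrow(annotations))
           else annotations$score
  context <- if (is.null(annotations$context)) rep(NA_character_, nrow(annotations))
             else as.character(annotations$context)
  cls <- rep("other", nrow(annotations))
  cls[!is.na(context) & context == "intergenic"] <- "neutral-intergenic"
  cls[!is.na(score) & score < score_threshold] <- "deleterious"
  orphan <- is.na(score) & is.na(context)
  if (any(orphan))
    warning(sum(orphan), " site(s) with neither score nor context; classed 'other'")
  annotations$class <- cls
  annotations
}

# match a classification table to a genotype matrix's site order
site_classes_for <- function(x, classification) {
  if (length(classification) == nrow(x$sites)) return(as.character(classification))
  if (is.data.frame(classification)) {
    key <- paste(x$sites$chrom, x$sites$pos)
    ckey <- paste(classification$chrom, classification$pos)
    cls <- classification$class[match(key, ckey)]
    cls[is.na(cls)] <- "other"
    return(cls)
  }
  stop("classification must be a per-site vector or a table with chrom/pos/class")
}

#' Allele-frequency spectrum per site class
#'
#' Histogram of the alternate (deleterious for the deleterious class)
#' allele frequency per population group and site class, over bins of width
#' `1/bins` on (0, 1]; the top bin, frequency in (0.95, 1], is the explicit
#' "fixed" bin. Frequencies use called alleles only; monomorphic-reference
#' sites (frequency 0) and fully missing sites are excluded.
#'
#' @param x a [genotype_matrix()].
#' @param classification per-site class vector, or table with
#'   `chrom`, `pos`, `class` (see [classify_sites()]).
#' @param group group label.
#' @param bins number of equal bins on \[0, 1\] (default 20).
#' @param classes site classes to tabulate.
#' @return data.frame of class `class_spectrum`: `group`, `class`,
#'   `bin_lo`, `bin_hi`, `fixed` (logical), `count`, `prop`.
#' @export
frequency_spectrum <- function(x, classification, group, bins = 20,
                               classes = c("deleterious", "neutral-intergenic")) {
  cls <- site_classes_for(x, classification)
  ac <- count_alleles(x, group)
  breaks <- seq(0, 1, length.out = bins + 1)
  out <- lapply(classes, function(cl) {
    f <- ac$freq[cls == cl]
    f <- f[!is.na(f) & f > 0]
    cnt <- if (length(f)) tabulate(findInterval(f, breaks, left.open = TRUE,
                                                rightmost.closed = TRUE),
                                   nbins = bins) else integer(bins)
    data.frame(group = group, class = cl,
               bin_lo = breaks[-length(breaks)], bin_hi = breaks[-1],
               fixed = breaks[-1] == 1,
               count = cnt,
               prop = if (sum(cnt) > 0) cnt / sum(cnt) else rep(NA_real_, bins))
  })
  res <- do.call(rbind, out)
  class(res) <- c("class_spectrum", "data.frame")
  res
}

#' Relative load: deleterious vs neutral proportion per frequency bin
#'
#' Per bin, the deleterious proportion divided by the neutral-intergenic
#' proportion of the spectrum. Bins with no neutral mass are flagged
#' undefined (`NA` ratio); an empty class histogram yields all-undefined
#' ratios with a warning.
#'
#' @param spectrum a `class_spectrum` from [frequency_spectrum()].
#' @param deleterious_class,neutral_class class labels to compare.
#' @return data.frame `bin_lo`, `bin_hi`, `fixed`, `ratio`, `undefined`.
#' @export
relative_load <- function(spectrum, deleterious_class = "deleterious",
                          neutral_class = "neutral-intergenic") {
  d <- spectrum[spectrum$class == deleterious_class, , drop = FALSE]
  n <- spectrum[spectrum$class == neutral_class, , drop = FALSE]
  if (nrow(d) == 0L || nrow(n) == 0L)
    stop("spectrum must contain both classes")
  if (sum(d$count) == 0L || sum(n$count) == 0L) {
    warning("a class has zero total count; all ratios undefined")
    return(data.frame(d[, c("bin_lo", "bin_hi", "fixed")],
                      ratio = NA_real_, undefined = TRUE))
  }
  ratio <- ifelse(n$count > 0, (d$count / sum(d$count)) / (n$count / sum(n$count)),
                  NA_real_)
  data.frame(d[, c("bin_lo", "bin_hi", "fixed")],
             ratio = ratio, undefined = n$count == 0)
}

#' Per-individual genetic-load ratio
#'
#' For each sample, the number of deleterious sites where the sample carries
#' at least one alternate allele (dSNPs), the analogous count over
#' neutral-intergenic sites (iSNPs), and their ratio, reported per subgenome
#' and genome-wide. With `mode = "dosage"` alleles are counted instead of
#' sites.
#'
#' @param x a [genotype_matrix()].
#' @param classification per-site classes (vector or table).
#' @param samples sample ids (default: all).
#' @param mode `"presence"` (site counts, default) or `"dosage"` (allele
#'   counts).
#' @return data.frame `sample_id`, `subgenome` (`"A"`, `"C"` or
#'   `"genome"`), `dsnp`, `isnp`, `ratio` (`NA` with `undefined = TRUE`
#'   where the iSNP count is zero).
#' @export
individual_load <- function(x, classification, samples = NULL,
                            mode = c("presence", "dosage")) {
  mode <- match.arg(mode)
  cls <- site_classes_for(x, classification)
  if (is.null(samples)) samples <- x$samples$sample_id
  sub <- x$sites$subgenome
  rows <- list()
  for (s in samples) {
    g <- x$geno[match(s, x$samples$sample_id), ]
    carry <- if (mode == "presence") as.numeric(!is.na(g) & g >= 1L)
             else ifelse(is.na(g), 0, g)
    for (sg in c(unique(sub), "genome")) {
      in_sg <- if (sg == "genome") rep(TRUE, length(g)) else sub == sg
      dsnp <- sum(carry[in_sg & cls == "deleterious"])
      isnp <- sum(carry[in_sg & cls == "neutral-intergenic"])
      rows[[length(rows) + 1L]] <- data.frame(
        sample_id = s, subgenome = sg, dsnp = dsnp, isnp = isnp,
        ratio = if (isnp > 0) dsnp / isnp else NA_real_,
        undefined = isnp == 0)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
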