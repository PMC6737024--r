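#' Simulate an admixed population with known introgression tracts
#'
#' Each sample receives two haplotypes copied from random background-panel
#' haplotypes. For every introgression event, a binomial draw at the event's
#' carrier fraction decides which samples carry the donor tract; in carriers,
#' one randomly chosen haplotype has its alleles inside the event interval
#' replaced by a random donor-panel haplotype. A small per-allele noise rate
#' emulates post-admixture mutation and genotyping error. Truth tracts are
#' recorded per haplotype and tile every chromosome.
#'
#' @param background_panel,donor_panel phased [genotype_matrix()] objects on
#'   the same site list.
#' @param events data.frame with `chrom`, `start`, `end` (0-based half-open,
#'   within chromosome bounds) and `carrier_fraction`.
#' @param n_samples number of diploid samples to simulate.
#' @param seed optional integer seed.
#' @param noise per-allele flip probability applied after copying.
#' @param group group label for the simulated samples.
#' @return list with `genotypes` (phased `genotype_matrix`), `truth`
#'   (data.frame `sample_id`, `hap`, `chrom`, `start`, `end`, `origin` tiling
#'   each chromosome per haplotype) and `carriers` (list of carrier sample
#'   indices per event).
#' @export
simulate_admixed_population <- function(background_panel, donor_panel, events,
                                        n_samples, seed = NULL, noise = 0.01,
                                        group = "ADMIX") {
  stopifnot(inherits(background_panel, "genotype_matrix"),
            inherits(donor_panel, "genotype_matrix"))
  if (is.null(background_panel$haplotypes) || is.null(donor_panel$haplotypes))
    stop("panels must be phased (haplotypes present)")
  if (!identical(background_panel$sites[, c("chrom", "pos")],
                 donor_panel$sites[, c("chrom", "pos")]))
    stop("panels must be aligned on the same site list")
  sites <- background_panel$sites
  lens <- background_panel$chrom_lengths
  for (i in seq_len(NROW(events))) {
    ev <- events[i, ]
    if (!ev$chrom %in% names(lens) || ev$start < 0 || ev$end > lens[[ev$chrom]] ||
        ev$start >= ev$end)
      stop("event interval outside chromosome ", ev$chrom)
  }
  run <- function() {
    bg <- background_panel$haplotypes
    dn <- donor_panel$haplotypes
    nh <- 2L * n_samples
    hap <- bg[sample.int(nrow(bg), nh, replace = TRUE), , drop = FALSE]
    # donor tract bookkeeping: per haplotype, list of donor intervals per chrom
    donor_iv <- vector("list", nh)
    carriers <- list()
    for (i in seq_len(NROW(events))) {
      ev <- events[i, ]
      in_ev <- which(sites$chrom == ev$chrom & sites$pos >= ev$start &
                       sites$pos < ev$end)
      carrier <- which(runif(n_samples) < ev$carrier_fraction)
      carriers[[i]] <- carrier
      for (s in carrier) {
        h <- 2L * s - 2L + sample.int(2L, 1L)
        if (length(in_ev) > 0L)
          hap[h, in_ev] <- dn[sample.int(nrow(dn), 1L), in_ev]
        donor_iv[[h]] <- rbind(donor_iv[[h]],
                               data.frame(chrom = ev$chrom, start = ev$start,
                                          end = ev$end))
      }
    }
    if (noise > 0) {
      flip <- matrix(runif(length(hap)) < noise, nrow = nrow(hap))
      hap[flip] <- 1L - hap[flip]
    }
    ids <- sprintf("%s_%03d", group, seq_len(n_samples))
    gm <- genotype_matrix(NULL, sites, data.frame(sample_id = ids, group = group),
                          haplotypes = hap, chrom_lengths = lens)
    truth <- do.call(rbind, lapply(seq_len(nh), function(h) {
      s <- (h + 1L) %/% 2L
      out <- lapply(names(lens), function(ch) {
        L <- lens[[ch]]
        iv <- donor_iv[[h]]
        iv <- if (is.null(iv)) iv else iv[iv$chrom == ch, , drop = FALSE]
        if (is.null(iv) || nrow(iv) == 0L)
          return(data.frame(chrom = ch, start = 0L, end = L,
                            origin = "background"))
        iv <- iv[order(iv$start), , drop = FALSE]
        bounds <- sort(unique(c(0L, iv$start, iv$end, L)))
        seg <- data.frame(chrom = ch, start = bounds[-length(bounds)],
                          end = bounds[-1])
        seg$origin <- ifelse(vapply(seq_len(nrow(seg)), function(k)
          any(seg$start[k] >= iv$start & seg$end[k] <= iv$end), logical(1)),
          "donor", "background")
        merge_tracts(seg)
      })
      out <- do.call(rbind, out)
      out$sample_id <- ids[s]
      out$hap <- ifelse(h %% 2L == 1L, 1L, 2L)
      out
    }))
    truth <- truth[, c("sample_id", "hap", "chrom", "start", "end", "origin")]
    rownames(truth) <- NULL
    list(genotypes = gm, truth = truth, carriers = carriers)
  }
  if (is.null(seed)) run() else withr::with_seed(as.integer(seed), run())
}

#' Extract a phased source panel from a genotype matrix
#'
#' Convenience for local-ancestry painting: takes the haplotypes of the first
#' `n` samples of a phased genotype matrix as a reference panel.
#'
#' @param x a phased `genotype_matrix`.
#' @param n number of diploid samples to take.
#' @return 0/1 haplotype matrix with `2n` rows.
#' @export
panel_haplotypes <- function(x, n = nrow(x$samples)) {
  stopifnot(inherits(x, "genotype_matrix"), !is.null(x$haplotypes))
  n <- min(n, nrow(x$samples))
  x$haplotypes[seq_len(2L * n), , drop = FALSE]
}
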