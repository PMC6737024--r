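#' Simulate founder genomes and group genotype panels
#'
#' Draws a shared ancestral genome, derives the founder landrace (SL-1) and
#' the diverged interspecific donor (CDA) from it at the configured rates,
#' lays out gene and QTL intervals, assigns site classes (deleterious /
#' neutral-intergenic / other genic) with selection-skewed frequencies, and
#' generates one diploid genotype panel per population group plus a donor
#' haplotype panel. Group allele frequencies drift around the shared base
#' frequency under a Balding-Nichols model, so between-group differentiation
#' is controlled by `group_fst`. Sites inside `selected_regions` are locally
#' fixed for alternate alleles in the second group and absent from the first,
#' emulating a hard selective sweep contrast.
#'
#' @param config a [simulation_config()].
#' @return a list of class `population_sim` with elements `config`,
#'   `ancestral`, `assemblies` (SL-1 and CDA [assembly_set()]s with founder
#'   mutation positions as attributes), `sites` (site table with class,
#'   score, context and per-group frequencies), `genes`, `qtl`,
#'   `genotypes` (named list of [genotype_matrix()] per group),
#'   `donor_panel` (phased donor genotype matrix) and `truth`
#'   (site classes, selected regions, founder mutation positions).
#' @export
simulate_founders <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  withr::with_seed(config$seed, simulate_founders_impl(config))
}

simulate_founders_impl <- function(config) {
  chs <- config$chromosomes
  # --- ancestral genome and founder assemblies ---------------------------
  anc <- setNames(vapply(chs$length, random_chromosome, ""), chs$name)
  ancestral <- assembly_set("ancestral", anc)

  founder_mut <- list()
  sl1 <- anc; cda <- anc
  for (ch in chs$name) {
    m <- mutate_sequence(sl1[[ch]], config$polymorphism_density)
    sl1[[ch]] <- m$seq
    founder_mut[[paste0("SL-1.", ch)]] <- m$pos
    m <- mutate_sequence(cda[[ch]], config$donor_divergence)
    cda[[ch]] <- m$seq
    founder_mut[[paste0("CDA.", ch)]] <- m$pos
  }
  assemblies <- list(`SL-1` = assembly_set("SL-1", sl1),
                     CDA = assembly_set("CDA", cda))

  # --- gene and QTL intervals --------------------------------------------
  genes <- do.call(rbind, lapply(seq_len(nrow(chs)), function(i) {
    L <- chs$length[i]
    n <- max(1L, floor(L * config$gene_fraction / config$gene_length))
    starts <- floor(seq(0, L - config$gene_length, length.out = n))
    data.frame(chrom = chs$name[i], start = as.integer(starts),
               end = as.integer(starts + config$gene_length))
  }))
  genes$id <- sprintf("gene%05d", seq_len(nrow(genes)))

  qtl <- NULL
  if (config$n_qtl > 0L) {
    qi <- sample.int(nrow(chs), config$n_qtl, replace = TRUE)
    qlen <- sample(seq(5e4, 2e5, by = 1e4), config$n_qtl, replace = TRUE)
    qlen <- pmin(qlen, chs$length[qi] - 1L)
    qst <- floor(runif(config$n_qtl, 0, chs$length[qi] - qlen))
    qtl <- data.frame(chrom = chs$name[qi], start = as.integer(qst),
                      end = as.integer(qst + qlen),
                      id = sprintf("qtl%03d", seq_len(config$n_qtl)))
    qtl <- qtl[order(match(qtl$chrom, chs$name), qtl$start), ]
    rownames(qtl) <- NULL
  }

  # --- segregating sites --------------------------------------------------
  sites <- do.call(rbind, lapply(seq_len(nrow(chs)), function(i) {
    L <- chs$length[i]
    n <- rbinom(1L, L, min(config$polymorphism_density, 1))
    pos <- sort(sample.int(L, n)) - 1L
    ref <- substring(anc[[chs$name[i]]], pos + 1L, pos + 1L)
    shift <- sample.int(3L, n, replace = TRUE)
    alt <- BASES[((match(ref, BASES) - 1L + shift) %% 4L) + 1L]
    data.frame(chrom = chs$name[i], pos = pos, ref = ref, alt = alt,
               subgenome = chs$subgenome[i])
  }))
  rownames(sites) <- NULL
  ns <- nrow(sites)
  sites$base_freq <- runif(ns)^1.5  # low-frequency-biased neutral spectrum

  # --- site classes and selection skew -----------------------------------
  sites <- assign_site_classes(sites, genes, config$deleterious_fraction,
                               config$selection_skew)

  # --- group frequencies (Balding-Nichols drift) -------------------------
  groups <- names(config$founder_count)
  p0 <- pmin(pmax(sites$freq, 1e-4), 1 - 1e-4)
  bn_draw <- function(p, F) {
    if (F <= 0) return(p)
    q <- rbeta(length(p), p * (1 - F) / F, (1 - p) * (1 - F) / F)
    pmin(pmax(q, 1e-6), 1 - 1e-6)
  }
  group_freqs <- vapply(groups, function(g) bn_draw(p0, config$group_fst),
                        numeric(ns))
  donor_freq <- bn_draw(p0, config$donor_fst)

  # selected regions: fixed difference between group 1 (ref) and group 2 (alt)
  if (!is.null(config$selected_regions) && length(groups) >= 2L) {
    for (i in seq_len(nrow(config$selected_regions))) {
      r <- config$selected_regions[i, ]
      in_r <- sites$chrom == r$chrom & sites$pos >= r$start & sites$pos < r$end
      group_freqs[in_r, 1L] <- 0
      group_freqs[in_r, 2L] <- 1
    }
  }

  # --- genotype panels ----------------------------------------------------
  draw_panel <- function(freq, n_dip, ids, group) {
    nh <- 2L * n_dip
    hap <- matrix(rbinom(nh * ns, 1L, rep(freq, each = nh)), nrow = nh)
    genotype_matrix(NULL, sites[, c("chrom", "pos", "ref", "alt", "subgenome")],
                    data.frame(sample_id = ids, group = group),
                    haplotypes = hap,
                    chrom_lengths = setNames(as.integer(chs$length), chs$name))
  }
  genotypes <- list()
  for (g in groups) {
    n <- config$founder_count[[g]]
    genotypes[[g]] <- draw_panel(group_freqs[, g], n,
                                 sprintf("%s_%02d", g, seq_len(n)), g)
  }
  donor_panel <- draw_panel(donor_freq, config$panel_size,
                            sprintf("DONOR_%02d", seq_len(config$panel_size)),
                            "DONOR")

  structure(list(
    config = config, ancestral = ancestral, assemblies = assemblies,
    sites = sites, genes = genes, qtl = qtl,
    group_freqs = group_freqs, donor_freq = donor_freq,
    genotypes = genotypes, donor_panel = donor_panel,
    truth = list(site_class = sites$class,
                 selected_regions = config$selected_regions,
                 founder_mutations = founder_mut)),
    class = "population_sim")
}

#' Assign site classes and selection-adjusted frequencies
#'
#' Sites falling outside every gene interval are labelled
#' `neutral-intergenic`; a configured fraction of genic sites is labelled
#' `deleterious` and given a synthetic annotation score below 0.05 (other
#' genic sites score >= 0.05 and are labelled `other`). Deleterious site
#' frequencies are the base frequencies multiplied by `selection_skew`
#' (capped at 1), so the realized deleterious:neutral mean-frequency ratio
#' converges to the skew as the site count grows.
#'
#' @param sites data.frame with `chrom`, `pos` and (optionally) `base_freq`.
#' @param gene_intervals data.frame with `chrom`, `start`, `end`
#'   (0-based half-open, within chromosome bounds).
#' @param deleterious_fraction fraction of genic sites labelled deleterious.
#' @param selection_skew frequency down-weighting for deleterious sites;
#'   must be >= 0.
#' @return `sites` with added columns `context` ("genic"/"intergenic"),
#'   `class`, `score` and `freq` (adjusted frequency).
#' @export
assign_site_classes <- function(sites, gene_intervals, deleterious_fraction,
                                selection_skew) {
  if (selection_skew < 0) stop("selection_skew must be >= 0")
  ns <- nrow(sites)
  genic <- rep(FALSE, ns)
  for (ch in unique(sites$chrom)) {
    gi <- gene_intervals[gene_intervals$chrom == ch, , drop = FALSE]
    si <- which(sites$chrom == ch)
    if (nrow(gi) == 0L || length(si) == 0L) next
    r_g <- IRanges::IRanges(gi$start + 1L, gi$end)
    r_s <- IRanges::IRanges(sites$pos[si] + 1L, width = 1L)
    genic[si] <- IRanges::overlapsAny(r_s, r_g)
  }
  sites$context <- ifelse(genic, "genic", "intergenic")
  del <- genic & (runif(ns) < deleterious_fraction)
  sites$class <- ifelse(del, "deleterious",
                        ifelse(genic, "other", "neutral-intergenic"))
  score <- rep(NA_real_, ns)
  score[del] <- runif(sum(del)) * 0.05
  score[genic & !del] <- 0.05 + runif(sum(genic & !del)) * 0.95
  sites$score <- score
  base <- if (is.null(sites$base_freq)) runif(ns)^1.5 else sites$base_freq
  sites$freq <- ifelse(del, pmin(1, base * selection_skew), base)
  sites
}
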