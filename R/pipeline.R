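#' Pipeline run configuration
#'
#' Bundles the simulation configuration with every stage parameter at its
#' standard default: 50 kb IBD blocks, 100 kb / 10 kb scan windows, a Z
#' threshold of 3 SD, the >0.9 fixation rule, the maf 0.01 / call-rate 0.9
#' site filter, 50-SNP painting windows and 20 spectrum bins. The
#' configuration is serialized verbatim into the run report for provenance.
#'
#' @param sim a [simulation_config()] (or arguments passed to it via `...`
#'   when `sim` is `NULL`).
#' @param out_dir output directory for stage files and the report.
#' @param block_size IBD block length in bp.
#' @param anchor_k IBD anchor k-mer length.
#' @param min_match_fraction IBD assignment floor.
#' @param window,step scan window grid in bp.
#' @param z_threshold divergent-region threshold in SD.
#' @param z_scope `"genome"` (Z over both subgenomes jointly, default) or
#'   `"subgenome"`.
#' @param maf,max_missing site filter.
#' @param window_snps painting window size in SNPs.
#' @param fixation_threshold introgression fixation rule (strict `>`).
#' @param carrier_level `"sample"` or `"haplotype"` counting for fixation.
#' @param bins spectrum bins.
#' @param scan_groups character pair: the two groups scanned against each
#'   other (FST) — first is the reference (e.g. EU).
#' @param ... forwarded to [simulation_config()] when `sim` is `NULL`.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, out_dir = NULL,
                       block_size = 50000, anchor_k = 21,
                       min_match_fraction = 0.1,
                       window = 1e5, step = 1e4,
                       z_threshold = 3, z_scope = c("genome", "subgenome"),
                       maf = 0.01, max_missing = 0.9,
                       window_snps = 50, fixation_threshold = 0.9,
                       carrier_level = c("sample", "haplotype"),
                       bins = 20, scan_groups = NULL, ...) {
  if (is.null(sim)) sim <- simulation_config(...)
  stopifnot(inherits(sim, "simulation_config"))
  if (is.null(out_dir)) stop("configuration error [config]: out_dir is required")
  groups <- names(sim$founder_count)
  if (is.null(scan_groups)) scan_groups <- groups[seq_len(min(2L, length(groups)))]
  structure(list(sim = sim, out_dir = out_dir, block_size = block_size,
                 anchor_k = anchor_k, min_match_fraction = min_match_fraction,
                 window = window, step = step, z_threshold = z_threshold,
                 z_scope = match.arg(z_scope), maf = maf,
                 max_missing = max_missing, window_snps = window_snps,
                 fixation_threshold = fixation_threshold,
                 carrier_level = match.arg(carrier_level), bins = bins,
                 scan_groups = scan_groups), class = "run_config")
}

#' Simulate the full study: founders, pedigree and admixed groups
#'
#' Composes the generator stages: founder genomes and group panels
#' ([simulate_founders()]), the four-line pedigree ([simulate_pedigree()]),
#' and donor introgression into the recipient groups
#' ([simulate_admixed_population()]); recipient groups' genotype matrices
#' are replaced by their admixed versions. Sub-stage seeds are derived from
#' the configuration seed, so one seed fixes the whole study.
#'
#' @param config a [simulation_config()].
#' @return list of class `study_sim` with `founders`, `pedigree`,
#'   `genotypes` (final per-group matrices), `ancestry_truth` and `panels`
#'   (background/donor haplotype panels used for admixture).
#' @export
simulate_study <- function(config) {
  founders <- simulate_founders(config)
  pedigree <- simulate_pedigree(founders, seed = config$seed + 1L)
  genotypes <- founders$genotypes
  ancestry_truth <- NULL
  panels <- NULL
  ev <- config$introgression_events
  if (!is.null(ev) && nrow(ev) > 0L) {
    for (recip in unique(ev$recipient)) {
      if (!recip %in% names(genotypes)) next
      background <- subset_genotypes(genotypes[[recip]],
                                     samples = seq_len(min(config$panel_size,
                                                           n_samples(genotypes[[recip]]))))
      adm <- simulate_admixed_population(
        background, founders$donor_panel,
        ev[ev$recipient == recip, , drop = FALSE],
        n_samples = n_samples(genotypes[[recip]]),
        seed = config$seed + 2L, group = recip)
      adm$genotypes$samples$sample_id <- genotypes[[recip]]$samples$sample_id
      rownames(adm$genotypes$geno) <- genotypes[[recip]]$samples$sample_id
      genotypes[[recip]] <- adm$genotypes
      ancestry_truth <- adm$truth
      panels <- list(background = panel_haplotypes(background),
                     donor = panel_haplotypes(founders$donor_panel))
    }
  }
  structure(list(founders = founders, pedigree = pedigree,
                 genotypes = genotypes, ancestry_truth = ancestry_truth,
                 panels = panels), class = "study_sim")
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage [", name, "] failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline on a simulated study
#'
#' Chains simulate, IBD tracing (including decomposition of the
#' landrace-x-donor parent), selection scan, local ancestry and genetic
#' load, writes every stage's tables plus one structured YAML report, and
#' returns the report. Identical configuration and seed give a
#' byte-identical report.
#'
#' @param config a [run_config()].
#' @return the report list, invisibly; files under `config$out_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(config = serialize_config(config))

  study <- stage("simulate", simulate_study(config$sim))
  ped <- study$pedigree

  # --- IBD ---------------------------------------------------------------
  report$ibd <- stage("ibd", {
    parents <- ped$assemblies[c("NY1", "CY2", "SL-1", "CDA")]
    tr <- ibd_trace(ped$assemblies$NY7, parents, config$block_size,
                    config$anchor_k, config$min_match_fraction)
    track2 <- decompose_parent(tr$track, ped$assemblies$NY7, "CY2",
                               ped$assemblies[c("SL-1", "CDA")],
                               config$anchor_k, config$min_match_fraction)
    truth <- block_truth_labels(tr$matches$blocks, ped$tracks$NY7)
    acc <- mean(tr$track$origin == truth)
    write_bed(tr$track, file.path(config$out_dir, "ibd_track.bed"))
    write_bed(track2, file.path(config$out_dir, "ibd_track_decomposed.bed"))
    sm <- tr$summary
    write.table(sm, file.path(config$out_dir, "ibd_contributions.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    list(contributions = setNames(as.list(round(sm$percent, 4)), sm$origin),
         decomposed = setNames(
           as.list(round(summarize_contributions(track2)$percent, 4)),
           summarize_contributions(track2)$origin),
         block_accuracy = round(acc, 4))
  })

  # --- selection scan ----------------------------------------------------
  report$scan <- stage("scan", {
    gm <- combine_genotypes(study$genotypes)
    gm <- filter_sites(gm, config$maf, config$max_missing)
    ga <- config$scan_groups[1]; gb <- config$scan_groups[2]
    pis <- lapply(names(study$genotypes), function(g)
      windowed_pi(gm, g, config$window, config$step))
    names(pis) <- names(study$genotypes)
    fst <- windowed_fst(gm, ga, gb, config$window, config$step)
    if (config$z_scope == "genome") {
      fst$z <- z_transform(fst$value)
    } else {
      sg <- substr(fst$chrom, 1, 1)
      fst$z <- NA_real_
      for (s in unique(sg)) fst$z[sg == s] <- z_transform(fst$value[sg == s])
    }
    regions <- call_divergent_regions(fst, config$z_threshold)
    genes_in <- intersect_features(regions, study$founders$genes,
                                   chromosomes = names(gm$chrom_lengths))
    ld <- lapply(config$scan_groups, function(g) ld_decay(gm, g))
    names(ld) <- config$scan_groups
    write.table(fst, file.path(config$out_dir, "fst_windows.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    for (g in names(pis))
      write.table(pis[[g]], file.path(config$out_dir,
                                      paste0("pi_windows_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    write_bed(data.frame(regions,
                         name = rep("divergent", nrow(regions))),
              file.path(config$out_dir, "divergent_regions.bed"))
    for (g in names(ld))
      write.table(ld[[g]], file.path(config$out_dir,
                                     paste0("ld_decay_", g, ".tsv")),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    list(n_sites = n_sites(gm),
         mean_pi = lapply(pis, function(p)
           round(mean(p$value, na.rm = TRUE), 8)),
         n_windows = nrow(fst),
         n_flagged_windows = attr(regions, "n_flagged"),
         n_divergent_regions = nrow(regions),
         divergent_bp = attr(regions, "total_bp"),
         n_divergent_genes = genes_in$n_features)
  })

  # --- local ancestry ----------------------------------------------------
  report$ancestry <- stage("ancestry", {
    if (is.null(study$panels)) list(skipped = "no introgression events")
    else {
      recip <- unique(config$sim$introgression_events$recipient)[1]
      tracks <- paint_population(study$genotypes[[recip]],
                                 study$panels$background, study$panels$donor,
                                 config$window_snps,
                                 labels = c("background", "donor"))
      fx <- population_ancestry_frequency(tracks, "donor",
                                          level = config$carrier_level)
      fixed <- call_fixed_introgressions(fx, config$fixation_threshold)
      write.table(fx, file.path(config$out_dir, "ancestry_fixation.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(fixed$regions))
        write_bed(data.frame(fixed$regions,
                             name = rep("fixed_introgression",
                                        nrow(fixed$regions))),
                  file.path(config$out_dir, "fixed_introgressions.bed"))
      list(recipient = recip,
           unresolved_fraction = round(mean(tracks$label == "unresolved"), 6),
           n_fixed_regions = nrow(fixed$regions),
           fixed_bp = fixed$total_bp)
    }
  })

  # --- genetic load -------------------------------------------------------
  report$load <- stage("load", {
    gm <- combine_genotypes(study$genotypes)
    cls <- study$founders$sites[, c("chrom", "pos", "class")]
    groups <- names(study$genotypes)
    spectra <- lapply(groups, function(g)
      frequency_spectrum(gm, cls, g, config$bins))
    names(spectra) <- groups
    rel <- lapply(spectra, relative_load)
    loads <- individual_load(gm, cls)
    write.table(do.call(rbind, spectra),
                file.path(config$out_dir, "load_spectra.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    write.table(loads, file.path(config$out_dir, "individual_load.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
    gen <- loads[loads$subgenome == "genome", ]
    mean_ratio <- tapply(gen$ratio, gm$samples$group[match(gen$sample_id,
                                                           gm$samples$sample_id)],
                         mean, na.rm = TRUE)
    list(mean_dsnp_isnp_ratio = as.list(round(mean_ratio, 6)),
         fixed_bin_relative_load = lapply(rel, function(r)
           round(r$ratio[r$fixed], 6)))
  })

  yaml::write_yaml(report, file.path(config$out_dir, "report.yaml"))
  log <- c(paste("polyped", as.character(utils::packageVersion("polyped"))),
           paste("R", paste(R.version$major, R.version$minor, sep = ".")),
           paste("seed", config$sim$seed))
  writeLines(log, file.path(config$out_dir, "run.log"))
  invisible(report)
}

# flatten a run_config into YAML-friendly plain lists
serialize_config <- function(config) {
  out <- unclass(config)
  sim <- unclass(out$sim)
  sim$chromosomes <- as.list(setNames(sim$chromosomes$length,
                                      sim$chromosomes$name))
  sim$founder_count <- as.list(sim$founder_count)
  if (!is.null(sim$introgression_events))
    sim$introgression_events <- lapply(
      seq_len(nrow(sim$introgression_events)),
      function(i) as.list(sim$introgression_events[i, ]))
  if (!is.null(sim$selected_regions))
    sim$selected_regions <- lapply(
      seq_len(nrow(sim$selected_regions)),
      function(i) as.list(sim$selected_regions[i, ]))
  out$sim <- sim
  out$out_dir <- NULL  # keep reports location-independent
  out
}
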