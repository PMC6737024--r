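#' Write a simulated dataset to standard formats
#'
#' Materializes a simulation as the files a real study would start from:
#' one FASTA per genome, a single multi-sample VCF of all groups, BED files
#' for genes, QTL and truth tracts, a site-classification TSV, a group file
#' and the configuration (with seed) as YAML. Reading the files back
#' reproduces the in-memory objects.
#'
#' @param founders a `population_sim` from [simulate_founders()].
#' @param dir output directory (created if needed).
#' @param pedigree optional result of [simulate_pedigree()]; adds the
#'   pedigree FASTA files and the derived cultivar's truth-tract BED.
#' @param extra_genotypes optional named list of additional
#'   [genotype_matrix()] objects (e.g. an admixed group) replacing the
#'   same-named simulated groups in the VCF.
#' @return named character vector of written paths, invisibly.
#' @export
write_dataset <- function(founders, dir, pedigree = NULL,
                          extra_genotypes = NULL) {
  stopifnot(inherits(founders, "population_sim"))
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok || !dir.exists(dir)) stop("cannot create directory ", dir)
  }
  paths <- c()
  genomes <- c(list(ancestral = founders$ancestral), founders$assemblies,
               if (!is.null(pedigree)) pedigree$assemblies)
  genomes <- genomes[!duplicated(names(genomes))]
  for (g in names(genomes)) {
    f <- file.path(dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", g), ".fa"))
    write_assembly(genomes[[g]], f)
    paths[paste0("fasta_", g)] <- f
  }
  gts <- founders$genotypes
  if (!is.null(extra_genotypes))
    for (g in names(extra_genotypes)) gts[[g]] <- extra_genotypes[[g]]
  combined <- combine_genotypes(gts)
  paths["vcf"] <- file.path(dir, "genotypes.vcf")
  write_vcf(combined, paths["vcf"])
  paths["groups"] <- file.path(dir, "groups.tsv")
  write_groups(combined$samples, paths["groups"])
  paths["genes"] <- file.path(dir, "genes.bed")
  write_bed(founders$genes, paths["genes"])
  if (!is.null(founders$qtl)) {
    paths["qtl"] <- file.path(dir, "qtl.bed")
    write_bed(founders$qtl, paths["qtl"])
  }
  paths["site_classes"] <- file.path(dir, "site_classes.tsv")
  write_site_classes(founders$sites, paths["site_classes"])
  if (!is.null(pedigree)) {
    paths["truth_tracts"] <- file.path(dir, "truth_tracts.bed")
    write_bed(pedigree$tracks$NY7, paths["truth_tracts"])
  }
  paths["config"] <- file.path(dir, "config.yaml")
  cfg <- founders$config
  cfg$chromosomes <- as.list(setNames(cfg$chromosomes$length,
                                      cfg$chromosomes$name))
  cfg$introgression_events <- if (is.null(cfg$introgression_events)) NULL
    else lapply(seq_len(nrow(cfg$introgression_events)), function(i)
      as.list(cfg$introgression_events[i, ]))
  cfg$selected_regions <- if (is.null(cfg$selected_regions)) NULL
    else lapply(seq_len(nrow(cfg$selected_regions)), function(i)
      as.list(cfg$selected_regions[i, ]))
  cfg$founder_count <- as.list(cfg$founder_count)
  yaml::write_yaml(unclass(cfg), paths["config"])
  invisible(paths)
}
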