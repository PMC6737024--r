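#' Default chromosome layout for simulations
#'
#' Ten chromosomes of 1 Mb each, five per subgenome (A01..A05, C01..C05),
#' mirroring the two-subgenome structure of an allotetraploid at a size where
#' every stage runs in minutes.
#'
#' @param n_per_subgenome chromosomes per subgenome.
#' @param length chromosome length in bp.
#' @return data.frame with columns `name`, `subgenome`, `length`.
#' @export
default_chromosomes <- function(n_per_subgenome = 5L, length = 1e6) {
  data.frame(
    name = c(sprintf("A%02d", seq_len(n_per_subgenome)),
             sprintf("C%02d", seq_len(n_per_subgenome))),
    subgenome = rep(c("A", "C"), each = n_per_subgenome),
    length = as.integer(length))
}

#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator. Defaults describe the
#' study conditions the package is validated under: a four-line pedigree with
#' two crosses on 10 x 1 Mb chromosomes, three population groups sized like
#' the resequencing panel (EU = 59, AS_DH = 38, AS_DL = 30), per-lineage
#' polymorphism density 1e-3/bp, an interspecific donor diverged at 5e-3/bp,
#' Poisson(2) crossovers per chromosome per meiosis, per-generation mutation
#' 1e-4/bp, and deleterious sites whose frequencies are down-weighted by a
#' selection skew of 0.5 relative to neutral sites.
#'
#' @param seed integer RNG seed; identical configurations (including seed)
#'   produce byte-identical outputs.
#' @param chromosomes data.frame (`name`, `subgenome`, `length`).
#' @param founder_count named integer vector: diploid samples per group.
#' @param polymorphism_density segregating sites per bp per lineage.
#' @param donor_divergence per-bp substitution rate of the interspecific
#'   donor relative to the shared ancestral background.
#' @param recombination_rate expected crossovers per chromosome per meiosis.
#' @param mutation_rate per-bp mutation rate per pedigree generation.
#' @param deleterious_fraction fraction of genic sites labelled deleterious.
#' @param selection_skew mean frequency ratio deleterious:neutral; must be
#'   >= 0 (1 = no selection).
#' @param group_fst drift level (Balding-Nichols F) separating the groups.
#' @param donor_fst drift level separating the donor panel.
#' @param gene_fraction fraction of each chromosome covered by genes.
#' @param gene_length gene length in bp.
#' @param n_qtl number of QTL intervals scattered over the genome.
#' @param introgression_events data.frame (`donor`, `recipient`, `chrom`,
#'   `start`, `end`, `carrier_fraction`); default: one donor tract spanning
#'   the middle 60% of the first A chromosome into AS_DH, carried by 95%
#'   of samples.
#' @param selected_regions data.frame (`chrom`, `start`, `end`) of tracts
#'   locally fixed for alternate alleles between AS_DH and EU; default: the
#'   middle 30% of the first C chromosome.
#' @param carrier_fraction default carrier fraction for introgression events.
#' @param panel_size diploid accessions per local-ancestry source panel.
#' @return a validated list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              chromosomes = default_chromosomes(),
                              founder_count = c(EU = 59L, AS_DH = 38L, AS_DL = 30L),
                              polymorphism_density = 1e-3,
                              donor_divergence = 5e-3,
                              recombination_rate = 2,
                              mutation_rate = 1e-4,
                              deleterious_fraction = 0.2,
                              selection_skew = 0.5,
                              group_fst = 0.1,
                              donor_fst = 0.5,
                              gene_fraction = 0.35,
                              gene_length = 3000L,
                              n_qtl = 20L,
                              introgression_events = NULL,
                              selected_regions = NULL,
                              carrier_fraction = 0.95,
                              panel_size = 12L) {
  stopifnot(is.data.frame(chromosomes),
            all(c("name", "subgenome", "length") %in% names(chromosomes)))
  if (any(chromosomes$length <= 0)) stop("chromosome lengths must be > 0")
  if (!all(chromosomes$subgenome %in% c("A", "C")))
    stop("subgenome must be 'A' or 'C'")
  rates <- c(polymorphism_density, donor_divergence, recombination_rate,
             mutation_rate, deleterious_fraction, group_fst, donor_fst,
             gene_fraction)
  if (any(rates < 0)) stop("rates must be >= 0")
  if (selection_skew < 0) stop("selection_skew must be >= 0")
  if (carrier_fraction < 0 || carrier_fraction > 1)
    stop("carrier_fraction must be in [0, 1]")
  if (is.null(names(founder_count))) stop("founder_count must be named")

  first_a <- chromosomes$name[chromosomes$subgenome == "A"][1]
  first_c <- chromosomes$name[chromosomes$subgenome == "C"][1]
  len_of <- function(ch) chromosomes$length[chromosomes$name == ch]
  if (is.null(introgression_events) && !is.na(first_a)) {
    L <- len_of(first_a)
    introgression_events <- data.frame(
      donor = "DONOR", recipient = names(founder_count)[2],
      chrom = first_a, start = as.integer(0.2 * L), end = as.integer(0.8 * L),
      carrier_fraction = carrier_fraction)
  }
  if (is.null(selected_regions) && !is.na(first_c)) {
    L <- len_of(first_c)
    selected_regions <- data.frame(
      chrom = first_c, start = as.integer(0.3 * L), end = as.integer(0.6 * L))
  }
  for (i in seq_len(NROW(introgression_events))) {
    ev <- introgression_events[i, ]
    L <- len_of(ev$chrom)
    if (length(L) == 0L) stop("introgression event on unknown chromosome ", ev$chrom)
    if (ev$start < 0 || ev$end > L || ev$start >= ev$end)
      stop("introgression event interval outside chromosome ", ev$chrom)
    if (ev$carrier_fraction < 0 || ev$carrier_fraction > 1)
      stop("carrier fraction must be in [0, 1]")
  }
  structure(list(
    seed = as.integer(seed), chromosomes = chromosomes,
    founder_count = founder_count,
    polymorphism_density = polymorphism_density,
    donor_divergence = donor_divergence,
    recombination_rate = recombination_rate,
    mutation_rate = mutation_rate,
    deleterious_fraction = deleterious_fraction,
    selection_skew = selection_skew,
    group_fst = group_fst, donor_fst = donor_fst,
    gene_fraction = gene_fraction, gene_length = as.integer(gene_length),
    n_qtl = as.integer(n_qtl),
    introgression_events = introgression_events,
    selected_regions = selected_regions,
    carrier_fraction = carrier_fraction,
    panel_size = as.integer(panel_size)), class = "simulation_config")
}

#' Pedigree of the simulated derived cultivar
#'
#' Four lines and two crosses: the founder landrace (SL-1) and the
#' interspecific donor (CDA) are crossed to give CY2; NY1 is derived from
#' SL-1 by selfing; NY1 x CY2 gives the derived cultivar NY7. Edges are
#' ordered so parents precede children.
#'
#' @return list with `nodes` and an `edges` data.frame
#'   (`child`, `parent1`, `parent2`).
#' @export
pedigree_spec <- function() {
  edges <- data.frame(
    child = c("NY1", "CY2", "NY7"),
    parent1 = c("SL-1", "SL-1", "NY1"),
    parent2 = c("SL-1", "CDA", "CY2"))
  nodes <- c("SL-1", "CDA", "NY1", "CY2", "NY7")
  seen <- setdiff(nodes, edges$child)
  for (i in seq_len(nrow(edges))) {
    if (!all(c(edges$parent1[i], edges$parent2[i]) %in% seen))
      stop("pedigree edges must be ordered so parents precede children")
    seen <- c(seen, edges$child[i])
  }
  list(nodes = nodes, edges = edges)
}
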